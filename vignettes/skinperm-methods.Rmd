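---
title: "Methods: topological QSAR models of skin permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological QSAR models of skin permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Percutaneous absorption is summarized by the skin permeability
coefficient $K_p$ (cm/h); models work on $\log_{10} K_p$, which for
typical permeants spans roughly $-6.1$ to $-0.8$. The package implements
a three-descriptor model family for this endpoint: a hydrophobicity term,
a size/branching term and a drug-likeness indicator, feeding either an
ordinary least-squares model or an $\varepsilon$-insensitive support
vector regression. All three descriptors are 2D/topological, so no
conformer generation or geometry optimization is involved anywhere.

## Descriptors

**A log P and its cosine transform.** A log P is an atom-contribution
estimate of the octanol–water partition coefficient,
$\mathrm{AlogP} = \sum_i n_i a_i$ over typed atoms (hydrogens included).
The package delegates atom typing and the contribution sums to Open
Babel's implementation of the Wildman–Crippen scheme — the published
successor of the Ghose–Crippen–Viswanadhan constants — and records that
provenance in the `alogp_table` object. A custom element-level table can
be injected for testing (zeroed tables, additivity checks); element-level
typing is deliberately coarser than the published atom typing and is not
meant for production values. The models use
$\cos^2[(4.31 + \mathrm{AlogP})/8.66]$ with the argument in radians:
over the A log P range of interest the argument spans about $[0, 1]$, so
the transform is a smooth monotone map into $[0,1]$ (period
$8.66\pi$ in A log P, far wider than any chemically meaningful range).

**X3v.** The valence connectivity index of order $k$ is
$\sum_{\text{paths}} (\prod_i \delta^v_i)^{-1/2}$ over all simple paths
of $k$ edges ($k+1$ distinct vertices) in the H-depleted molecular
graph, each undirected path counted once; orders 0–5 are exposed, the
models use $k = 3$. The valence vertex degree follows the Kier–Hall
convention: $\delta^v = Z^v - h$ for second-row atoms and
$\delta^v = (Z^v - h)/(Z - Z^v - 1)$ for heavier heteroatoms, where
$Z^v$ counts valence electrons and $h$ attached hydrogens. This
convention is an explicit design choice: it is what the major descriptor
packages implement, and it depends only on the element and its hydrogen
count, so kekulized and aromatic representations of the same ring give
identical indices (the package's relabeling-invariance tests rely on
this). Degree-zero vertices (the lone carbon of methane) contribute
nothing to the order-0 sum, avoiding a division by zero.

**Neoplastic-80.** The indicator equals 1 iff the molecule carries at
least one qualifying functional group — benzene ring, heterocyclic ring,
aliphatic amine, carboxamide, alcoholic hydroxyl, carboxy ester, keto
group — and all four bulk properties fall inside the 80%-coverage
ranges: A log P $\in [-1.5, 4.7]$, molar refractivity $\in [43, 128]$
cm³/mol, MW $\in [180, 470]$ g/mol, total atom count $\in [21, 63]$.
Three conventions were genuinely open and were fixed as follows:
interval bounds are inclusive (the ranges read as closed intervals);
the atom count includes hydrogens (the drug-likeness literature counts
total atoms); and the functional groups are detected with the SMARTS
patterns returned by `neoplastic_groups()`, each unit-tested on one
positive and one negative example. The aliphatic-amine pattern excludes
amides, anilines and N–heteroatom bonds; the alcoholic-hydroxyl pattern
requires an sp³ carbon, excluding phenols and acids.

## Dataset handling

Compound tables are CSV (UTF-8, comma, header, "." decimal) with
`id`, `smiles`, `logkp` and optional tabulated descriptor columns.
Duplicate structures are detected by Open Babel canonical SMILES — a
stricter, fully automatic version of the molecular-weight-plus-inspection
screen used when such tables are curated by hand — keeping the first
occurrence and warning when duplicates disagree in log Kp by more than
0.01. The descriptor pre-filter removes constant columns, then greedily
drops any column correlating above $|r| = 0.90$ with an already-kept one,
scanning in column order (deterministic, matching the usual
first-come-first-kept practice).

The Kennard–Stone split seeds the training set with the two points at
maximal Euclidean distance and repeatedly adds the candidate whose
minimum distance to the selected set is largest. Every tie breaks toward
the lowest row index, making the split bit-reproducible. The distance
space is a genuinely open choice (it is rarely reported); the package
standardizes the three model descriptors to zero mean and unit variance
and splits there, with the column set overridable. Because the original
split of the published dataset is not recoverable exactly, any statistic
that depends on the partition carries reconstruction ambiguity; the
package treats the published training fraction 139/274 as the default
proportion.

## Least squares

`ols_fit()` wraps `stats::lm` and assembles the diagnostics reported for
QSAR models: per-coefficient standard error, $t$, two-sided $P$
(a printed "0.000" in such tables is read as $< 0.0005$), variance
inflation factors $1/(1 - R_j^2)$, and $n$, $R$, $R^2$, adjusted $R^2$,
standard error of estimate and $F$. Stepwise selection is the classical
SPSS-style procedure on coefficient $P$ values (entry $p < 0.05$,
removal $p > 0.10$ — the tool defaults, since the thresholds themselves
are rarely stated); with entry stricter than removal the procedure
terminates, and it is deterministic given column order.

The four published equations are frozen verbatim in
`published_equations()`. The full-set and training-set models disagree
about which of X3v and Neoplastic-80 carries the larger coefficient
(full set: $-0.174$ X3v, $-0.704$ Neo; training set and its diagnostics
table: $-0.722$ X3v, $-0.168$ Neo). This looks like a typesetting swap
in one of the two, but both are carried exactly as printed — a frozen
predictor that silently "corrects" its source is worse than a faithful
one — and the package's own refits on synthetic data are the place where
internally consistent coefficients come from.

## Support vector regression

The SVR minimizes $\tfrac12\|w\|^2 + C\sum_i(\xi_i + \xi_i^*)$ under the
$\varepsilon$-insensitive constraints, solved in the dual over the net
coefficients $\beta_i = a_i - a_i^*$:
$$\max_\beta \; y^\top\beta - \varepsilon\|\beta\|_1
  - \tfrac12 \beta^\top K \beta, \qquad
  \textstyle\sum_i \beta_i = 0,\; -C \le \beta_i \le C,$$
with $K_{ij} = \exp(-\gamma\|x_i - x_j\|^2)$. The solver (compiled code)
is a maximal-violating-pair SMO: each iteration selects the feasible
pair with the largest joint KKT violation and solves the two-variable
subproblem exactly — the subproblem objective is piecewise quadratic
because of the $\ell_1$ kink at zero, so the optimum of each sign region
and every breakpoint is evaluated directly rather than approximated.
Convergence is declared when the best violating pair improves the dual
by less than $10^{-6}$; the test suite verifies KKT residuals below
$10^{-3}$, exact box feasibility, and agreement with an exact
active-set QP oracle to $10^{-6}$ in the objective.

The bias $b$ averages the KKT equalities over unbounded support vectors;
when every coefficient sits at a bound it falls back to the midpoint of
the feasible interval, and for an all-zero solution (constant response
within the tube) to the mean residual, which reproduces the constant
exactly. Inputs are standardized to zero mean/unit variance inside
`svr_fit()` and the standardization is stored in the model, so a
serialized model is self-contained; the response is not scaled, keeping
$\varepsilon$ in log-Kp units. The published optimum
$(C, \gamma) = (7.2906, 1.7200)$ with $\varepsilon = 0.001$ is treated
as a frozen input rather than a reproduction target: the genetic
algorithm's fitness folds and seed that produced it are unrecoverable.

**Genetic algorithm.** Tuning minimizes the 5-fold cross-validation MSE
over $C \in [0, 1000]$, $\gamma \in [0, 10]$ (at most 200 generations,
population 20). The fold assignment is drawn once per run from the seed
so fitness values are comparable across generations. The operators are
not dictated by the protocol and were fixed as: tournament selection of
size 2, BLX-0.5 blend crossover (rate 0.9), per-gene Gaussian mutation
with standard deviation 5% of the range (rate 0.2), elitism of 1.
Children are clipped to the search box and $C$ is clamped to
$\ge 10^{-6}$, since $C = 0$ makes the dual degenerate.

## Validation

`rms_r2()` reports $\sqrt{\text{mean squared residual}}$ and the squared
Pearson correlation of observed and predicted. The leave-one-out
statistic is reported as a Pearson correlation $R$ (not $q^2$): the
"internal correlation coefficient" convention for these models — the
assumption is isolated in one function so a $q^2$ reading would change
exactly one line. The Golbraikh–Tropsha battery computes
$q^2_{ext}$ (denominator centered on the *training* mean),
through-origin slopes $k = \sum y\tilde y / \sum \tilde y^2$ and
$k' = \sum y\tilde y / \sum y^2$, and the through-origin determination
coefficients with denominators centered on the mean of the first-listed
vector ($R_0^2$ on predictions, $R_0'^2$ on observations) — variants of
these formulas circulate, and this is the convention the printed values
of the source model family anchor. $R^2$ in the relative differences is
the test-set squared correlation.

## The synthetic compound table

`generate_dataset()` emulates the shape of the 274-compound table:
$\cos^2$-transformed A log P uniform on $[0,1]$, X3v uniform on
$[0,8]$, Neoplastic-80 Bernoulli(0.5), and
$\log K_p$ = full-set-equation value + Gaussian noise, sd 0.3 by
default. The sizes and descriptor ranges mirror the real table's stated
conditions; the Bernoulli probability is unreported anywhere and 0.5 was
fixed once as the maximally uninformative choice. Descriptors are
sampled *independently*, which real compounds do not obey (hydrophobic
compounds tend to be larger); the generated table is therefore adequate
for coefficient recovery, split determinism and pipeline wiring tests,
and for checking that the fitted $R^2$ matches its analytic expectation
$\mathrm{var(signal)}/(\mathrm{var(signal)} + \sigma^2)$, but passing
those tests says nothing about predictive accuracy on measured
permeability data — reproducing the published headline statistics
requires the original measured table, which the package does not
redistribute.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: single-atom molecules give a
one-vertex graph with $\delta = 0$; empty path sets give index 0;
all-identical rows split by lowest index; zero-variance observations
make $R^2$ an error rather than NaN; charged species, organometallics
and unparsable SMILES raise structured errors naming the input. The test
suite sizes were chosen to keep every oracle exact and fast: QP-oracle
instances at $n \le 25$, Kennard–Stone oracles at $n \le 50$, OLS
oracles at $n \le 50, p \le 5$, 50 seeds for the Monte-Carlo $R^2$
check, and full-size ($n = 274$) synthetic tables for the
pipeline-level statistics including 139 leave-one-out SVR refits.

## Known limitations

- A log P/MR use the Wildman–Crippen constants as implemented by Open
  Babel, not the original Ghose–Crippen–Viswanadhan table of the frozen
  equations' provenance; for compounds far from the parameterization
  both schemes drift, and descriptor values tabulated by other software
  can differ in the second decimal.
- The functional-group SMARTS set for Neoplastic-80 is documented and
  tested but not guaranteed identical to the pattern set of commercial
  descriptor software.
- The Kennard–Stone feature space is a package choice; a different
  space yields a different (equally deterministic) split.
- Stereochemistry is ignored throughout (all descriptors are
  2D/topological).
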