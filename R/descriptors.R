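#' Atom-contribution table for logP and molar refractivity
#'
#' The hydrophobicity and molar-refractivity atom contributions used by
#' \code{\link{alogp}} and \code{\link{molar_refractivity}}. The default
#' table delegates atom typing and summation to Open Babel's implementation
#' of the Wildman-Crippen atom-contribution scheme (the published successor
#' of the Ghose-Crippen-Viswanadhan constants), with provenance recorded in
#' the object. Alternatively, a custom element-level table can be supplied
#' as a data frame with columns \code{element}, \code{hydrophobicity} and
#' \code{refractivity}; every atom (including hydrogen, when present) is
#' then typed by its element symbol alone. Element-level typing is coarser
#' than the published atom typing and is intended for testing additivity
#' and error handling, not for production descriptor values.
#'
#' @param entries Optional custom contribution data frame as described
#'   above. \code{NULL} (default) selects the Open Babel table.
#' @return An object of class \code{"alogp_table"}.
#' @export
alogp_table <- function(entries = NULL) {
  if (is.null(entries)) {
    out <- list(scheme = "openbabel",
                provenance = paste("Wildman & Crippen (1999) atom-contribution",
                                   "logP/MR as implemented by Open Babel"))
  } else {
    stopifnot(is.data.frame(entries),
              all(c("element", "hydrophobicity", "refractivity") %in%
                    names(entries)))
    if (anyDuplicated(entries$element)) {
      stop("duplicate element entries in contribution table", call. = FALSE)
    }
    out <- list(scheme = "custom", entries = entries,
                provenance = "user-supplied element-level table")
  }
  class(out) <- "alogp_table"
  out
}

#' @export
print.alogp_table <- function(x, ...) {
  cat(sprintf("<alogp_table> scheme: %s\n  %s\n", x$scheme, x$provenance))
  invisible(x)
}

.sum_contributions <- function(mol, table, column) {
  if (table$scheme == "openbabel") {
    p <- .mol_props(mol)
    return(as.numeric(p[[if (column == "hydrophobicity") "logP" else "MR"]]))
  }
  # explicit per-atom loop so errors can name the offending atom
  total <- 0
  for (a in seq_len(nrow(mol$atoms))) {
    el <- mol$atoms$element[a]
    row <- match(el, table$entries$element)
    if (is.na(row)) {
      stop(sprintf("atom %d (%s) has no entry in the contribution table",
                   a, el), call. = FALSE)
    }
    total <- total + table$entries[[column]][row]
    if (mol$atoms$nh[a] > 0L) {
      total <- total + mol$atoms$nh[a] * .h_contribution(table, column, a, el)
    }
  }
  total
}

.h_contribution <- function(table, column, atom, element) {
  row <- match("H", table$entries$element)
  if (is.na(row)) {
    stop(sprintf("hydrogens attached to atom %d (%s) have no 'H' entry in the contribution table",
                 atom, element), call. = FALSE)
  }
  table$entries[[column]][row]
}

#' Atom-contribution octanol-water partition coefficient (A log P)
#'
#' Sum over all atoms (hydrogens included) of their hydrophobicity
#' contributions.
#'
#' @param mol A \code{"molecule"}.
#' @param table An \code{\link{alogp_table}}.
#' @return The estimated log P (dimensionless).
#' @export
alogp <- function(mol, table = alogp_table()) {
  stopifnot(inherits(mol, "molecule"), inherits(table, "alogp_table"))
  .sum_contributions(mol, table, "hydrophobicity")
}

#' Atom-contribution molar refractivity
#'
#' @inheritParams alogp
#' @return Molar refractivity in cm^3/mol.
#' @export
molar_refractivity <- function(mol, table = alogp_table()) {
  stopifnot(inherits(mol, "molecule"), inherits(table, "alogp_table"))
  .sum_contributions(mol, table, "refractivity")
}

#' Cosine-squared transform of A log P
#'
#' The permeability models use \eqn{\cos^2[(4.31 + A\log P)/8.66]} (argument
#' in radians) in place of raw A log P. Over the log P range of typical
#' permeants (about -4.3 to 4.4) the radian argument spans about 0 to 1, so
#' the transform is a smooth monotone rescaling into [0, 1].
#'
#' @param alogp_value Numeric vector of A log P values.
#' @return Values in [0, 1].
#' @export
cos2_transform <- function(alogp_value) {
  cos((4.31 + alogp_value) / 8.66)^2
}

#' Functional-group SMARTS patterns for the Neoplastic-80 gate
#'
#' The qualifying functional groups of the antineoplastic drug-likeness
#' indicator, as SMARTS substructure patterns matched by Open Babel. A
#' molecule qualifies when at least one pattern matches.
#'
#' @return Named character vector of SMARTS patterns.
#' @export
neoplastic_groups <- function() {
  c(benzene_ring       = "c1ccccc1",
    heterocyclic_ring  = "[!#6;!#1;R]",
    aliphatic_amine    = "[NX3;!$([NX3]C=O);!$([NX3]a);!$([NX3][!#6;!#1])]",
    carboxamide        = "[CX3](=O)[NX3]",
    alcoholic_hydroxyl = "[OX2H][CX4]",
    carboxy_ester      = "[CX3](=O)[OX2][#6]",
    keto_group         = "[#6][CX3](=O)[#6]")
}

#' Does a molecule carry a Neoplastic-80 qualifying functional group?
#'
#' @param mol A \code{"molecule"}.
#' @return Logical scalar.
#' @export
has_qualifying_group <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sdfset <- .molblock_sdfset(mol$molblock)
  for (pat in neoplastic_groups()) {
    hits <- ChemmineR::smartsSearchOB(sdfset, pat, uniqueMatches = FALSE)
    if (hits[1] > 0) return(TRUE)
  }
  FALSE
}

#' Antineoplastic drug-likeness indicator (Neoplastic-80)
#'
#' Equals 1 when the molecule carries at least one qualifying functional
#' group (benzene ring, heterocyclic ring, aliphatic amine, carboxamide,
#' alcoholic hydroxyl, carboxy ester or keto group) and all four bulk
#' properties fall in the 80 percent drug-coverage ranges: A log P in
#' [-1.5, 4.7], molar refractivity in [43, 128] cm^3/mol, molecular weight
#' in [180, 470] g/mol and total atom count (hydrogens included) in
#' [21, 63]. Otherwise 0. All interval bounds are inclusive.
#'
#' @param mol A \code{"molecule"}.
#' @param alogp A log P of the same molecule.
#' @param mr Molar refractivity.
#' @param mw Molecular weight (g/mol).
#' @param n_atoms Total atom count, hydrogens included.
#' @return 0 or 1.
#' @export
neoplastic80 <- function(mol, alogp, mr, mw, n_atoms) {
  in_range <- alogp >= -1.5 && alogp <= 4.7 &&
    mr >= 43 && mr <= 128 &&
    mw >= 180 && mw <= 470 &&
    n_atoms >= 21 && n_atoms <= 63
  as.integer(in_range && has_qualifying_group(mol))
}

#' Full descriptor vector for one compound
#'
#' Parses a SMILES string and computes every quantity the permeability
#' models need: A log P and its cosine-squared transform, the third-order
#' valence connectivity index X3v, the Neoplastic-80 indicator, and the
#' supporting molecular weight, molar refractivity and total atom count.
#'
#' @param smiles A single SMILES string.
#' @param table An \code{\link{alogp_table}}.
#' @return An object of class \code{"descriptor_vector"}: named list with
#'   \code{alogp}, \code{cos2_alogp}, \code{x3v}, \code{neoplastic80},
#'   \code{mw}, \code{molar_refractivity}, \code{n_atoms_total},
#'   \code{smiles}, \code{cansmi}.
#' @export
descriptor_vector <- function(smiles, table = alogp_table()) {
  mol <- if (inherits(smiles, "molecule")) smiles else parse_smiles(smiles)
  g <- heavy_graph(mol)
  lp <- alogp(mol, table)
  mr <- molar_refractivity(mol, table)
  mw <- as.numeric(.mol_props(mol)[["MW"]])
  n_atoms <- nrow(mol$atoms) + sum(mol$atoms$nh)
  out <- list(alogp = lp,
              cos2_alogp = cos2_transform(lp),
              x3v = connectivity_index(g, 3L, valence = TRUE),
              neoplastic80 = neoplastic80(mol, lp, mr, mw, n_atoms),
              mw = mw,
              molar_refractivity = mr,
              n_atoms_total = n_atoms,
              smiles = mol$smiles,
              cansmi = mol$cansmi)
  class(out) <- "descriptor_vector"
  out
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat(sprintf("<descriptors> %s\n", x$smiles))
  cat(sprintf("  AlogP %.4f  cos2 %.4f  X3v %.4f  Neo80 %d\n",
              x$alogp, x$cos2_alogp, x$x3v, x$neoplastic80))
  cat(sprintf("  MW %.2f  MR %.2f  atoms %d\n",
              x$mw, x$molar_refractivity, x$n_atoms_total))
  invisible(x)
}

#' Descriptor table for a vector of SMILES
#'
#' @param smiles Character vector of SMILES strings.
#' @param id Optional compound identifiers (defaults to the SMILES).
#' @param table An \code{\link{alogp_table}}.
#' @return Data frame with one row per compound: \code{id}, \code{smiles},
#'   \code{alogp}, \code{cos2_alogp}, \code{x3v}, \code{neoplastic80},
#'   \code{mw}, \code{mr}, \code{n_atoms}.
#' @export
descriptor_table <- function(smiles, id = NULL, table = alogp_table()) {
  if (is.null(id)) id <- smiles
  stopifnot(length(id) == length(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    d <- descriptor_vector(smiles[i], table)
    data.frame(id = id[i], smiles = smiles[i], alogp = d$alogp,
               cos2_alogp = d$cos2_alogp, x3v = d$x3v,
               neoplastic80 = d$neoplastic80, mw = d$mw,
               mr = d$molar_refractivity, n_atoms = d$n_atoms_total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
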