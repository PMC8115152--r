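#' Configuration for the synthetic compound-table generator
#'
#' The generator emulates the shape of the 274-compound permeability
#' table: independent descriptor triples (cosine-squared A log P transform
#' uniform on [0, 1], X3v uniform on [0, 8], Neoplastic-80 Bernoulli) with
#' log Kp produced by a frozen published equation (the three-descriptor
#' full-set model by default) plus Gaussian noise. Descriptors are sampled
#' independently, which real compounds do not obey; the generated table is
#' adequate for coefficient-recovery and pipeline tests, not a substitute
#' for measured data.
#'
#' @param n Number of compounds (>= 10; default 274).
#' @param noise_sd Gaussian noise standard deviation in log Kp units
#'   (default 0.3).
#' @param cos2_range,x3v_range Uniform sampling intervals.
#' @param neo_prob Bernoulli probability of Neoplastic-80 = 1.
#' @param equation Generating published equation id (default "eq13").
#' @param seed Integer seed.
#' @return A \code{"synth_config"} list.
#' @export
synth_config <- function(n = 274L, noise_sd = 0.3, cos2_range = c(0, 1),
                         x3v_range = c(0, 8), neo_prob = 0.5,
                         equation = "eq13", seed = 1L) {
  stopifnot(n >= 10L, noise_sd >= 0, diff(cos2_range) >= 0,
            diff(x3v_range) >= 0, neo_prob >= 0, neo_prob <= 1)
  if (!equation %in% names(published_equations())) {
    stop(sprintf("unknown generating equation '%s'", equation), call. = FALSE)
  }
  structure(list(n = as.integer(n), noise_sd = noise_sd,
                 cos2_range = cos2_range, x3v_range = x3v_range,
                 neo_prob = neo_prob, equation = equation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic compound table
#'
#' @param config A \code{\link{synth_config}}.
#' @return A \code{\link{qsar_dataset}} with tabulated descriptors,
#'   synthetic ids and no SMILES.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    n <- config$n
    d <- data.frame(
      id = sprintf("synth_%03d", seq_len(n)),
      smiles = NA_character_,
      cos2_alogp = runif(n, config$cos2_range[1], config$cos2_range[2]),
      x3v = runif(n, config$x3v_range[1], config$x3v_range[2]),
      neoplastic80 = as.integer(runif(n) < config$neo_prob))
    d$logkp <- predict_published(config$equation, d) +
      rnorm(n, 0, config$noise_sd)
    qsar_dataset(d, descriptor_source = "tabulated")
  })
}

#' Curated micro-set of molecules with hand-derived descriptor facts
#'
#' Small molecules whose third-order valence connectivity index and
#' Neoplastic-80 outcome are known by hand (path enumeration on the
#' H-depleted graph and direct application of the gate rules). X3v values
#' marked \code{NA} are not hand-derivable in a line or two and are left
#' to the path-enumeration oracle.
#'
#' For n-butane the single 4-vertex path has valence degrees (1, 2, 2, 1),
#' giving X3v = 1/sqrt(4) = 0.5; n-pentane has two such paths each with
#' degree product 8, giving 2/sqrt(8); benzene has six ring paths with
#' degree product 81. Propane, isobutane, ethanol and methane have no
#' 4-vertex path at all.
#'
#' @return Data frame with columns \code{name}, \code{smiles},
#'   \code{x3v} (expected; NA when not hand-derived),
#'   \code{neoplastic80} (expected), \code{n_heavy}.
#' @export
fixture_molecules <- function() {
  data.frame(
    name = c("methane", "ethanol", "propane", "isobutane", "n-butane",
             "n-pentane", "benzene", "caffeine"),
    smiles = c("C", "CCO", "CCC", "CC(C)C", "CCCC",
               "CCCCC", "c1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C"),
    x3v = c(0, 0, 0, 0, 0.5, 2 / sqrt(8), 6 / 9, NA),
    neoplastic80 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    n_heavy = c(1L, 3L, 3L, 4L, 4L, 5L, 6L, 14L))
}
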