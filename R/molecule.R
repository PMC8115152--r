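#' @importFrom stats coef cor lm pf predict pt quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# Elements accepted in neutral organic structures; anything else (metals,
# counterions) is rejected up front.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Br", "I")

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# Valence-electron counts used by the Kier-Hall valence vertex degree.
.VALENCE_ELECTRONS <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4,
                        P = 5, S = 6, Cl = 7, Br = 7, I = 7)

#' Parse a SMILES string into a molecule
#'
#' Converts a SMILES string into a chemical structure using Open Babel
#' (through \pkg{ChemmineOB}), with aromaticity perceived and implicit
#' hydrogens resolved. The returned object records, for every heavy atom,
#' its element, formal charge and attached-hydrogen count, together with
#' the bond list (aromatic systems are stored in their kekulized form) and
#' the canonical SMILES of the structure.
#'
#' Only neutral organic molecules are accepted: structures containing
#' formal charges, counterions or elements outside H, B, C, N, O, F, Si,
#' P, S, Cl, Br, I are rejected with an error.
#'
#' @param smiles A single SMILES string.
#' @return An object of class \code{"molecule"}: a list with components
#'   \code{atoms} (data frame: \code{element}, \code{charge}, \code{nh}),
#'   \code{bonds} (data frame: \code{i}, \code{j}, \code{order}),
#'   \code{smiles}, \code{cansmi} and \code{molblock} (the explicit-hydrogen
#'   MDL molblock used for downstream property and substructure queries).
#' @examples
#' \dontrun{
#' mol <- parse_smiles("CCO")
#' mol$atoms
#' }
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("parse error: SMILES input must be a single non-empty string",
         call. = FALSE)
  }
  smiles <- trimws(smiles)
  molblock <- .smiles_to_molblock(smiles)
  sdf <- .read_single_sdf(molblock)

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_[0-9]+$", "", rownames(ab))
  unknown <- setdiff(unique(elements), .ORGANIC_ELEMENTS)
  if (length(unknown) > 0L) {
    stop(sprintf("unsupported element(s) %s in '%s': only neutral organic molecules are handled",
                 paste(unknown, collapse = ", "), smiles), call. = FALSE)
  }
  if (any(grepl("^M  (CHG|RAD)", strsplit(molblock, "\n")[[1]]))) {
    stop(sprintf("charged or radical species '%s' rejected: only neutral organics are handled",
                 smiles), call. = FALSE)
  }

  n_atoms <- length(elements)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0L))
  bonds_all <- if (nrow(bb) > 0L) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }

  heavy <- which(elements != "H")
  nh <- integer(length(heavy))
  names(nh) <- as.character(heavy)
  for (r in seq_len(nrow(bonds_all))) {
    i <- bonds_all$i[r]; j <- bonds_all$j[r]
    if (elements[i] == "H" && elements[j] != "H") {
      nh[as.character(j)] <- nh[as.character(j)] + 1L
    } else if (elements[j] == "H" && elements[i] != "H") {
      nh[as.character(i)] <- nh[as.character(i)] + 1L
    }
  }

  remap <- integer(n_atoms)
  remap[heavy] <- seq_along(heavy)
  keep <- bonds_all$i %in% heavy & bonds_all$j %in% heavy
  bonds <- bonds_all[keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]
  bonds$j <- remap[bonds$j]
  rownames(bonds) <- NULL

  atoms <- data.frame(element = elements[heavy],
                      charge = 0L,
                      nh = as.integer(nh))
  props <- ChemmineR::propOB(.molblock_sdfset(molblock))[1, ]
  out <- list(atoms = atoms,
              bonds = bonds,
              smiles = smiles,
              cansmi = trimws(props[["cansmiNS"]]),
              molblock = molblock,
              .props = props)
  class(out) <- "molecule"
  out
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s\n", x$smiles))
  cat(sprintf("  canonical: %s\n", x$cansmi))
  cat(sprintf("  %d heavy atoms, %d bonds, %d hydrogens\n",
              nrow(x$atoms), nrow(x$bonds), sum(x$atoms$nh)))
  invisible(x)
}

#' Canonical SMILES of a parsed molecule or SMILES string
#'
#' @param x A \code{"molecule"} object or a SMILES string.
#' @return The Open Babel canonical SMILES (no name field).
#' @export
canonical_smiles <- function(x) {
  if (inherits(x, "molecule")) return(x$cansmi)
  parse_smiles(x)$cansmi
}

# SMILES -> explicit-hydrogen V2000 molblock via Open Babel.
.smiles_to_molblock <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " mol\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))),
    error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) {
    stop(sprintf("parse error: SMILES '%s' could not be interpreted", smiles),
         call. = FALSE)
  }
  out
}

.read_single_sdf <- function(molblock) {
  .molblock_sdfset(molblock)[[1]]
}

.molblock_sdfset <- function(molblock) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(molblock, tf)
  ChemmineR::read.SDFset(tf)
}

# Open Babel properties (logP, MR, MW, canonical SMILES ...) for a molecule.
.mol_props <- function(mol) {
  if (is.null(mol$.props)) {
    ChemmineR::propOB(.molblock_sdfset(mol$molblock))[1, ]
  } else {
    mol$.props
  }
}

#' @useDynLib skinperm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
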