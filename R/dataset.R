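#' Construct a QSAR dataset
#'
#' A \code{qsar_dataset} is a validated data frame of compound records with
#' columns \code{id}, \code{smiles}, \code{logkp} (log10 of the skin
#' permeability coefficient in cm/h), an optional \code{name}, an optional
#' \code{split} label (\code{"train"}, \code{"test"} or
#' \code{"unassigned"}) and optional tabulated descriptor columns
#' \code{cos2_alogp}, \code{x3v}, \code{neoplastic80}.
#'
#' @param df Data frame of records.
#' @param descriptor_source \code{"tabulated"} when descriptor columns are
#'   taken as given, \code{"computed"} when they were derived from the
#'   SMILES by this package.
#' @return The validated data frame with class \code{"qsar_dataset"}.
#' @export
qsar_dataset <- function(df, descriptor_source = c("tabulated", "computed")) {
  descriptor_source <- match.arg(descriptor_source)
  required <- c("id", "smiles", "logkp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("dataset is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(df$logkp)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$logkp)))))
    stop(sprintf("non-numeric logkp value(s) at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(df$logkp) || any(!is.finite(df$logkp))) {
    bad <- which(!is.finite(df$logkp))
    stop(sprintf("non-finite logkp at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    dup <- df$id[duplicated(df$id)][1L]
    stop(sprintf("duplicate id '%s' (row %d)", dup,
                 which(df$id == dup)[2L]), call. = FALSE)
  }
  if (!"split" %in% names(df)) df$split <- "unassigned"
  df$split[is.na(df$split) | df$split == ""] <- "unassigned"
  bad_split <- setdiff(unique(df$split), c("train", "test", "unassigned"))
  if (length(bad_split) > 0L) {
    stop(sprintf("invalid split label(s): %s",
                 paste(bad_split, collapse = ", ")), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$smiles <- as.character(df$smiles)
  rownames(df) <- NULL
  structure(df, class = c("qsar_dataset", "data.frame"),
            descriptor_source = descriptor_source)
}

#' Read a compound table from CSV
#'
#' Expects a UTF-8 comma-separated file with a header row and at least the
#' columns \code{id}, \code{smiles}, \code{logkp}. When the descriptor
#' columns \code{cos2_alogp}, \code{x3v} and \code{neoplastic80} are all
#' present the dataset is flagged as carrying tabulated descriptors.
#'
#' @param path CSV file path.
#' @return A \code{\link{qsar_dataset}}.
#' @export
read_qsar_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  src <- if (all(c("cos2_alogp", "x3v", "neoplastic80") %in% names(df)))
    "tabulated" else "computed"
  qsar_dataset(df, descriptor_source = src)
}

#' Write a compound table to CSV
#'
#' @param ds A \code{\link{qsar_dataset}}.
#' @param path Output CSV path.
#' @export
write_qsar_table <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %d compounds (%s descriptors)\n", nrow(x),
              attr(x, "descriptor_source")))
  cat(sprintf("  split: %d train / %d test / %d unassigned\n",
              sum(x$split == "train"), sum(x$split == "test"),
              sum(x$split == "unassigned")))
  cat(sprintf("  logkp range: [%.2f, %.2f]\n", min(x$logkp), max(x$logkp)))
  invisible(x)
}

#' Remove duplicate structures from a dataset
#'
#' Compounds are compared by Open Babel canonical SMILES; the first
#' occurrence of each structure is kept. When two duplicates disagree in
#' their measured log Kp by more than 0.01 log units a warning lists both
#' records.
#'
#' @param ds A \code{\link{qsar_dataset}}.
#' @return The deduplicated dataset; removed ids are available in the
#'   \code{"removed_ids"} attribute.
#' @export
deduplicate <- function(ds) {
  stopifnot(inherits(ds, "qsar_dataset"))
  cansmi <- vapply(ds$smiles, function(s) parse_smiles(s)$cansmi, character(1))
  keep <- !duplicated(cansmi)
  for (dup_row in which(!keep)) {
    first_row <- which(cansmi == cansmi[dup_row])[1L]
    if (abs(ds$logkp[dup_row] - ds$logkp[first_row]) > 0.01) {
      warning(sprintf(
        "duplicate structure with conflicting logkp: '%s' (%.3f) vs '%s' (%.3f)",
        ds$id[first_row], ds$logkp[first_row],
        ds$id[dup_row], ds$logkp[dup_row]), call. = FALSE)
    }
  }
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  res <- qsar_dataset(as.data.frame(out),
                      descriptor_source = attr(ds, "descriptor_source"))
  attr(res, "removed_ids") <- ds$id[!keep]
  res
}

#' Pre-filter a descriptor matrix
#'
#' Removes constant columns, then scans the remaining columns in order and
#' drops any column whose absolute Pearson correlation with an
#' already-kept column exceeds \code{r_max}.
#'
#' @param x Numeric matrix (compounds in rows, descriptors in columns).
#' @param r_max Correlation threshold (default 0.90).
#' @return Integer vector of kept column indices.
#' @export
prefilter_descriptors <- function(x, r_max = 0.90) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L)
  variable <- which(apply(x, 2L, function(col) stats::sd(col) > 0))
  kept <- integer(0)
  for (j in variable) {
    if (length(kept) == 0L) {
      kept <- j
    } else {
      r <- abs(suppressWarnings(stats::cor(x[, kept, drop = FALSE], x[, j])))
      if (all(r <= r_max)) kept <- c(kept, j)
    }
  }
  kept
}

#' Kennard-Stone train/test split
#'
#' Deterministic max-min selection of a representative training subset.
#' The two points with the largest Euclidean distance seed the training
#' set; thereafter the candidate whose minimum distance to the selected
#' points is largest is added, until \code{n_train} points are selected.
#' All ties are broken by lowest row index, so the split is reproducible
#' across runs and platforms.
#'
#' @param x Numeric matrix of descriptor coordinates (standardize the
#'   columns first if they are on different scales; see
#'   \code{\link{split_dataset}}).
#' @param n_train Number of training points, between 2 and
#'   \code{nrow(x) - 1}.
#' @return An object of class \code{"ks_split"}: list with integer vectors
#'   \code{train}, \code{test} and \code{selection_order}.
#' @export
kennard_stone_split <- function(x, n_train) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n_train >= 2L, n_train < n)
  d <- as.matrix(stats::dist(x))
  # seed pair: largest distance, ties by lexicographically smallest (i, j)
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] > best_d + 1e-12) { best_d <- d[i, j]; best <- c(i, j) }
    }
  }
  selected <- best
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_train) {
    min_d <- apply(d[remaining, selected, drop = FALSE], 1L, min)
    pick <- remaining[which.max(min_d)]  # which.max: first max, lowest index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(train = sort(selected), test = sort(remaining),
                 selection_order = selected),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d train / %d test\n", length(x$train),
              length(x$test)))
  invisible(x)
}

#' Assign Kennard-Stone split labels to a dataset
#'
#' Standardizes the model descriptors (\code{cos2_alogp}, \code{x3v},
#' \code{neoplastic80} by default) to zero mean and unit variance, runs
#' \code{\link{kennard_stone_split}} in that space, and writes
#' \code{"train"}/\code{"test"} labels into the \code{split} column.
#'
#' @param ds A \code{\link{qsar_dataset}} carrying descriptor columns.
#' @param n_train Training-set size (default: the published proportion,
#'   139 of 274, rounded).
#' @param columns Descriptor columns defining the distance space.
#' @return The dataset with filled \code{split}; the \code{"ks_split"}
#'   object is attached as attribute \code{"split_result"}.
#' @export
split_dataset <- function(ds, n_train = round(nrow(ds) * 139 / 274),
                          columns = c("cos2_alogp", "x3v", "neoplastic80")) {
  stopifnot(inherits(ds, "qsar_dataset"))
  missing_cols <- setdiff(columns, names(ds))
  if (length(missing_cols) > 0L) {
    stop(sprintf("descriptor column(s) absent: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x <- scale(as.matrix(as.data.frame(ds)[, columns, drop = FALSE]))
  x[, apply(x, 2L, function(col) anyNA(col))] <- 0  # constant columns
  ks <- kennard_stone_split(x, n_train)
  ds$split <- "test"
  ds$split[ks$train] <- "train"
  attr(ds, "split_result") <- ks
  ds
}
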