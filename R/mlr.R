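#' Ordinary least squares with QSAR diagnostics
#'
#' Fits a multiple linear regression of an activity on a descriptor matrix
#' and assembles the diagnostics conventionally reported for QSAR models:
#' per-coefficient standard errors, t statistics, two-sided P values and
#' variance inflation factors, plus n, R, R-squared, adjusted R-squared,
#' the standard error of the estimate and the F ratio.
#'
#' @param x Numeric matrix or data frame of descriptors (n rows, p
#'   columns); column names become coefficient names.
#' @param y Numeric response of length n.
#' @return An object of class \code{"qsar_mlr"} with components
#'   \code{coefficients} (intercept first), \code{coef_table} (data frame
#'   with estimate, se, t, p, vif), \code{n}, \code{p}, \code{r},
#'   \code{r2}, \code{r2_adj}, \code{se}, \code{F}, \code{fitted},
#'   \code{residuals} and the underlying \code{lm} fit.
#' @seealso \code{\link{stepwise_select}}, \code{\link{predict_published}}
#' @export
ols_fit <- function(x, y) {
  x <- as.data.frame(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0("x", seq_along(x))
  }
  names(x) <- make.names(names(x), unique = TRUE)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n)
  if (n <= p + 1L) {
    stop(sprintf("need n > p + 1 observations (n = %d, p = %d)", n, p),
         call. = FALSE)
  }
  dat <- cbind(x, .y = y)
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(sprintf("rank-deficient descriptor matrix; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  vif <- rep(NA_real_, p)
  if (p >= 2L) {
    for (j in seq_len(p)) {
      r2j <- summary(lm(stats::as.formula(paste0("`", names(x)[j], "` ~ .")),
                        data = x))$r.squared
      vif[j] <- 1 / (1 - r2j)
    }
  } else {
    vif <- 1
  }
  r2 <- sm$r.squared
  coef_table <- data.frame(term = rownames(ct), estimate = ct[, 1],
                           se = ct[, 2], t = ct[, 3], p = ct[, 4],
                           vif = c(NA_real_, vif), row.names = NULL)
  out <- list(coefficients = coef(fit),
              coef_table = coef_table,
              n = n, p = p,
              r = sqrt(r2), r2 = r2, r2_adj = sm$adj.r.squared,
              se = sm$sigma,
              F = unname(sm$fstatistic["value"]),
              fitted = unname(fitted(fit)),
              residuals = unname(stats::residuals(fit)),
              lm = fit,
              call = match.call())
  class(out) <- "qsar_mlr"
  out
}

#' Fit a permeability regression by formula
#'
#' Formula front end to \code{\link{ols_fit}}.
#'
#' @param formula Model formula, e.g.
#'   \code{logkp ~ cos2_alogp + x3v + neoplastic80}.
#' @param data Data frame (typically a \code{\link{qsar_dataset}}).
#' @return A \code{"qsar_mlr"} fit.
#' @export
qsar_mlr <- function(formula, data) {
  mf <- stats::model.frame(formula, as.data.frame(data))
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  out <- ols_fit(x, y)
  out$call <- match.call()
  out
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("Skin-permeability MLR model\n")
  cat("log Kp =", format(round(x$coefficients[1], 3)))
  for (nm in names(x$coefficients)[-1]) {
    b <- x$coefficients[nm]
    cat(sprintf(" %s %s %s", ifelse(b < 0, "-", "+"),
                format(abs(round(b, 3))), nm))
  }
  cat("\n")
  cat(sprintf("n = %d, R = %.3f, R2 = %.3f, R2adj = %.3f, se = %.3f, F = %.3f\n",
              x$n, x$r, x$r2, x$r2_adj, x$se, x$F))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  ct <- object$coef_table
  ct$estimate <- round(ct$estimate, 4)
  ct$se <- round(ct$se, 4)
  ct$t <- round(ct$t, 3)
  ct$p <- signif(ct$p, 3)
  ct$vif <- round(ct$vif, 3)
  print(ct, row.names = FALSE)
  invisible(object)
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.data.frame(newdata)
  terms <- names(object$coefficients)[-1]
  missing_cols <- setdiff(terms, names(newdata))
  if (length(missing_cols) > 0L) {
    stop(sprintf("newdata lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(newdata[, terms, drop = FALSE])
  unname(drop(object$coefficients[1] + m %*% object$coefficients[-1]))
}

#' Stepwise descriptor selection by partial-F significance
#'
#' Classical forward-entry/backward-removal stepwise regression on
#' coefficient P values (equivalent to partial-F tests for single-column
#' steps): at each round the excluded descriptor with the smallest entry P
#' value below \code{p_enter} is added, then any included descriptor whose
#' P value exceeds \code{p_remove} is removed (largest first). With
#' \code{p_enter < p_remove} the procedure terminates; it is deterministic
#' given the column order. Candidate columns that would make the model
#' rank-deficient are skipped.
#'
#' @param x Descriptor matrix or data frame.
#' @param y Response vector.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return List with \code{selected} (column names in order of entry) and
#'   \code{fit} (the final \code{"qsar_mlr"}, or \code{NULL} when nothing
#'   enters).
#' @export
stepwise_select <- function(x, y, p_enter = 0.05, p_remove = 0.10) {
  stopifnot(p_enter < p_remove)
  x <- as.data.frame(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- paste0("x", seq_along(x))
  }
  names(x) <- make.names(names(x), unique = TRUE)
  selected <- character(0)
  repeat {
    changed <- FALSE
    candidates <- setdiff(names(x), selected)
    if (length(candidates) > 0L) {
      entry_p <- vapply(candidates, function(cand) {
        cols <- c(selected, cand)
        fit <- tryCatch(ols_fit(x[, cols, drop = FALSE], y),
                        error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        fit$coef_table$p[fit$coef_table$term == make.names(cand)][1]
      }, numeric(1))
      entry_p <- entry_p[!is.na(entry_p)]
      if (length(entry_p) > 0L && min(entry_p) < p_enter) {
        selected <- c(selected, names(which.min(entry_p)))
        changed <- TRUE
      }
    }
    while (length(selected) > 0L) {
      fit <- ols_fit(x[, selected, drop = FALSE], y)
      pv <- fit$coef_table$p[-1]
      names(pv) <- selected
      if (max(pv) > p_remove) {
        selected <- setdiff(selected, names(which.max(pv)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- if (length(selected) > 0L) ols_fit(x[, selected, drop = FALSE], y)
         else NULL
  list(selected = selected, fit = fit)
}

#' The published fitted equations
#'
#' The four multiple linear regression equations reported for the
#' 274-compound skin permeability dataset, frozen exactly as printed: a
#' one-descriptor model on the cosine-squared A log P transform, a
#' two-descriptor model adding X3v, the three-descriptor full-set model,
#' and the three-descriptor training-set (139 compounds) model. The full-
#' set and training-set models disagree on which of X3v and Neoplastic-80
#' carries the larger coefficient; both are preserved verbatim as printed,
#' without correction.
#'
#' @return Named list of equations; each has \code{id}, \code{intercept},
#'   \code{coefficients} (named vector over \code{cos2_alogp}, \code{x3v},
#'   \code{neoplastic80}) and the printed fit statistics.
#' @export
published_equations <- function() {
  list(
    eq10 = list(id = "eq10", intercept = 0.624,
                coefficients = c(cos2_alogp = -5.178),
                stats = c(n = 274, r = 0.695, r2 = 0.483, r2_adj = 0.481,
                          se = 0.713, F = 253.903)),
    eq12 = list(id = "eq12", intercept = 2.230,
                coefficients = c(cos2_alogp = -6.643, x3v = -0.245),
                stats = c(n = 274, r = 0.918, r2 = 0.844, r2_adj = 0.842,
                          se = 0.393, F = 731.089)),
    eq13 = list(id = "eq13", intercept = 2.209,
                coefficients = c(cos2_alogp = -6.698, x3v = -0.174,
                                 neoplastic80 = -0.704),
                stats = c(n = 274, r = 0.945, r2 = 0.893, r2_adj = 0.892,
                          se = 0.324, F = 756.879)),
    eq14 = list(id = "eq14", intercept = 2.068,
                coefficients = c(cos2_alogp = -6.515, x3v = -0.722,
                                 neoplastic80 = -0.168),
                stats = c(n = 139, r = 0.949, r2 = 0.901, r2_adj = 0.899,
                          se = 0.349, F = 410.148)))
}

#' Predict log Kp from a frozen published equation
#'
#' @param eq_id One of \code{"eq10"}, \code{"eq12"}, \code{"eq13"},
#'   \code{"eq14"}.
#' @param descriptors Data frame (or named list/vector) carrying the
#'   descriptor columns the equation needs.
#' @return Numeric vector of predicted log Kp (log10 cm/h).
#' @examples
#' predict_published("eq13",
#'   data.frame(cos2_alogp = 1, x3v = 0, neoplastic80 = 0))  # -4.489
#' @export
predict_published <- function(eq_id, descriptors) {
  eqs <- published_equations()
  if (!eq_id %in% names(eqs)) {
    stop(sprintf("unknown equation id '%s' (have: %s)", eq_id,
                 paste(names(eqs), collapse = ", ")), call. = FALSE)
  }
  eq <- eqs[[eq_id]]
  if (!is.data.frame(descriptors)) descriptors <- as.data.frame(as.list(descriptors))
  missing_cols <- setdiff(names(eq$coefficients), names(descriptors))
  if (length(missing_cols) > 0L) {
    stop(sprintf("descriptor(s) %s required by %s are absent",
                 paste(missing_cols, collapse = ", "), eq_id), call. = FALSE)
  }
  m <- as.matrix(descriptors[, names(eq$coefficients), drop = FALSE])
  unname(drop(eq$intercept + m %*% eq$coefficients))
}
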