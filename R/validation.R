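#' Root-mean-square error and squared correlation
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values of the same length.
#' @return List with \code{rms} (square root of the mean squared residual)
#'   and \code{r2} (squared Pearson correlation of observed and
#'   predicted).
#' @export
rms_r2 <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) > 0L)
  if (stats::sd(y_obs) == 0) {
    stop("observed values have zero variance; R2 is undefined",
         call. = FALSE)
  }
  list(rms = sqrt(mean((y_obs - y_pred)^2)),
       r2 = cor(y_obs, y_pred)^2)
}

#' Leave-one-out cross-validation
#'
#' Predicts each point from a model trained on the remaining n - 1 points
#' and reports the Pearson correlation between the LOO predictions and
#' the observations (the conventional internal validation statistic for
#' these models).
#'
#' @param trainer Function \code{(x, y) -> model}; the model must support
#'   \code{predict(model, newdata)}.
#' @param x Input matrix or data frame.
#' @param y Response vector.
#' @return List with \code{predictions} (length n) and \code{r}.
#' @export
loo_cv <- function(trainer, x, y) {
  x <- as.data.frame(x)
  n <- nrow(x)
  stopifnot(n >= 3L, length(y) == n)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    model <- tryCatch(trainer(x[-i, , drop = FALSE], y[-i]),
                      error = function(e) {
                        stop(sprintf("training failed with point %d left out: %s",
                                     i, conditionMessage(e)), call. = FALSE)
                      })
    preds[i] <- predict(model, x[i, , drop = FALSE])
  }
  list(predictions = preds, r = cor(y, preds))
}

#' k-fold cross-validation mean squared error
#'
#' Deterministic fold assignment derived from the seed; with \code{m = n}
#' this reduces to the leave-one-out mean squared error.
#'
#' @inheritParams loo_cv
#' @param m Number of folds, between 2 and n.
#' @param seed Integer seed for the fold assignment.
#' @return Mean over folds of the held-out mean squared error.
#' @export
kfold_cv <- function(trainer, x, y, m, seed = 1L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (m > n) stop(sprintf("m = %d folds exceed n = %d points", m, n),
                  call. = FALSE)
  folds <- .make_folds(n, m, seed)
  errs <- vapply(seq_len(m), function(f) {
    hold <- folds == f
    model <- trainer(x[!hold, , drop = FALSE], y[!hold])
    mean((y[hold] - predict(model, x[hold, , drop = FALSE]))^2)
  }, numeric(1))
  mean(errs)
}

#' Golbraikh-Tropsha external validation battery
#'
#' Computes the acceptability criteria for an externally validated QSAR
#' model: the external explained variance
#' \eqn{q^2_{ext} = 1 - \sum (y_i - \tilde y_i)^2 / \sum (y_i -
#' \bar y_{train})^2}, the through-origin regression slopes
#' \eqn{k = \sum y_i \tilde y_i / \sum \tilde y_i^2} and
#' \eqn{k' = \sum y_i \tilde y_i / \sum y_i^2}, the through-origin
#' determination coefficients \eqn{R_0^2} (predicted vs observed, with
#' \eqn{y_i^{r_0} = k \tilde y_i}) and \eqn{R_0'^2} (observed vs
#' predicted, with \eqn{\tilde y_i^{r_0} = k' y_i}), and the relative
#' differences \eqn{|R^2 - R_0^2| / R^2} and \eqn{|R^2 - R_0'^2| / R^2},
#' where \eqn{R^2} is the squared correlation of observed and predicted
#' test-set values. A model passes when \eqn{q^2_{ext} > 0.5}, both slopes
#' lie in (0.85, 1.15) and both relative differences are below 0.1.
#'
#' @param y_obs_test Observed test-set activities.
#' @param y_pred_test Predicted test-set activities.
#' @param y_train_mean Mean observed activity of the training set (centers
#'   the \eqn{q^2_{ext}} denominator).
#' @return An object of class \code{"gt_report"} with all quantities and
#'   logical pass flags (\code{pass_q2}, \code{pass_k}, \code{pass_kp},
#'   \code{pass_rel_diff}, \code{pass_rel_diff_prime}, \code{pass_all}),
#'   plus \code{rms} and \code{r2} of the test set.
#' @export
golbraikh_tropsha <- function(y_obs_test, y_pred_test, y_train_mean) {
  y <- y_obs_test; yp <- y_pred_test
  stopifnot(length(y) == length(yp), length(y) >= 3L)
  if (stats::sd(y) == 0 || stats::sd(yp) == 0) {
    stop("zero variance in observed or predicted values", call. = FALSE)
  }
  if (sum(yp^2) == 0 || sum(y^2) == 0) {
    stop("zero denominator in through-origin slope", call. = FALSE)
  }
  r2 <- cor(y, yp)^2
  q2_ext <- 1 - sum((y - yp)^2) / sum((y - y_train_mean)^2)
  k <- sum(y * yp) / sum(yp^2)
  kp <- sum(y * yp) / sum(y^2)
  y_r0 <- k * yp
  yp_r0 <- kp * y
  r0_sq <- 1 - sum((yp - y_r0)^2) / sum((yp - mean(yp))^2)
  r0p_sq <- 1 - sum((y - yp_r0)^2) / sum((y - mean(y))^2)
  rel_diff <- abs(r2 - r0_sq) / r2
  rel_diff_prime <- abs(r2 - r0p_sq) / r2
  out <- list(rms = sqrt(mean((y - yp)^2)), r2 = r2,
              q2_ext = q2_ext, k = k, k_prime = kp,
              r0_sq = r0_sq, r0_prime_sq = r0p_sq,
              rel_diff = rel_diff, rel_diff_prime = rel_diff_prime,
              pass_q2 = q2_ext > 0.5,
              pass_k = k > 0.85 && k < 1.15,
              pass_kp = kp > 0.85 && kp < 1.15,
              pass_rel_diff = rel_diff < 0.1,
              pass_rel_diff_prime = rel_diff_prime < 0.1)
  out$pass_all <- out$pass_q2 && out$pass_k && out$pass_kp &&
    out$pass_rel_diff && out$pass_rel_diff_prime
  class(out) <- "gt_report"
  out
}

#' @export
print.gt_report <- function(x, ...) {
  flag <- function(ok) ifelse(ok, "pass", "FAIL")
  cat("External validation (Golbraikh-Tropsha)\n")
  cat(sprintf("  test rms = %.3f, R2 = %.3f\n", x$rms, x$r2))
  cat(sprintf("  q2_ext = %.3f > 0.5            [%s]\n", x$q2_ext,
              flag(x$pass_q2)))
  cat(sprintf("  k      = %.3f in (0.85, 1.15)  [%s]\n", x$k, flag(x$pass_k)))
  cat(sprintf("  k'     = %.3f in (0.85, 1.15)  [%s]\n", x$k_prime,
              flag(x$pass_kp)))
  cat(sprintf("  |R2 - R0^2|/R2  = %.3f < 0.1   [%s] (R0^2  = %.3f)\n",
              x$rel_diff, flag(x$pass_rel_diff), x$r0_sq))
  cat(sprintf("  |R2 - R0'^2|/R2 = %.3f < 0.1   [%s] (R0'^2 = %.3f)\n",
              x$rel_diff_prime, flag(x$pass_rel_diff_prime), x$r0_prime_sq))
  cat(sprintf("  overall: %s\n", flag(x$pass_all)))
  invisible(x)
}
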