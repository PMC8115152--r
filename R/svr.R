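#' Gaussian radial basis function kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-\gamma \, ||x_i - x_j||^2)}.
#'
#' @param x_i,x_j Numeric vectors of equal length.
#' @param gamma Kernel width parameter, non-negative.
#' @return A number in (0, 1].
#' @export
rbf_kernel <- function(x_i, x_j, gamma) {
  stopifnot(length(x_i) == length(x_j), gamma >= 0)
  exp(-gamma * sum((x_i - x_j)^2))
}

# Full RBF Gram matrix between the rows of a and b.
.rbf_matrix <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train an epsilon-insensitive support vector regression
#'
#' Solves the epsilon-SVR dual problem with an RBF kernel: minimize
#' \eqn{\frac12 ||w||^2 + C \sum_i (\xi_i + \xi_i^*)} subject to the
#' epsilon-insensitive constraints, via its dual in the net coefficients
#' \eqn{\beta_i = a_i - a_i^*} with \eqn{\sum_i \beta_i = 0} and
#' \eqn{-C \le \beta_i \le C}. The solver is a maximal-violating-pair SMO:
#' each iteration picks the feasible ascent pair with the largest joint
#' KKT violation and solves the two-variable subproblem exactly (the
#' subproblem objective is piecewise quadratic because of the
#' epsilon-insensitive kink at zero; all region optima and breakpoints are
#' evaluated). The bias is the average of the KKT equalities over
#' unbounded support vectors, falling back to the midpoint of the feasible
#' interval when every coefficient is at a bound.
#'
#' Inputs are standardized to zero mean and unit variance internally; the
#' standardization is stored in the model, so prediction takes raw
#' coordinates. The response is not scaled (epsilon is in response units).
#'
#' @param x Numeric matrix of training inputs (n rows).
#' @param y Numeric response of length n.
#' @param C Box constraint (cost), > 0.
#' @param gamma RBF width, >= 0.
#' @param epsilon Half-width of the insensitive tube (default 0.001).
#' @param tol KKT violation tolerance for convergence (default 1e-6).
#' @param max_iter Iteration cap.
#' @return An object of class \code{"svr_model"}: \code{beta} (net dual
#'   coefficients), \code{b}, hyperparameters, the standardized training
#'   inputs with centering/scaling, fitted values and the dual objective.
#' @export
svr_fit <- function(x, y, C, gamma, epsilon = 0.001, tol = 1e-6,
                    max_iter = 50000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(n >= 2L, length(y) == n, C > 0, gamma >= 0, epsilon >= 0)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in training data", call. = FALSE)
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2L, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")

  K <- .rbf_matrix(xs, xs, gamma)
  sol <- .smo_solve(K, y, C, epsilon, tol, max_iter)

  fitted <- drop(K %*% sol$beta) + sol$b
  out <- list(beta = sol$beta, b = sol$b,
              C = C, gamma = gamma, epsilon = epsilon,
              x_train = xs, center = center, scale = scale_,
              y_train = y, fitted = fitted,
              support = which(abs(sol$beta) > 1e-8),
              dual_objective = sol$objective,
              iterations = sol$iterations,
              converged = sol$converged)
  class(out) <- "svr_model"
  out
}

# Maximal-violating-pair SMO on the net-coefficient dual (inner loop in
# compiled code, src/smo.cpp):
#   maximize W(beta) = y'beta - eps * sum(|beta|) - 1/2 beta' K beta
#   s.t. sum(beta) = 0, -C <= beta_i <= C.
.smo_solve <- function(K, y, C, epsilon, tol, max_iter) {
  res <- .smo_solve_cpp(K, y, C, epsilon, tol, as.integer(max_iter))
  beta <- res$beta
  b <- .svr_bias(K, y, beta, C, epsilon)
  obj <- sum(y * beta) - epsilon * sum(abs(beta)) -
    0.5 * drop(crossprod(beta, K %*% beta))
  list(beta = beta, b = b, objective = obj, iterations = res$iterations,
       converged = res$converged)
}

# KKT-consistent bias: average over unbounded support vectors, else the
# midpoint of the feasible interval implied by all points.
.svr_bias <- function(K, y, beta, C, epsilon) {
  r <- y - drop(K %*% beta)
  bound_tol <- 1e-8 * max(1, C)
  interior_pos <- beta > bound_tol & beta < C - bound_tol
  interior_neg <- beta < -bound_tol & beta > -C + bound_tol
  vals <- c(r[interior_pos] - epsilon, r[interior_neg] + epsilon)
  if (length(vals) > 0L) return(mean(vals))
  lo <- suppressWarnings(max(c(r[beta <= -C + bound_tol] + epsilon,
                               r[abs(beta) <= bound_tol] - epsilon)))
  hi <- suppressWarnings(min(c(r[beta >= C - bound_tol] - epsilon,
                               r[abs(beta) <= bound_tol] + epsilon)))
  if (!is.finite(lo) && !is.finite(hi)) return(mean(r))
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' @export
print.svr_model <- function(x, ...) {
  cat("epsilon-SVR (RBF kernel)\n")
  cat(sprintf("  C = %g, gamma = %g, epsilon = %g\n", x$C, x$gamma, x$epsilon))
  cat(sprintf("  %d training points, %d support vectors\n",
              length(x$beta), length(x$support)))
  cat(sprintf("  dual objective %.6g (%s in %d iterations)\n",
              x$dual_objective,
              ifelse(x$converged, "converged", "iteration cap reached"),
              x$iterations))
  invisible(x)
}

#' Predict from a fitted epsilon-SVR
#'
#' @param object An \code{"svr_model"}.
#' @param newdata Matrix or data frame of raw (unstandardized) inputs with
#'   the training feature count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$x_train)) {
    stop(sprintf("newdata has %d feature(s); model was trained on %d",
                 ncol(newdata), ncol(object$x_train)), call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  drop(.rbf_matrix(xs, object$x_train, object$gamma) %*% object$beta) +
    object$b
}

#' @export
residuals.svr_model <- function(object, ...) object$y_train - object$fitted

#' @export
coef.svr_model <- function(object, ...) {
  list(beta = object$beta, b = object$b)
}

#' Serialize an SVR model to JSON
#'
#' Writes hyperparameters, standardization, dual coefficients, bias and
#' the training coordinates, so the model file is self-contained.
#'
#' @param model An \code{"svr_model"}.
#' @param path Output file path.
#' @export
svr_to_json <- function(model, path) {
  payload <- list(schema = "skinperm/svr_model/1",
                  C = model$C, gamma = model$gamma, epsilon = model$epsilon,
                  b = model$b, beta = model$beta,
                  center = as.list(model$center),
                  scale = as.list(model$scale),
                  x_train = apply(model$x_train, 1L, as.numeric,
                                  simplify = FALSE),
                  y_train = model$y_train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SVR model from JSON
#'
#' @param path File written by \code{\link{svr_to_json}}.
#' @return An \code{"svr_model"} (fitted values recomputed).
#' @export
svr_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "skinperm/svr_model/1")) {
    stop("unrecognized model schema", call. = FALSE)
  }
  xs <- if (is.list(p$x_train)) do.call(rbind, p$x_train) else as.matrix(p$x_train)
  beta <- as.numeric(p$beta)
  K <- .rbf_matrix(xs, xs, p$gamma)
  out <- list(beta = beta, b = p$b, C = p$C, gamma = p$gamma,
              epsilon = p$epsilon, x_train = xs,
              center = unlist(p$center), scale = unlist(p$scale),
              y_train = as.numeric(p$y_train),
              fitted = drop(K %*% beta) + p$b,
              support = which(abs(beta) > 1e-8),
              dual_objective = NA_real_, iterations = NA_integer_,
              converged = TRUE)
  class(out) <- "svr_model"
  out
}
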