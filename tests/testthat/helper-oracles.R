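# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation it checks.

# Path-based connectivity index by igraph simple-path enumeration.
oracle_connectivity <- function(g, k, valence = FALSE) {
  d <- if (valence) g$delta_v else g$delta
  if (k == 0) return(sum(1 / sqrt(d[d > 0])))
  edges <- do.call(rbind, lapply(seq_len(g$n), function(v) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb) == 0) NULL else cbind(rep(v, length(nb)), nb)
  }))
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    ig <- igraph::add_edges(ig, t(edges))
  }
  total <- 0
  for (v in seq_len(g$n)) {
    paths <- igraph::all_simple_paths(ig, from = v, cutoff = k)
    for (p in paths) {
      p <- as.integer(p)
      if (length(p) == k + 1 && p[1] < p[length(p)]) {
        total <- total + 1 / sqrt(prod(d[p]))
      }
    }
  }
  total
}

# OLS by explicit normal equations.
oracle_ols <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  drop(solve(crossprod(xm), crossprod(xm, y)))
}

# Kennard-Stone by literal restatement of the max-min rule.
oracle_kennard_stone <- function(x, n_train) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  pair <- which(d == max(d), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  sel <- sort(unique(as.integer(pair[1, ])))[1:2]
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(n), sel)
    score <- sapply(rest, function(r) min(d[r, sel]))
    sel <- c(sel, rest[which.max(score)])
  }
  sel
}

# epsilon-SVR dual solved exactly by active-set QP: the optimal active set
# is identified from an independent libsvm solve at tight tolerance, the
# KKT equality system for the free coordinates is then solved by plain
# linear algebra (machine precision), and every KKT condition is verified.
# The oracle refuses to answer rather than return an unverified solution.
oracle_svr_qp <- function(xs, y, C, gamma, epsilon) {
  n <- length(y)
  K <- exp(-gamma * as.matrix(dist(xs))^2)
  ref <- e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
                    cost = C, gamma = gamma, epsilon = epsilon,
                    scale = FALSE, tolerance = 1e-8)
  beta0 <- numeric(n)
  beta0[ref$index] <- ref$coefs
  tol <- 1e-5 * max(1, C)

  at_up <- beta0 >= C - tol
  at_lo <- beta0 <= -C + tol
  at_zero <- abs(beta0) <= tol
  free <- !(at_up | at_lo | at_zero)
  beta <- numeric(n)
  beta[at_up] <- C
  beta[at_lo] <- -C
  sgn <- sign(beta0)

  if (any(free)) {
    kf <- which(free)
    lhs <- rbind(cbind(K[kf, kf, drop = FALSE], 1),
                 c(rep(1, length(kf)), 0))
    fixed_term <- if (any(!free)) {
      drop(K[kf, !free, drop = FALSE] %*% beta[!free])
    } else 0
    rhs <- c(y[kf] - epsilon * sgn[kf] - fixed_term, -sum(beta[!free]))
    sol <- solve(lhs, rhs)
    beta[kf] <- sol[seq_along(kf)]
    b <- sol[length(sol)]
  } else {
    b <- -ref$rho
  }

  # full KKT verification of the refined solution
  r <- y - drop(K %*% beta) - b
  ok <- abs(sum(beta)) < 1e-8 &&
    all(beta <= C + 1e-8) && all(beta >= -C - 1e-8) &&
    all(abs(r[at_zero]) <= epsilon + 1e-6) &&
    all(r[at_up] >= epsilon - 1e-6) &&
    all(r[at_lo] <= -epsilon + 1e-6) &&
    (!any(free) || all(abs(r[free] - epsilon * sgn[free]) < 1e-6)) &&
    (!any(free) || all(sign(beta[free]) == sgn[free]))
  if (!ok) return(NULL)  # degenerate instance; caller draws another

  obj <- sum(y * beta) - epsilon * sum(abs(beta)) -
    0.5 * drop(crossprod(beta, K %*% beta))
  list(beta = beta, objective = obj, b = b, K = K)
}

# Transcription-independent reimplementation of the external-validation
# battery, from the original criteria definitions.
oracle_gt <- function(y, yp, ybar_train) {
  press <- sum((y - yp)^2)
  sd_tot <- sum((y - ybar_train)^2)
  slope_pred_on_obs <- sum(y * yp) / sum(yp * yp)
  slope_obs_on_pred <- sum(y * yp) / sum(y * y)
  r0 <- 1 - sum((yp - slope_pred_on_obs * yp)^2) / sum((yp - mean(yp))^2)
  r0p <- 1 - sum((y - slope_obs_on_pred * y)^2) / sum((y - mean(y))^2)
  r2 <- (sum((y - mean(y)) * (yp - mean(yp))) /
           sqrt(sum((y - mean(y))^2) * sum((yp - mean(yp))^2)))^2
  list(q2_ext = 1 - press / sd_tot, k = slope_pred_on_obs,
       k_prime = slope_obs_on_pred, r0_sq = r0, r0_prime_sq = r0p,
       rel_diff = abs(r2 - r0) / r2, rel_diff_prime = abs(r2 - r0p) / r2)
}

# trainer closures used by the cross-validation tests; the mean model is
# an intercept-only lm so predict() dispatches without extra methods
ols_trainer <- function(x, y) ols_fit(x, y)
mean_trainer <- function(x, y) lm(y ~ 1, data = data.frame(y = y))
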