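# Independent oracles used across the suite. These deliberately avoid the
# package's own integration / classification code paths.

# fixed-step classical RK4 for dx/dt = x * (k + A x), with optional
# instantaneous doses into species 4
rk4_glv <- function(k, A, x0, t_end, h = 1e-3, doses = NULL) {
  f <- function(x) x * (k + as.numeric(A %*% x))
  x <- x0
  t <- 0
  dose_times <- if (is.null(doses)) numeric() else doses$time
  # apply dose at t = 0
  x[4] <- x[4] + sum(doses$amount[dose_times == 0])
  events <- sort(unique(c(dose_times[dose_times > 0], t_end)))
  for (ev in events) {
    nstep <- round((ev - t) / h)
    hh <- (ev - t) / nstep
    for (s in seq_len(nstep)) {
      k1 <- f(x)
      k2 <- f(x + hh / 2 * k1)
      k3 <- f(x + hh / 2 * k2)
      k4 <- f(x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- ev
    x[4] <- x[4] + sum(doses$amount[dose_times == ev])
  }
  x
}

# brute-force nearest centroid on a relative abundance vector
brute_nearest_centroid <- function(rel, centroids) {
  d <- apply(centroids, 1, function(ct) sqrt(sum((rel - ct)^2)))
  names(d)[which(d <= min(d) + 1e-12)[1]]
}

# attractors reached from random positive starts of a resident community,
# via the simulator (an independent path from the analytic enumeration)
basin_attractors <- function(resident, n_starts = 10, t_end = 500,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- community_params(resident, make_strain("null"))
  finals <- matrix(NA_real_, n_starts, 3)
  for (i in seq_len(n_starts)) {
    x0 <- c(stats::runif(3, 0.1, 30), 0)
    # unconstrained mutualistic draws can diverge; such starts have no
    # finite attractor and are reported as NA
    tr <- tryCatch(simulate_glv(params, x0, times = t_end),
                   error = function(e) NULL)
    if (!is.null(tr) && all(as.numeric(tr[1, 2:4]) < 1e6))
      finals[i, ] <- as.numeric(tr[1, c("nAB", "Li", "oLB")])
  }
  finals[stats::complete.cases(finals), , drop = FALSE]
}

# NIPALS PLS2 on column-standardized X and one-hot-dummy Y, unit-norm
# loading weights, regression-mode deflation of X only — the classical
# algorithm, coded independently of any PLS library
nipals_pls2 <- function(X, y, ncomp = 2, tol = 1e-12, maxit = 500) {
  X <- scale(as.matrix(X))
  Y <- stats::model.matrix(~ 0 + factor(y))
  Y <- scale(Y)
  n <- nrow(X)
  scores <- matrix(0, n, ncomp)
  weights <- matrix(0, ncol(X), ncomp)
  for (h in seq_len(ncomp)) {
    u <- Y[, 1]
    w <- rep(0, ncol(X))
    for (it in seq_len(maxit)) {
      w_new <- crossprod(X, u) / sum(u^2)
      w_new <- w_new / sqrt(sum(w_new^2))
      t_sc <- X %*% w_new
      q <- crossprod(Y, t_sc) / sum(t_sc^2)
      u <- Y %*% q / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < tol) break
      w <- w_new
    }
    t_sc <- X %*% w_new
    p <- crossprod(X, t_sc) / sum(t_sc^2)
    X <- X - t_sc %*% t(p)
    scores[, h] <- t_sc
    weights[, h] <- w_new
  }
  list(scores = scores, weights = weights)
}

# hand-computed Pearson chi-square on a 2x2 table
pearson_chisq_2x2 <- function(a, an, b, bn) {
  tab <- rbind(c(a, an - a), c(b, bn - b))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
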