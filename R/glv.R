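#' Generalized Lotka-Volterra parameter set
#'
#' Bundles the per-species intrinsic growth rates and the interaction
#' matrix of a generalized Lotka-Volterra (gLV) community
#' \deqn{dx_i/dt = x_i (k_i + \sum_j \alpha_{j \to i} x_j).}
#' `alpha[i, j]` holds \eqn{\alpha_{j \to i}}, the effect of species `j`
#' on the per-capita growth of species `i` (units density^-1 d^-1);
#' growth rates are in d^-1.
#'
#' @param k_grow Numeric vector of intrinsic growth rates, one per species.
#' @param alpha Square numeric interaction matrix, `alpha[i, j]` = effect of
#'   species `j` on species `i`. Diagonal entries (self-interaction) must be
#'   strictly negative for any species with positive growth, so that a
#'   species growing alone saturates at a finite carrying capacity.
#' @param species Character vector of species names; defaults to
#'   [glv_species()] for 4 entries, or the resident trio for 3.
#'
#' @return An object of class `glv_params`.
#' @examples
#' p <- glv_params(
#'   k_grow = c(0.5, 0.4, 0.3, 0.5),
#'   alpha  = diag(c(-0.02, -0.02, -0.02, -0.022))
#' )
#' p
#' @export
glv_params <- function(k_grow, alpha, species = NULL) {
  k_grow <- as.numeric(k_grow)
  alpha <- as.matrix(alpha)
  n <- length(k_grow)
  if (!all(dim(alpha) == c(n, n)))
    stop("`alpha` must be a ", n, "x", n, " matrix matching `k_grow`")
  if (!all(is.finite(k_grow)) || !all(is.finite(alpha)))
    stop("gLV parameters must be finite")
  if (any(k_grow > 0 & diag(alpha) >= 0))
    stop("self-interaction must be strictly negative for species with positive growth")
  if (is.null(species)) {
    species <- if (n == 4) glv_species() else if (n == 3) resident_species()
      else paste0("sp", seq_len(n))
  }
  names(k_grow) <- species
  dimnames(alpha) <- list(species, species)
  structure(list(k_grow = k_grow, alpha = alpha, species = species),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat("gLV parameter set (", length(x$species), " species)\n", sep = "")
  cat("growth rates (d^-1):\n")
  print(round(x$k_grow, 4))
  cat("interaction matrix alpha[i, j] = effect of j on i (density^-1 d^-1):\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Antibiotic exposure window
#'
#' During the window the net growth rate of the nAB group is replaced by a
#' negative first-order kill rate `k_kill`, emulating metronidazole, which
#' suppresses the anaerobes while *Lactobacillus* spp. (and the probiotic)
#' are resistant and unaffected.
#'
#' @param start,end Window bounds in days, `start < end`.
#' @param k_kill Net kill rate in d^-1; must be negative. The default
#'   -2.64 d^-1 is the moderate literature-derived decay rate; -3.82 d^-1
#'   corresponds to the most antibiotic-sensitive strains.
#' @return An object of class `antibiotic_window`.
#' @export
antibiotic_window <- function(start, end, k_kill = -2.64) {
  if (!is.finite(start) || !is.finite(end) || start >= end)
    stop("antibiotic window needs start < end")
  if (!is.finite(k_kill) || k_kill >= 0)
    stop("`k_kill` must be negative")
  structure(list(start = start, end = end, k_kill = k_kill),
            class = "antibiotic_window")
}

#' Probiotic dose schedule
#'
#' Doses are instantaneous boluses: at each time the probiotic abundance is
#' incremented by `amount` (density units).
#'
#' @param times Numeric vector of dose times, days.
#' @param amount Dose amount(s), recycled along `times`; must be >= 0.
#' @return A data frame with columns `time` and `amount`.
#' @export
dose_schedule <- function(times, amount) {
  if (length(times) == 0) return(data.frame(time = numeric(), amount = numeric()))
  amount <- rep_len(as.numeric(amount), length(times))
  if (any(amount < 0)) stop("dose amounts must be >= 0")
  d <- data.frame(time = as.numeric(times), amount = amount)
  d[order(d$time), , drop = FALSE]
}

check_windows <- function(windows) {
  if (length(windows) == 0) return(invisible(NULL))
  b <- do.call(rbind, lapply(windows, function(w) c(w$start, w$end)))
  b <- b[order(b[, 1]), , drop = FALSE]
  if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2]))
    stop("overlapping antibiotic windows give an ambiguous kill rate")
  invisible(NULL)
}

kill_rate_at <- function(time, windows) {
  for (w in windows)
    if (time >= w$start && time < w$end) return(w$k_kill)
  NA_real_
}

#' gLV right-hand side
#'
#' Time derivative of the community state. Inside an antibiotic window the
#' nAB growth rate is replaced by the window's `k_kill`; all interaction
#' terms remain active.
#'
#' @param state Abundance vector (one entry per species), >= 0.
#' @param time Time in days (used only to locate antibiotic windows).
#' @param params A [glv_params()] object.
#' @param windows List of [antibiotic_window()] objects (non-overlapping).
#' @return Numeric vector of derivatives, density d^-1.
#' @export
glv_rhs <- function(state, time = 0, params, windows = list()) {
  if (any(state < 0)) stop("abundances must be >= 0")
  check_windows(windows)
  k <- params$k_grow
  kk <- kill_rate_at(time, windows)
  if (!is.na(kk) && "nAB" %in% names(k)) k[["nAB"]] <- kk
  as.numeric(state * (k + params$alpha %*% state))
}

# effective growth-rate vector for a segment whose interior lies at `tmid`
segment_growth <- function(params, tmid, windows) {
  k <- params$k_grow
  kk <- kill_rate_at(tmid, windows)
  if (!is.na(kk)) k[["nAB"]] <- kk
  k
}

#' Simulate the community through a dosing regimen
#'
#' Integrates the 4-species gLV system from time 0, restarting the solver
#' at every dose time and antibiotic-window boundary (the dynamics are
#' piecewise smooth between such events). Probiotic doses are instantaneous
#' boluses added to `P`; the state reported at a dose time is the
#' post-bolus state.
#'
#' @param params A 4-species [glv_params()] object.
#' @param init Initial abundances (4-vector, >= 0) at time 0.
#' @param times Output times (days, >= 0, need not include event times).
#' @param doses Dose schedule from [dose_schedule()] (or `NULL`).
#' @param windows List of [antibiotic_window()] objects.
#' @param rtol,atol Solver tolerances (adaptive stiff-capable `lsoda`).
#' @return A data frame with column `time` and one abundance column per
#'   species, rows at the requested `times`.
#' @examples
#' p <- glv_params(c(0.5, 0.4, 0.3, 0.5), diag(c(-0.02, -0.02, -0.02, -0.022)))
#' tr <- simulate_glv(p, c(10, 1, 1, 0), times = 0:30,
#'                    doses = dose_schedule(0:6, 5))
#' tail(tr, 3)
#' @export
simulate_glv <- function(params, init, times, doses = NULL, windows = list(),
                         rtol = 1e-6, atol = 1e-9) {
  if (length(params$species) != 4)
    stop("simulate_glv() integrates the full 4-species community")
  init <- as.numeric(init)
  if (length(init) != 4) stop("`init` must have 4 entries")
  if (any(init < 0)) stop("negative initial abundance")
  check_windows(windows)
  if (is.null(doses)) doses <- dose_schedule(numeric(), numeric())
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("output times must be >= 0")
  horizon <- max(times, doses$time, vapply(windows, `[[`, 0, "end"), 0)

  breaks <- sort(unique(c(0, horizon, doses$time,
                          unlist(lapply(windows, function(w) c(w$start, w$end))))))
  breaks <- breaks[breaks >= 0 & breaks <= horizon]

  out_t <- numeric(0)
  out_x <- NULL
  y <- init
  record <- function(tt, yy) {
    out_t <<- c(out_t, tt)
    out_x <<- rbind(out_x, yy)
  }
  # dose exactly at t = 0
  amt0 <- sum(doses$amount[doses$time == 0])
  y[4] <- y[4] + amt0
  if (0 %in% times) record(0, y)

  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    k_eff <- segment_growth(params, (t0 + t1) / 2, windows)
    want <- times[times > t0 & times < t1]
    seg_times <- sort(unique(c(t0, want, t1)))
    sol <- suppressWarnings(deSolve::lsoda(
      y = y, times = seg_times, func = "glv_derivs",
      parms = c(k_eff, as.numeric(params$alpha)),
      dllname = "vmbsim", initfunc = "glv_init",
      rtol = rtol, atol = atol
    ))
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(seg_times) ||
        !all(is.finite(sol)))
      stop(sprintf("gLV solver failed on segment [%g, %g]", t0, t1))
    sol <- unname(as.matrix(sol))
    xs <- sol[, -1, drop = FALSE]
    # gLV preserves non-negativity analytically; clip solver undershoot
    neg <- xs < 0
    if (any(xs[neg] < -100 * atol))
      stop(sprintf("solver produced a negative abundance (%.3e) on [%g, %g]",
                   min(xs), t0, t1))
    xs[neg] <- 0
    if (length(want))
      for (i in seq_along(want)) record(want[i], xs[match(want[i], sol[, 1]), ])
    y <- xs[nrow(xs), ]
    # bolus at the segment's right endpoint
    amt <- sum(doses$amount[doses$time == t1])
    y[4] <- y[4] + amt
    if (t1 %in% times) record(t1, y)
  }

  out <- data.frame(time = out_t)
  out_x <- matrix(out_x, ncol = 4)
  colnames(out_x) <- params$species
  out <- cbind(out, out_x)
  rownames(out) <- NULL
  out[match(times, out$time), , drop = FALSE]
}

#' Find the fixed points of a gLV community
#'
#' Enumerates every support subset S of the species, solves the linear
#' steady-state system \eqn{\sum_{j \in S} \alpha_{j \to i} x_j = -k_i}
#' for \eqn{i \in S}, keeps solutions with strictly positive abundance on
#' the support, and classifies local stability from the Jacobian
#' \eqn{J = diag(k + \alpha x) + diag(x) \alpha} (stable iff every
#' eigenvalue has real part < `-tol`).
#'
#' @param params A [glv_params()] object (any number of species).
#' @param tol Stability tolerance on eigenvalue real parts; marginal points
#'   are treated as unstable.
#' @return List of fixed points, each a list with `support` (character),
#'   `abundance` (full named vector) and `stable` (logical). The extinction
#'   state (all zero) is included.
#' @export
find_fixed_points <- function(params, tol = 1e-9) {
  n <- length(params$species)
  k <- params$k_grow
  A <- params$alpha
  pts <- list()
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- rep(0, n)
    if (length(S) > 0) {
      sol <- tryCatch(solve(A[S, S, drop = FALSE], -k[S]),
                      error = function(e) NULL)
      if (is.null(sol)) {
        message("singular interaction submatrix for support {",
                paste(params$species[S], collapse = ","), "}; skipped")
        next
      }
      if (any(sol <= 0)) next
      x[S] <- sol
    }
    J <- diag(as.numeric(k + A %*% x), n) + diag(x, n) %*% A
    ev <- eigen(J, only.values = TRUE)$values
    names(x) <- params$species
    pts[[length(pts) + 1]] <- list(
      support = params$species[S],
      abundance = x,
      stable = all(Re(ev) < -tol)
    )
  }
  pts
}

#' @rdname find_fixed_points
#' @param ... Passed to `find_fixed_points()`.
#' @return `stable_fixed_points()` returns only the stable points.
#' @export
stable_fixed_points <- function(params, ...) {
  Filter(function(p) p$stable, find_fixed_points(params, ...))
}
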