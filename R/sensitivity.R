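#' Normalized local sensitivity coefficient
#'
#' \deqn{S = \frac{Y - Y_0}{P - P_0} \cdot \frac{P_0}{Y_0}}
#' standardizes the change in a response fraction relative to the change
#' in a parameter value. `Y0` is the response under the unperturbed (null)
#' strain; for interspecies interaction terms the reference parameter
#' value is `P0 = 0.01` by convention.
#'
#' @param Y Response fraction at parameter value `P`.
#' @param Y0 Response fraction of the reference (null) strain; must be > 0.
#' @param P Perturbed parameter value.
#' @param P0 Reference parameter value; must differ from `P`.
#' @return Dimensionless sensitivity `S` (`NA` if `Y0` is 0).
#' @examples
#' normalized_sensitivity(Y = 0.365, Y0 = 0.465, P = 0.02, P0 = 0.01)
#' @export
normalized_sensitivity <- function(Y, Y0, P, P0 = 0.01) {
  if (any(P == P0)) stop("P must differ from P0")
  if (Y0 == 0) return(NA_real_)
  ((Y - Y0) / (P - P0)) * (P0 / Y0)
}

probiotic_parameters <- function() {
  c("kgrow_P", "alpha_P_to_P", "alpha_nAB_to_P", "alpha_Li_to_P",
    "alpha_oLB_to_P", "alpha_P_to_nAB", "alpha_P_to_Li", "alpha_P_to_oLB")
}

default_sweep_grid <- function(parameter, n_points = 11) {
  switch(parameter,
         kgrow_P = seq(0, 1, length.out = n_points),
         alpha_P_to_P = seq(-0.04, -0.004, length.out = n_points),
         seq(-0.10, 0.10, length.out = n_points))
}

#' One-at-a-time local sensitivity sweep
#'
#' Perturbs a single probiotic parameter over a grid (all other parameters
#' held at the base strain's values), evaluates the regimen across the
#' population at each value, and computes the normalized sensitivity of
#' each response type at the final evaluation timepoint. Default grids:
#' interspecies terms on \[-0.10, 0.10\], growth rate on \[0, 1\],
#' self-interaction on \[-0.04, -0.004\]; `P0 = 0.01` for interspecies
#' terms and the base strain's own value otherwise.
#'
#' @param population A `virtual_population`.
#' @param parameter One of the 8 probiotic strain parameters.
#' @param grid Sweep values; defaults as above (11 points).
#' @param base_strain Reference strain (default null).
#' @param regimen Regimen (default short-term with `dose_amount`).
#' @param dose_amount Bolus size used when `regimen` is not supplied.
#' @param time Evaluation day; default the regimen's last timepoint.
#' @return A `sensitivity_result`: list with `parameter`, `grid`,
#'   `fractions` (value x label matrix), `S` (value x label matrix of
#'   pointwise coefficients), `S_mean` (per-label mean over the sweep),
#'   `Y0`, `P0`.
#' @export
local_sweep_1d <- function(population, parameter, grid = NULL,
                           base_strain = make_strain("null"),
                           regimen = NULL, dose_amount = 1, time = NULL) {
  if (!parameter %in% probiotic_parameters())
    stop("unknown probiotic parameter '", parameter, "'")
  if (is.null(grid)) grid <- default_sweep_grid(parameter)
  if (parameter == "alpha_P_to_P" && any(grid >= 0))
    stop("self-interaction sweep values must be negative")
  if (is.null(regimen))
    regimen <- make_regimen("short_term", dose_amount = dose_amount)
  if (is.null(time)) time <- max(regimen$eval_times)

  base_profile <- evaluate_regimen(population, base_strain, regimen)
  i0 <- match(time, regimen$eval_times)
  Y0 <- base_profile$fractions[i0, ]
  P_null <- base_strain[[parameter]]
  P0 <- if (startsWith(parameter, "alpha_") && parameter != "alpha_P_to_P")
    0.01 else P_null

  frac <- matrix(NA_real_, length(grid), length(Y0),
                 dimnames = list(signif(grid, 6), names(Y0)))
  for (g in seq_along(grid)) {
    st <- do.call(modify_strain,
                  c(list(base_strain), stats::setNames(list(grid[g]), parameter)))
    prof <- if (grid[g] == P_null) base_profile
      else evaluate_regimen(population, st, regimen)
    frac[g, ] <- prof$fractions[i0, ]
  }
  S <- frac * NA
  use <- grid != P0
  for (lab in colnames(frac))
    S[use, lab] <- normalized_sensitivity(frac[use, lab], Y0[[lab]],
                                          grid[use], P0)
  structure(list(parameter = parameter, grid = grid, fractions = frac,
                 S = S, S_mean = colMeans(S, na.rm = TRUE),
                 Y0 = Y0, P0 = P0, time = time),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("1D sensitivity sweep of", x$parameter, "at day", x$time, "\n")
  cat("mean normalized sensitivity per response type:\n")
  print(round(x$S_mean, 4))
  invisible(x)
}

#' Four-parameter combination grid
#'
#' Evaluates every combination of `alpha_nAB_to_P`, `alpha_P_to_nAB`,
#' `alpha_P_to_Li`, `alpha_P_to_oLB` over `values` (3^4 = 81 combinations
#' by default), reporting per-response fractions at the final evaluation
#' timepoint plus a chi-square test of the failure frequency against the
#' all-zero (null) combination. Rows are ordered from most to least
#' efficacious (ascending failure rate).
#'
#' @param population A `virtual_population`.
#' @param values Values each parameter may take (default -0.01, 0, +0.01).
#' @param base_strain Base strain the modifications apply to.
#' @param regimen Regimen (default short-term with `dose_amount`).
#' @param dose_amount Bolus size used when `regimen` is not supplied.
#' @return Data frame with the four parameter columns, `nAB`, `Li`, `oLB`,
#'   `P` fractions, and `chisq_p` versus the null combination.
#' @export
four_parameter_grid <- function(population, values = c(-0.01, 0, 0.01),
                                base_strain = make_strain("null"),
                                regimen = NULL, dose_amount = 1) {
  if (is.null(regimen))
    regimen <- make_regimen("short_term", dose_amount = dose_amount)
  pars <- c("alpha_nAB_to_P", "alpha_P_to_nAB", "alpha_P_to_Li",
            "alpha_P_to_oLB")
  combos <- expand.grid(rep(list(values), 4))
  names(combos) <- pars
  i0 <- length(regimen$eval_times)
  n <- length(population$patients)
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    st <- do.call(modify_strain, c(list(base_strain), as.list(combos[r, ])))
    prof <- evaluate_regimen(population, st, regimen)
    cbind(combos[r, ], as.data.frame(t(prof$fractions[i0, ])))
  })
  out <- do.call(rbind, rows)
  null_row <- which(rowSums(abs(as.matrix(combos))) == 0)
  null_fail <- out$nAB[null_row]
  out$chisq_p <- vapply(out$nAB, function(f) {
    if (f == null_fail) return(1)
    chi_square_frequency_test(round(f * n), n, round(null_fail * n), n)$p.value
  }, 0)
  out <- out[order(out$nAB), ]
  rownames(out) <- NULL
  out
}
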