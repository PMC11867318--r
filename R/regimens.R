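#' Construct a treatment regimen
#'
#' A regimen bundles the probiotic dose schedule, any antibiotic exposure
#' windows, and the evaluation timepoints (absolute days from treatment
#' start). Built-in regimens:
#' \describe{
#'   \item{`short_term`}{7 once-daily probiotic doses (days 0-6), therapy
#'     cessation day 7; evaluated at cessation and 1 wk, 1 mo, 3 mo, 6 mo,
#'     12 mo post-cessation.}
#'   \item{`abx_only`}{7-day antibiotic window, no probiotic; evaluated at
#'     cessation and 1/3/6 months post.}
#'   \item{`abx_then_probiotic`}{7-day antibiotic window followed by the
#'     7-day daily probiotic course; evaluated at cessation (day 14) and
#'     1/3/6 months post.}
#'   \item{`lactin_v`}{5-day antibiotic window, 4 once-daily doses (days
#'     5-8), then 10 weeks of twice-weekly doses; therapy ends week 11
#'     (day 77); evaluated at weeks 12 and 24 from treatment start.}
#' }
#' Calendar constants: 1 month = 30 d, 3 months = 90 d, 6 months = 180 d,
#' 12 months = 365 d.
#'
#' @param name One of `short_term`, `abx_only`, `abx_then_probiotic`,
#'   `lactin_v`.
#' @param dose_amount Probiotic bolus size, density units (see
#'   [calibrate_dose()]).
#' @param k_kill Antibiotic kill rate (d^-1, negative); -2.64 moderate,
#'   -3.82 strong.
#' @param lv_frequency For `lactin_v`, the week 2-11 dosing frequency: one
#'   of `"biweekly"` (every other week), `"weekly"`, `"twice_weekly"`
#'   (the trial schedule), `"4x_weekly"`, `"daily"`.
#' @param dose_multiplier Scales every dose amount (dose-amount sweeps).
#' @return An object of class `regimen` with elements `name`, `doses`,
#'   `windows`, `eval_times` (absolute days), `cessation` (day).
#' @examples
#' make_regimen("short_term", dose_amount = 10)
#' make_regimen("lactin_v", dose_amount = 10, lv_frequency = "daily")
#' @export
make_regimen <- function(name, dose_amount = 1, k_kill = -2.64,
                         lv_frequency = "twice_weekly", dose_multiplier = 1) {
  amt <- dose_amount * dose_multiplier
  reg <- switch(
    name,
    short_term = list(
      doses = dose_schedule(0:6, amt), windows = list(),
      cessation = 7, eval_times = 7 + c(0, 7, 30, 90, 180, 365)
    ),
    abx_only = list(
      doses = dose_schedule(numeric(), numeric()),
      windows = list(antibiotic_window(0, 7, k_kill)),
      cessation = 7, eval_times = 7 + c(0, 30, 90, 180)
    ),
    abx_then_probiotic = list(
      doses = dose_schedule(7:13, amt),
      windows = list(antibiotic_window(0, 7, k_kill)),
      cessation = 14, eval_times = 14 + c(0, 30, 90, 180)
    ),
    lactin_v = {
      spacing <- c(biweekly = 14, weekly = 7, twice_weekly = 3.5,
                   `4x_weekly` = 1.75, daily = 1)
      if (!lv_frequency %in% names(spacing))
        stop("unknown lv_frequency; use one of: ",
             paste(names(spacing), collapse = ", "))
      maintenance <- seq(9, 77 - 1e-9, by = spacing[[lv_frequency]])
      list(
        doses = dose_schedule(c(5:8, maintenance), amt),
        windows = list(antibiotic_window(0, 5, k_kill)),
        cessation = 77, eval_times = c(84, 168)
      )
    },
    stop("unknown regimen '", name, "'; use short_term, abx_only, ",
         "abx_then_probiotic or lactin_v")
  )
  structure(c(list(name = name, dose_amount = amt,
                   lv_frequency = if (name == "lactin_v") lv_frequency else NA),
              reg), class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("regimen '", x$name, "': ", nrow(x$doses), " doses of ",
      signif(x$dose_amount, 4), ", ", length(x$windows),
      " antibiotic window(s)\n", sep = "")
  cat("evaluation at days:", paste(x$eval_times, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a regimen for one patient
#'
#' @param patient A `virtual_patient`.
#' @param strain A [make_strain()] object.
#' @param regimen A [make_regimen()] object.
#' @param times Output times; defaults to the regimen's evaluation times.
#' @return Trajectory data frame from [simulate_glv()].
#' @export
simulate_patient <- function(patient, strain, regimen,
                             times = regimen$eval_times) {
  params <- community_params(patient$params, strain)
  simulate_glv(params, patient$initial_state, times = times,
               doses = regimen$doses, windows = regimen$windows)
}

#' Evaluate a strain and regimen across a virtual population
#'
#' Simulates every patient through the regimen and classifies the
#' community state at each evaluation timepoint. Patients whose simulation
#' fails are excluded (and counted).
#'
#' @param population A `virtual_population`.
#' @param strain A [make_strain()] object.
#' @param regimen A [make_regimen()] object.
#' @param centroids Centroid matrix for classification.
#' @return A `response_profile`: list with `fractions` (timepoint x label
#'   matrix of population fractions), `labels` (patient x timepoint
#'   character matrix), `eval_times`, `n`, `n_excluded`.
#' @examples
#' pop <- generate_population(pool_size = 200, n = 20, seed = 1)
#' prof <- evaluate_regimen(pop, make_strain("null"),
#'                          make_regimen("short_term", dose_amount = 10))
#' prof
#' @export
evaluate_regimen <- function(population, strain, regimen,
                             centroids = default_centroids()) {
  pts <- population$patients
  if (length(pts) == 0) stop("empty population")
  et <- regimen$eval_times
  labs <- matrix(NA_character_, length(pts), length(et),
                 dimnames = list(NULL, paste0("d", et)))
  failed <- 0
  for (i in seq_along(pts)) {
    row <- tryCatch({
      tr <- simulate_patient(pts[[i]], strain, regimen)
      classify_cst(as.matrix(tr[, glv_species()]), centroids)
    }, error = function(e) NULL)
    if (is.null(row)) { failed <- failed + 1; next }
    labs[i, ] <- row
  }
  if (failed > 0)
    message(failed, " patient simulation(s) failed and were excluded")
  ok <- !is.na(labs[, 1])
  frac <- t(apply(labs[ok, , drop = FALSE], 2, function(col)
    table(factor(col, levels = rownames(centroids))) / sum(ok)))
  structure(list(fractions = frac, labels = labs, eval_times = et,
                 n = sum(ok), n_excluded = failed,
                 strain = strain$name, regimen = regimen$name),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat("response profile: strain '", x$strain, "', regimen '", x$regimen,
      "', n = ", x$n, if (x$n_excluded) paste0(" (", x$n_excluded, " excluded)"),
      "\n", sep = "")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Population fraction with a given response at a timepoint
#'
#' @param profile A `response_profile`.
#' @param label Response label (default `"nAB"`, i.e. the failure rate).
#' @param time Evaluation day; default the last evaluation timepoint.
#' @return Fraction in \[0, 1\].
#' @export
response_fraction <- function(profile, label = "nAB",
                              time = max(profile$eval_times)) {
  i <- match(time, profile$eval_times)
  if (is.na(i)) stop("time ", time, " is not an evaluation timepoint")
  profile$fractions[i, label]
}

#' Calibrate the probiotic dose amount
#'
#' Chooses the bolus size so that the population-median probiotic relative
#' abundance one day after a single dose (given at time 0 into each
#' patient's baseline state) reaches `target`. This stands in for the
#' published calibration against clinically observed post-dose relative
#' abundance distributions, whose numeric target is not public.
#'
#' @param population A `virtual_population`.
#' @param strain Strain used for the calibration (default null strain).
#' @param target Target median relative abundance of P at day 1.
#' @param interval Dose search interval (density units).
#' @return The calibrated dose amount (scalar).
#' @export
calibrate_dose <- function(population, strain = make_strain("null"),
                           target = 0.5, interval = c(1e-3, 1e4)) {
  pts <- population$patients
  med_rel <- function(dose) {
    rel <- vapply(pts, function(p) {
      params <- community_params(p$params, strain)
      tr <- simulate_glv(params, p$initial_state, times = 1,
                         doses = dose_schedule(0, dose))
      x <- as.numeric(tr[1, glv_species()])
      x[4] / sum(x)
    }, 0)
    stats::median(rel)
  }
  f <- function(ld) med_rel(exp(ld)) - target
  exp(stats::uniroot(f, log(interval), tol = 1e-3)$root)
}

#' Dose-frequency sweep for the Lactin-V regimen
#'
#' Evaluates each strain under the Lactin-V regimen with the week 2-11
#' maintenance dosing set to each frequency variant, reporting the failure
#' rate (nAB-dominant fraction) at weeks 12 and 24.
#'
#' @param population A `virtual_population`.
#' @param strains List of [make_strain()] objects.
#' @param variants Character vector of frequency variants (see
#'   [make_regimen()]).
#' @param dose_amount Bolus size.
#' @param k_kill Antibiotic kill rate.
#' @return Data frame with columns `strain`, `variant`, `failure_12wk`,
#'   `failure_24wk`.
#' @export
sweep_dose_frequency <- function(population, strains,
                                 variants = c("biweekly", "weekly",
                                              "twice_weekly", "4x_weekly",
                                              "daily"),
                                 dose_amount = 1, k_kill = -2.64) {
  grid <- expand.grid(strain = seq_along(strains), variant = variants,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    st <- strains[[grid$strain[r]]]
    reg <- make_regimen("lactin_v", dose_amount = dose_amount,
                        k_kill = k_kill, lv_frequency = grid$variant[r])
    prof <- evaluate_regimen(population, st, reg)
    data.frame(strain = st$name, variant = grid$variant[r],
               failure_12wk = response_fraction(prof, "nAB", 84),
               failure_24wk = response_fraction(prof, "nAB", 168))
  })
  do.call(rbind, res)
}

#' Dose-amount sweep for the Lactin-V regimen
#'
#' @param population A `virtual_population`.
#' @param strains List of [make_strain()] objects.
#' @param multipliers Dose multipliers relative to the baseline amount.
#' @param dose_amount Baseline bolus size.
#' @param k_kill Antibiotic kill rate.
#' @return Data frame with columns `strain`, `multiplier`, `failure_12wk`,
#'   `failure_24wk`.
#' @export
sweep_dose_amount <- function(population, strains,
                              multipliers = 10^seq(-3, 3),
                              dose_amount = 1, k_kill = -2.64) {
  grid <- expand.grid(strain = seq_along(strains), mult = multipliers)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    st <- strains[[grid$strain[r]]]
    reg <- make_regimen("lactin_v", dose_amount = dose_amount,
                        k_kill = k_kill, dose_multiplier = grid$mult[r])
    prof <- evaluate_regimen(population, st, reg)
    data.frame(strain = st$name, multiplier = grid$mult[r],
               failure_12wk = response_fraction(prof, "nAB", 84),
               failure_24wk = response_fraction(prof, "nAB", 168))
  })
  do.call(rbind, res)
}
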