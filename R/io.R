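#' Serialize a virtual population to CSV
#'
#' One row per patient: `id`, the 12 resident parameters, the
#' equilibrium-behavior label and the initial abundances.
#'
#' @param population A `virtual_population`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(population, path) {
  rows <- lapply(population$patients, function(p) {
    data.frame(id = p$id, t(p$draw), behavior = p$behavior,
               init_nAB = p$initial_state[["nAB"]],
               init_Li = p$initial_state[["Li"]],
               init_oLB = p$initial_state[["oLB"]],
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a virtual population from CSV
#'
#' Patients are reconstructed from their parameter draws (fixed points and
#' behavior labels are recomputed, guaranteeing internal consistency).
#'
#' @param path CSV written by [write_population_csv()].
#' @param centroids Centroid matrix.
#' @return A `virtual_population`.
#' @export
read_population_csv <- function(path, centroids = default_centroids()) {
  d <- utils::read.csv(path, check.names = FALSE)
  pars <- default_ranges()$parameter
  pats <- lapply(seq_len(nrow(d)), function(i) {
    p <- virtual_patient(d[i, pars], id = d$id[i], centroids = centroids)
    if (is.null(p)) stop("row ", i, " is not a BV+ patient")
    p
  })
  structure(list(patients = pats, target_freqs = NULL),
            class = "virtual_population")
}

#' Serialize a response profile to tidy CSV
#'
#' @param profile A `response_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly. Columns: `timepoint` (day), `label`,
#'   `fraction`, `n`, `strain`, `regimen`.
#' @export
write_profile_csv <- function(profile, path) {
  d <- expand.grid(timepoint = profile$eval_times,
                   label = colnames(profile$fractions),
                   stringsAsFactors = FALSE)
  d$fraction <- as.numeric(profile$fractions[cbind(
    match(d$timepoint, profile$eval_times),
    match(d$label, colnames(profile$fractions)))])
  d$n <- profile$n
  d$strain <- profile$strain
  d$regimen <- profile$regimen
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Load parameter ranges from YAML
#'
#' Expected layout: a mapping `parameter: [lower, upper]`, one entry per
#' resident parameter; missing parameters fall back to [default_ranges()].
#'
#' @param path YAML file.
#' @return Ranges data frame.
#' @export
load_ranges <- function(path) {
  y <- yaml::read_yaml(path)
  r <- default_ranges()
  for (nm in names(y)) {
    i <- match(nm, r$parameter)
    if (is.na(i)) stop("unknown parameter '", nm, "' in ", path)
    r$lower[i] <- y[[nm]][[1]]
    r$upper[i] <- y[[nm]][[2]]
  }
  if (any(r$lower > r$upper)) stop("lower bound exceeds upper bound")
  r
}
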