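#' Parameter sampling ranges for the resident community
#'
#' Uniform sampling bounds for the 12 resident-community gLV parameters:
#' growth rates of nAB/Li/oLB on \[0.1, 1\] d^-1, self-interactions on
#' \[-0.04, -0.004\] density^-1 d^-1, and the six interspecies terms on
#' \[-0.10, 0.10\] density^-1 d^-1. Interaction-term bounds can be narrowed
#' (e.g. to impose sign constraints such as *Lactobacillus* inhibiting nAB)
#' by editing the returned table or via a YAML file ([load_ranges()]).
#'
#' @return A data frame with columns `parameter`, `lower`, `upper`.
#' @export
default_ranges <- function() {
  sp <- resident_species()
  inter <- expand.grid(from = sp, to = sp, stringsAsFactors = FALSE)
  inter <- inter[inter$from != inter$to, ]
  data.frame(
    parameter = c(paste0("kgrow_", sp),
                  paste0("alpha_", sp, "_to_", sp),
                  paste0("alpha_", inter$from, "_to_", inter$to)),
    lower = c(rep(0.1, 3), rep(-0.04, 3), rep(-0.10, 6)),
    upper = c(rep(1.0, 3), rep(-0.004, 3), rep(0.10, 6)),
    stringsAsFactors = FALSE
  )
}

#' Latin Hypercube Sample of parameter sets
#'
#' Stratified uniform sampling: each parameter's range is split into `n`
#' equal-probability bins, one draw per bin, with bins permuted
#' independently across parameters.
#'
#' @param ranges Data frame as from [default_ranges()].
#' @param n Number of parameter sets.
#' @param seed Integer seed for reproducibility.
#' @return An `n` x `nrow(ranges)` data frame, one column per parameter.
#' @export
lhs_sample <- function(ranges, n, seed = NULL) {
  stopifnot(n >= 1, all(ranges$lower <= ranges$upper))
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n, nrow(ranges))
  x <- sweep(u, 2, ranges$upper - ranges$lower, "*")
  x <- sweep(x, 2, ranges$lower, "+")
  colnames(x) <- ranges$parameter
  as.data.frame(x)
}

#' Assemble resident-community gLV parameters from a named draw
#'
#' @param draw Named numeric vector or one-row data frame with the 12
#'   resident parameters (`kgrow_*`, `alpha_*_to_*`).
#' @return A 3-species [glv_params()] object.
#' @export
resident_params <- function(draw) {
  draw <- unlist(draw)
  sp <- resident_species()
  k <- draw[paste0("kgrow_", sp)]
  A <- matrix(0, 3, 3, dimnames = list(sp, sp))
  for (to in sp) for (from in sp)
    A[to, from] <- draw[[paste0("alpha_", from, "_to_", to)]]
  glv_params(k, A, species = sp)
}

# resident state (3-vector) padded with P = 0 for classification
pad_probiotic <- function(x) c(x, P = 0)

#' Classify the equilibrium behavior of a resident community
#'
#' Finds all stable fixed points of the 3-species resident system, labels
#' each by the community state classifier (with probiotic absent), and
#' summarises the attractor structure: `"1SS X"` for a mono-stable system
#' whose sole stable state is X-dominant, `"2SS X/Y"` for a bi-stable
#' system with two distinct dominant states, `"other"` otherwise.
#'
#' @param params 3-species resident [glv_params()].
#' @param centroids Centroid matrix for [classify_cst()].
#' @return List with `label`, `stable_points` (list of fixed points, each
#'   annotated with its `cst`), and `cst_labels`.
#' @export
classify_equilibrium_behavior <- function(params, centroids = default_centroids()) {
  stable <- stable_fixed_points(params)
  if (length(stable) == 0) {
    warning("no stable fixed point found; labelling 'other'")
    return(list(label = "other", stable_points = list(), cst_labels = character()))
  }
  labs <- vapply(stable, function(p) classify_cst(pad_probiotic(p$abundance), centroids), "")
  for (i in seq_along(stable)) stable[[i]]$cst <- labs[i]
  u <- unique(labs)
  # order multi-stable labels by the classifier's priority order
  u <- u[order(match(u, rownames(centroids)))]
  label <- if (length(u) == 1) paste("1SS", u)
    else if (length(u) == 2) paste0("2SS ", u[1], "/", u[2])
    else "other"
  list(label = label, stable_points = stable, cst_labels = labs)
}

#' Construct a virtual patient from a parameter draw
#'
#' A virtual BV+ patient is a resident parameter set whose equilibrium
#' behavior includes a stable nAB-dominant state; the patient's initial
#' condition is that state (highest-nAB one if several), with probiotic
#' absent.
#'
#' @param draw Named resident parameter draw (see [resident_params()]).
#' @param id Patient identifier.
#' @param centroids Centroid matrix.
#' @param inoculum Detection-floor abundance given to resident species that
#'   are absent from the analytic equilibrium. Exact zeros are absorbing in
#'   gLV dynamics — a species at 0 can never regrow, which would make
#'   antibiotic clearance structurally irreversible for patients whose
#'   BV state excludes *Lactobacillus* entirely; clinically, both
#'   BV-associated bacteria and *Lactobacillus* spp. persist at low levels
#'   in communities dominated by the other. The default 0.01 is ~0.1% of a
#'   typical equilibrium abundance, far below any classification threshold.
#' @return A `virtual_patient` (list with `id`, `draw`, `params`,
#'   `behavior`, `initial_state`), or `NULL` if the patient is not BV+.
#' @export
virtual_patient <- function(draw, id = NA_integer_, centroids = default_centroids(),
                            inoculum = 0.01) {
  params <- resident_params(draw)
  beh <- classify_equilibrium_behavior(params, centroids)
  nab_pts <- Filter(function(p) identical(p$cst, "nAB"), beh$stable_points)
  if (length(nab_pts) == 0) return(NULL)
  best <- nab_pts[[which.max(vapply(nab_pts, function(p) p$abundance[["nAB"]], 0))]]
  init <- best$abundance
  init[init == 0] <- inoculum
  structure(list(id = id, draw = unlist(draw), params = params,
                 behavior = beh$label, stable_points = beh$stable_points,
                 initial_state = pad_probiotic(init)),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat("virtual patient", x$id, "-", x$behavior, "\n")
  cat("initial state:", paste(sprintf("%s=%.3g", names(x$initial_state),
                                      x$initial_state), collapse = ", "), "\n")
  invisible(x)
}

#' Default target distribution of CST equilibrium behaviors
#'
#' The clinically observed distribution of BV-compatible equilibrium
#' behaviors in the Human Microbiome Project cohort: 60% mono-stable
#' nAB-dominant, 31% bi-stable nAB/Li, 9% bi-stable nAB/oLB.
#'
#' @return Named numeric vector of fractions summing to 1.
#' @export
hmp_target_frequencies <- function() {
  c("1SS nAB" = 0.60, "2SS nAB/Li" = 0.31, "2SS nAB/oLB" = 0.09)
}

largest_remainder <- function(n, freqs) {
  raw <- n * freqs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Resample a candidate pool to a target behavior distribution
#'
#' Draws exactly `round(n * fraction)` patients per equilibrium-behavior
#' label (largest-remainder rounding), without replacement when the pool
#' stratum suffices, with replacement (and a message) otherwise.
#'
#' @param pool List of `virtual_patient` objects.
#' @param target_freqs Named label -> fraction vector, e.g.
#'   [hmp_target_frequencies()].
#' @param n Output population size.
#' @param seed Integer seed.
#' @return A `virtual_population` object.
#' @export
resample_population <- function(pool, target_freqs = hmp_target_frequencies(),
                                n = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(pool, `[[`, "", "behavior")
  counts <- largest_remainder(n, target_freqs)
  out <- list()
  for (lab in names(target_freqs)) {
    if (counts[[lab]] == 0) next
    idx <- which(labels == lab)
    if (length(idx) == 0)
      stop("no candidate patients with behavior '", lab, "' in the pool")
    replace <- length(idx) < counts[[lab]]
    if (replace)
      message("stratum '", lab, "' smaller than target; sampling with replacement")
    out <- c(out, pool[sample(idx, counts[[lab]], replace = replace)])
  }
  for (i in seq_along(out)) out[[i]]$id <- i
  structure(list(patients = out, target_freqs = target_freqs),
            class = "virtual_population")
}

#' Generate a virtual BV+ patient population
#'
#' Runs the full protocol: Latin Hypercube Sample a base pool of resident
#' parameter sets, keep the BV+ candidates (stable nAB-dominant state
#' exists) whose equilibrium behavior is among the target labels, and
#' resample to the target distribution.
#'
#' @param pool_size Base pool size (LHS draws).
#' @param n Final population size.
#' @param ranges Sampling ranges, default [default_ranges()].
#' @param target_freqs Target behavior distribution.
#' @param seed Integer seed (drives both the LHS and the resampling).
#' @param centroids Centroid matrix.
#' @param inoculum Detection-floor abundance for species absent from the
#'   equilibrium (see [virtual_patient()]).
#' @return A `virtual_population`.
#' @examples
#' pop <- generate_population(pool_size = 300, n = 50, seed = 1)
#' pop
#' @export
generate_population <- function(pool_size = 30000, n = 2000,
                                ranges = default_ranges(),
                                target_freqs = hmp_target_frequencies(),
                                seed = NULL, centroids = default_centroids(),
                                inoculum = 0.01) {
  draws <- lhs_sample(ranges, pool_size, seed = seed)
  pool <- vector("list", pool_size)
  kept <- 0
  for (i in seq_len(pool_size)) {
    pat <- suppressWarnings(virtual_patient(draws[i, ], id = i,
                                            centroids = centroids,
                                            inoculum = inoculum))
    if (!is.null(pat) && pat$behavior %in% names(target_freqs)) {
      kept <- kept + 1
      pool[[kept]] <- pat
    }
  }
  pool <- pool[seq_len(kept)]
  resample_population(pool, target_freqs, n = n,
                      seed = if (is.null(seed)) NULL else seed + 1L)
}

#' @export
print.virtual_population <- function(x, ...) {
  labs <- vapply(x$patients, `[[`, "", "behavior")
  cat("virtual BV+ population:", length(x$patients), "patients\n")
  print(table(labs))
  invisible(x)
}

#' @export
length.virtual_population <- function(x) length(x$patients)
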