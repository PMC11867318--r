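#' Sampling ranges for candidate probiotic strains
#'
#' Same numeric bounds as the resident-population ranges — growth
#' U\[0.1, 1\], self-interaction U\[-0.04, -0.004\], interspecies terms
#' U\[-0.10, 0.10\] — with the single constraint that the probiotic's
#' inhibition of nAB (`alpha_P_to_nAB`) is restricted to be negative.
#'
#' @return Data frame with `parameter`, `lower`, `upper`.
#' @export
strain_ranges <- function() {
  data.frame(
    parameter = probiotic_parameters(),
    lower = c(0.1, -0.04, rep(-0.10, 6)),
    upper = c(1.0, -0.004, 0.10, 0.10, 0.10, 0, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Screen a library of LHS-sampled candidate probiotic strains
#'
#' Samples `n_strains` candidate strains by Latin Hypercube Sampling from
#' [strain_ranges()], evaluates each across the whole population under
#' the given regimen, and assigns each strain a modal response class: the
#' response type occurring at the highest frequency across patients at the
#' final evaluation timepoint (ties broken toward nAB, then Li, oLB, P).
#'
#' @param population A `virtual_population`.
#' @param regimen A [make_regimen()] object (short-term or Lactin-V).
#' @param n_strains Number of candidate strains (500 in the full screen).
#' @param seed Integer seed for the strain LHS.
#' @param centroids Centroid matrix.
#' @return A `screen_result`: list with `strains` (list of strains),
#'   `parameters` (n_strains x 8 matrix), `profiles` (list of
#'   `response_profile`), `fractions` (n_strains x 4 matrix at the final
#'   timepoint), `modal_class` (factor), `failure_12wk`/`failure_24wk`
#'   (for Lactin-V regimens).
#' @export
screen_strains <- function(population, regimen, n_strains = 500, seed = NULL,
                           centroids = default_centroids()) {
  draws <- lhs_sample(strain_ranges(), n_strains, seed = seed)
  strains <- lapply(seq_len(n_strains), function(i) {
    st <- do.call(make_strain, c(list(name = NULL), as.list(draws[i, ])))
    st$name <- paste0("lhs_", i)
    st
  })
  profiles <- lapply(strains, evaluate_regimen, population = population,
                     regimen = regimen, centroids = centroids)
  i0 <- length(regimen$eval_times)
  frac <- t(vapply(profiles, function(p) p$fractions[i0, ],
                   numeric(nrow(centroids))))
  # a strain whose every patient simulation failed has no profile
  modal <- apply(frac, 1, function(f)
    if (all(is.finite(f))) colnames(frac)[which.max(f)] else NA_character_)
  res <- list(strains = strains, parameters = as.matrix(draws),
              profiles = profiles, fractions = frac,
              modal_class = factor(modal, levels = rownames(centroids)),
              regimen = regimen$name)
  if (all(c(84, 168) %in% regimen$eval_times)) {
    res$failure_12wk <- vapply(profiles, function(p)
      p$fractions[match(84, p$eval_times), "nAB"], 0)
    res$failure_24wk <- vapply(profiles, function(p)
      p$fractions[match(168, p$eval_times), "nAB"], 0)
  }
  structure(res, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("probiotic strain screen:", length(x$strains), "strains, regimen '",
      x$regimen, "'\n")
  cat("modal response classes:\n")
  print(table(x$modal_class))
  invisible(x)
}

#' PLS-DA of strain parameters against modal response class
#'
#' Fits a two-block partial least squares discriminant analysis relating
#' the 8 strain parameters to the modal response classes, and reports the
#' cross-validated classification rate (maximum-distance prediction).
#'
#' @param strain_parameters Numeric matrix, strains x parameters.
#' @param modal_classes Factor/character of per-strain classes (>= 2
#'   distinct classes required).
#' @param ncomp Number of latent variables (default 2).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `loadings` (parameter x LV), `scores` (strain x LV),
#'   `cv_accuracy`, and the underlying `model`.
#' @export
fit_plsda <- function(strain_parameters, modal_classes, ncomp = 2,
                      n_folds = 10, seed = NULL) {
  X <- as.matrix(strain_parameters)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  y <- factor(as.character(modal_classes))
  if (nlevels(y) < 2) stop("PLS-DA needs at least 2 response classes")
  fit <- mixOmics::plsda(X, y, ncomp = ncomp)
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = nrow(X)))
  ok <- 0; tot <- 0
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (nlevels(droplevels(y[tr])) < 2) next
    m <- mixOmics::plsda(X[tr, , drop = FALSE], droplevels(y[tr]),
                         ncomp = ncomp)
    pr <- predict(m, X[!tr, , drop = FALSE])
    cls <- pr$class$max.dist[, ncomp]
    ok <- ok + sum(cls == as.character(y[!tr]))
    tot <- tot + sum(!tr)
  }
  list(loadings = fit$loadings$X, scores = fit$variates$X,
       cv_accuracy = if (tot > 0) ok / tot else NA_real_, model = fit)
}

#' Select strains best matching clinical recurrence rates
#'
#' Ranks the screened strains by the sum of absolute distances between
#' their predicted 12- and 24-week failure rates and the clinically
#' observed recurrence rates, and returns the top `k`. Defaults are the
#' Lactin-V phase 2b treatment-arm recurrences (34.6% at 12 weeks, 48.4%
#' at 24 weeks).
#'
#' @param screen A `screen_result` evaluated under the Lactin-V regimen.
#' @param clinical_rates Named vector with `wk12` and `wk24` fractions.
#' @param k Number of strains to return.
#' @return List with `strains` (the k best), `index`, and `distance`
#'   (sorted, all strains).
#' @export
select_best_fit_strains <- function(screen,
                                    clinical_rates = c(wk12 = 0.346,
                                                       wk24 = 0.484),
                                    k = 5) {
  if (is.null(screen$failure_12wk))
    stop("screen must be run under the lactin_v regimen (12/24-week rates)")
  if (k > length(screen$strains)) stop("k exceeds the number of strains")
  d <- abs(screen$failure_12wk - clinical_rates[["wk12"]]) +
    abs(screen$failure_24wk - clinical_rates[["wk24"]])
  o <- order(d)
  list(strains = screen$strains[o[seq_len(k)]], index = o[seq_len(k)],
       distance = d[o])
}
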