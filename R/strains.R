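#' Construct a probiotic strain
#'
#' A strain is the set of 8 parameters coupling the probiotic `P` into the
#' community: its growth rate `kgrow_P`, its self-interaction
#' `alpha_P_to_P`, how each resident affects it (`alpha_nAB_to_P`,
#' `alpha_Li_to_P`, `alpha_oLB_to_P`) and how it affects each resident
#' (`alpha_P_to_nAB`, `alpha_P_to_Li`, `alpha_P_to_oLB`).
#'
#' Named library strains (pass `name`):
#' \describe{
#'   \item{`null`}{moderate growth (0.5 d^-1), moderate self-interaction
#'     (-0.022), all six cross terms 0 — no coupling with the residents.}
#'   \item{`traditional`}{null plus inhibition of nAB,
#'     `alpha_P_to_nAB = -0.01`.}
#'   \item{`1p_best`}{null plus `alpha_nAB_to_P = +0.01` (nAB facilitates P).}
#'   \item{`2p_best`}{`alpha_nAB_to_P = +0.01` and `alpha_P_to_nAB = -0.01`.}
#'   \item{`3p_best`}{2p_best plus growth increment, `kgrow_P = 0.51`.}
#'   \item{`2p_counter`}{`alpha_nAB_to_P = -0.01` and
#'     `alpha_P_to_nAB = -0.01` (mutual antagonism with nAB).}
#'   \item{`1p_oLB`, `2p_oLB`, `3p_oLB`}{oLB-boosting designs:
#'     `+0.05 alpha_P_to_oLB`; plus `-0.05 alpha_P_to_nAB`; plus
#'     `-0.05 alpha_P_to_Li`.}
#'   \item{`traditional_lv`}{Lactin-V positive control,
#'     `alpha_P_to_nAB = -0.012`.}
#'   \item{`moderate`}{strong inhibition of nAB (`alpha_P_to_nAB = -0.012`),
#'     weak antagonism of nAB on P (`alpha_nAB_to_P = -0.006`), strong
#'     competition with resident *Lactobacillus* (all four Li/oLB cross
#'     terms at `competition`).}
#'   \item{`bad`}{negative control: weak inhibition of nAB
#'     (`alpha_P_to_nAB = -0.006`), strong antagonism of nAB on P
#'     (`alpha_nAB_to_P = -0.012`), same strong *Lactobacillus*
#'     competition.}
#' }
#'
#' @param name Library strain name, or `NULL` to start from the null strain.
#' @param ... Parameter overrides by name (e.g. `alpha_P_to_nAB = -0.02`).
#' @param competition Strength of the symmetric Li/oLB competition terms
#'   used by the `moderate` and `bad` strains (3x the -0.012 anchor by
#'   default).
#' @return An object of class `probiotic_strain` (named list of the 8
#'   parameters plus `name`).
#' @examples
#' make_strain("traditional")
#' make_strain("null", alpha_P_to_oLB = 0.05)
#' @export
make_strain <- function(name = NULL, ..., competition = -0.036) {
  null <- list(kgrow_P = 0.5, alpha_P_to_P = -0.022,
               alpha_nAB_to_P = 0, alpha_Li_to_P = 0, alpha_oLB_to_P = 0,
               alpha_P_to_nAB = 0, alpha_P_to_Li = 0, alpha_P_to_oLB = 0)
  lacto_comp <- list(alpha_Li_to_P = competition, alpha_oLB_to_P = competition,
                     alpha_P_to_Li = competition, alpha_P_to_oLB = competition)
  lib <- list(
    null = list(),
    traditional = list(alpha_P_to_nAB = -0.01),
    `1p_best` = list(alpha_nAB_to_P = 0.01),
    `2p_best` = list(alpha_nAB_to_P = 0.01, alpha_P_to_nAB = -0.01),
    `3p_best` = list(alpha_nAB_to_P = 0.01, alpha_P_to_nAB = -0.01,
                     kgrow_P = 0.51),
    `2p_counter` = list(alpha_nAB_to_P = -0.01, alpha_P_to_nAB = -0.01),
    `1p_oLB` = list(alpha_P_to_oLB = 0.05),
    `2p_oLB` = list(alpha_P_to_oLB = 0.05, alpha_P_to_nAB = -0.05),
    `3p_oLB` = list(alpha_P_to_oLB = 0.05, alpha_P_to_nAB = -0.05,
                    alpha_P_to_Li = -0.05),
    traditional_lv = list(alpha_P_to_nAB = -0.012),
    moderate = c(list(alpha_P_to_nAB = -0.012, alpha_nAB_to_P = -0.006),
                 lacto_comp),
    bad = c(list(alpha_P_to_nAB = -0.006, alpha_nAB_to_P = -0.012),
            lacto_comp)
  )
  pars <- null
  if (!is.null(name)) {
    if (!name %in% names(lib))
      stop("unknown strain '", name, "'; library: ",
           paste(names(lib), collapse = ", "))
    pars[names(lib[[name]])] <- lib[[name]]
  } else {
    name <- "custom"
  }
  over <- list(...)
  bad_over <- setdiff(names(over), names(pars))
  if (length(bad_over))
    stop("unknown strain parameter(s): ", paste(bad_over, collapse = ", "))
  pars[names(over)] <- over
  if (pars$kgrow_P > 0 && pars$alpha_P_to_P >= 0)
    stop("alpha_P_to_P must be negative when kgrow_P > 0")
  structure(c(pars, list(name = name)), class = "probiotic_strain")
}

#' @export
print.probiotic_strain <- function(x, ...) {
  cat("probiotic strain '", x$name, "'\n", sep = "")
  v <- unlist(x[setdiff(names(x), "name")])
  print(round(v, 4))
  invisible(x)
}

#' Modify a strain's parameters
#'
#' @param strain A `probiotic_strain`.
#' @param ... Named parameter overrides.
#' @return A new `probiotic_strain` (name suffixed with `*`).
#' @export
modify_strain <- function(strain, ...) {
  pars <- strain[c("kgrow_P", "alpha_P_to_P", "alpha_nAB_to_P",
                   "alpha_Li_to_P", "alpha_oLB_to_P", "alpha_P_to_nAB",
                   "alpha_P_to_Li", "alpha_P_to_oLB")]
  over <- list(...)
  pars[names(over)] <- over
  out <- do.call(make_strain, c(list(name = NULL), pars))
  out$name <- paste0(strain$name, "*")
  out
}

#' Names of the built-in strain library
#' @return Character vector of strain names accepted by [make_strain()].
#' @export
strain_library <- function() {
  c("null", "traditional", "1p_best", "2p_best", "3p_best", "2p_counter",
    "1p_oLB", "2p_oLB", "3p_oLB", "traditional_lv", "moderate", "bad")
}

#' Assemble full 4-species parameters from residents plus a strain
#'
#' @param resident 3-species resident [glv_params()].
#' @param strain A [make_strain()] object.
#' @return 4-species [glv_params()].
#' @export
community_params <- function(resident, strain) {
  sp <- glv_species()
  k <- c(resident$k_grow, P = strain$kgrow_P)
  A <- matrix(0, 4, 4, dimnames = list(sp, sp))
  A[1:3, 1:3] <- resident$alpha
  A["P", "P"] <- strain$alpha_P_to_P
  A["P", "nAB"] <- strain$alpha_nAB_to_P
  A["P", "Li"] <- strain$alpha_Li_to_P
  A["P", "oLB"] <- strain$alpha_oLB_to_P
  A["nAB", "P"] <- strain$alpha_P_to_nAB
  A["Li", "P"] <- strain$alpha_P_to_Li
  A["oLB", "P"] <- strain$alpha_P_to_oLB
  glv_params(k, A, species = sp)
}
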