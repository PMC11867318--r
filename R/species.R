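#' Species order of the community model
#'
#' The community model tracks four populations in a fixed order:
#' non-optimal anaerobic bacteria (`nAB`, the BV-associated group),
#' *Lactobacillus iners* (`Li`), optimal *Lactobacillus* spp. (`oLB`,
#' *L. crispatus*/*gasseri*/*jensenii*), and the probiotic strain (`P`).
#' This order is fixed across every function in the package.
#'
#' @return Character vector `c("nAB", "Li", "oLB", "P")`.
#' @export
glv_species <- function() c("nAB", "Li", "oLB", "P")

# resident community = the three endogenous groups (no probiotic)
resident_species <- function() c("nAB", "Li", "oLB")
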