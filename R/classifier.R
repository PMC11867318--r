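#' Default community-state centroids
#'
#' One-hot centroids, one per species, reproducing plain dominance
#' semantics: a community is nAB-dominant when nAB has the largest relative
#' abundance, and so on. Centroid tables derived from a taxonomic
#' classifier such as VALENCIA can be substituted via [load_centroids()].
#'
#' @return A 4x4 matrix, one centroid per row, rows named by label in the
#'   tie-break priority order nAB > Li > oLB > P.
#' @export
default_centroids <- function() {
  m <- diag(4)
  dimnames(m) <- list(glv_species(), glv_species())
  m
}

#' Read a centroid table from CSV
#'
#' @param path CSV with columns `label, nAB, Li, oLB, P`; each row a
#'   centroid of relative abundances summing to 1. Row order sets the
#'   tie-break priority.
#' @return Centroid matrix usable by [classify_cst()].
#' @export
load_centroids <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(d[, glv_species()])
  rownames(m) <- d$label
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8))
    stop("centroids must be relative abundances summing to 1")
  m
}

#' Classify a community state by nearest centroid
#'
#' Converts abundances to relative abundances and returns the label of the
#' centroid at minimal Euclidean distance, a configurable stand-in for the
#' VALENCIA community-state-type classifier. With the default one-hot
#' centroids this equals the species with the largest relative abundance.
#' Ties go to the earliest centroid row (default priority
#' nAB > Li > oLB > P, so ambiguous states count as treatment failure).
#'
#' @param state Abundance 4-vector, or a matrix with one state per row.
#' @param centroids Centroid matrix, default [default_centroids()].
#' @return Character label(s).
#' @examples
#' classify_cst(c(0.7, 0.1, 0.1, 0.1))
#' @export
classify_cst <- function(state, centroids = default_centroids()) {
  x <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  tot <- rowSums(x)
  if (any(x < 0)) stop("abundances must be >= 0")
  if (any(tot <= 0)) stop("total abundance 0: composition undefined")
  rel <- x / tot
  # squared distance to each centroid; argmin with first-row tie-break
  d2 <- outer(rowSums(rel^2), rowSums(centroids^2), "+") -
    2 * rel %*% t(centroids)
  pick <- apply(d2, 1, function(r) which(r <= min(r) + 1e-12)[1])
  lab <- rownames(centroids)[pick]
  if (!is.matrix(state)) lab[1] else lab
}
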