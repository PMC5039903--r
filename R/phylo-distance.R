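#' Pairwise K80 (Kimura two-parameter) distance matrix
#'
#' Distances are computed with \code{ape::dist.dna(model = "K80")}
#' (d = 1/2 ln(1/(1-2P-Q)) + 1/4 ln(1/(1-2Q)) with P, Q the transition and
#' transversion proportions). Pairs for which the closed form is undefined
#' (saturation, or no overlapping sites) are flagged and capped.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}} or character
#'   matrix; intended for a complete-deletion alignment.
#' @param cap Distance assigned to saturated/undefined pairs (default 5).
#' @return Symmetric numeric matrix with zero diagonal and a logical
#'   attribute \code{"saturated"} marking capped pairs.
#' @export
k80DistanceMatrix <- function(aln, cap = 5) {
  m <- if (is(aln, "RegulatoryAlignment")) alignmentMatrix(aln) else aln
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  dna <- ape::as.DNAbin(tolower(m))
  d <- as.matrix(ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE))
  sat <- !is.finite(d) | is.nan(d)
  diag(sat) <- FALSE
  if (any(sat)) {
    warning(sum(sat) / 2, " saturated/undefined pair(s) capped at ", cap)
    d[sat] <- cap
  }
  diag(d) <- 0
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining starting tree
#'
#' Standard NJ agglomeration (\code{ape::nj}); negative branch lengths,
#' which NJ can produce on non-additive matrices, are clamped to zero with
#' a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal, >= 3 taxa.
#' @return Unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("NJ needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}
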