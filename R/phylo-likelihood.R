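#' HKY85 + discrete-gamma model parameters
#'
#' The rate matrix built from \code{kappa} and \code{baseFreqs} is
#' normalised to one expected substitution per unit branch length; the
#' gamma rate categories are the means of \code{nCategories}
#' equal-probability bins of a Gamma(shape = alpha, rate = alpha)
#' distribution and average 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param baseFreqs Equilibrium frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape for among-site rate variation (> 0);
#'   \code{Inf} means rate homogeneity.
#' @param nCategories Number of discrete rate categories (default 4).
#' @return A list of class \code{HKYParams}.
#' @export
hkyParams <- function(kappa = 2, baseFreqs = rep(0.25, 4), alpha = 1,
                      nCategories = 4L) {
  stopifnot(kappa > 0, alpha > 0, nCategories >= 1,
            length(baseFreqs) == 4L, all(baseFreqs >= 0),
            abs(sum(baseFreqs) - 1) < 1e-8)
  structure(list(kappa = kappa, baseFreqs = baseFreqs, alpha = alpha,
                 nCategories = as.integer(nCategories)),
            class = "HKYParams")
}

#' Mean rates of equal-probability discrete-gamma categories
#'
#' @param alpha Gamma shape (> 0, may be \code{Inf}).
#' @param k Number of categories.
#' @return Numeric vector of length \code{k}, mean exactly 1.
#' @export
discreteGammaRates <- function(alpha, k = 4L) {
  if (is.infinite(alpha)) return(rep(1, k))
  stopifnot(alpha > 0, k >= 1)
  if (k == 1L) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # mean of each bin via the shape+1 incomplete-gamma identity
  r <- k * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

#' HKY85 transition-probability matrix (closed form)
#'
#' The TN93 analytic solution specialised to a single
#' transition/transversion ratio, with the rate matrix normalised to one
#' expected substitution per unit time. Row = ancestral state, column =
#' descendant state, order A, C, G, T.
#'
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param pi Equilibrium frequencies (A, C, G, T).
#' @param kappa Transition/transversion rate ratio.
#' @param rate Optional rate multiplier (gamma category rate).
#' @return 4x4 stochastic matrix.
#' @export
hkyTransitionProbs <- function(t, pi, kappa, rate = 1) {
  stopifnot(t >= 0, is.finite(t))
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  beta <- 1 / (2 * (kappa * (piA * piG + piC * piT) + piR * piY))
  alphaR <- kappa * beta
  tt <- t * rate
  e2 <- exp(-beta * tt)
  eR <- exp(-(piR * alphaR + piY * beta) * tt)
  eY <- exp(-(piY * alphaR + piR * beta) * tt)
  P <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  P["A","A"] <- piA + piA * piY / piR * e2 + piG / piR * eR
  P["A","G"] <- piG + piG * piY / piR * e2 - piG / piR * eR
  P["G","A"] <- piA + piA * piY / piR * e2 - piA / piR * eR
  P["G","G"] <- piG + piG * piY / piR * e2 + piA / piR * eR
  P["C","C"] <- piC + piC * piR / piY * e2 + piT / piY * eY
  P["C","T"] <- piT + piT * piR / piY * e2 - piT / piY * eY
  P["T","C"] <- piC + piC * piR / piY * e2 - piC / piY * eY
  P["T","T"] <- piT + piT * piR / piY * e2 + piC / piY * eY
  P["A","C"] <- P["G","C"] <- piC * (1 - e2)
  P["A","T"] <- P["G","T"] <- piT * (1 - e2)
  P["C","A"] <- P["T","A"] <- piA * (1 - e2)
  P["C","G"] <- P["T","G"] <- piG * (1 - e2)
  P
}

# --- internal alignment/tree plumbing for the likelihood ----------------

BASE4 <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# pattern-compress a character matrix (rows = taxa) restricted to tipOrder;
# returns integer matrix (taxa x patterns, 0-based states) + weights
compressPatterns <- function(m, tipOrder) {
  m <- m[tipOrder, , drop = FALSE]
  key <- apply(m, 2L, paste, collapse = "")
  tab <- table(key)
  pats <- names(tab)
  states <- vapply(strsplit(pats, "", fixed = TRUE),
                   function(ch) {
                     s <- BASE4[ch]
                     s[is.na(s)] <- 0L   # missing/ambiguous -> uninformative
                     as.integer(s) - 1L
                   }, integer(nrow(m)))
  if (is.null(dim(states))) states <- matrix(states, nrow = nrow(m))
  list(states = states, weights = as.numeric(tab))
}

empiricalBaseFreqs <- function(m) {
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(m == b), numeric(1))
  counts / sum(counts)
}

# tree prepared for pruning: postorder edges, root id
prepTree <- function(tree, tipOrder) {
  tree <- ape::reorder.phylo(tree, "postorder")
  idx <- match(tipOrder, tree$tip.label)
  if (anyNA(idx)) stop("tree tips do not match alignment ids")
  list(tree = tree, tipIndex = idx,
       root = length(tree$tip.label) + 1L)
}

# P arrays for all edges x categories, flattened for the C++ kernel;
# same closed form as hkyTransitionProbs, vectorised over (edge, category)
edgePArray <- function(tree, params) {
  rates <- discreteGammaRates(params$alpha, params$nCategories)
  bl <- tree$edge.length
  if (any(!is.finite(bl)) || any(bl < 0))
    stop("non-finite or negative branch length")
  pi <- params$baseFreqs; kappa <- params$kappa
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  piR <- piA + piG; piY <- piC + piT
  beta <- 1 / (2 * (kappa * (piA * piG + piC * piT) + piR * piY))
  tt <- as.vector(outer(bl, rates))      # edge index fastest, per category
  e2 <- exp(-beta * tt)
  eR <- exp(-(piR * kappa * beta + piY * beta) * tt)
  eY <- exp(-(piY * kappa * beta + piR * beta) * tt)
  P <- matrix(0, 16L, length(tt))        # each column: 4x4 in column-major
  P[1L, ] <- piA + piA * piY / piR * e2 + piG / piR * eR   # A->A
  P[3L, ] <- piA + piA * piY / piR * e2 - piA / piR * eR   # G->A
  P[2L, ] <- P[4L, ] <- piA * (1 - e2)                     # C,T->A
  P[6L, ] <- piC + piC * piR / piY * e2 + piT / piY * eY   # C->C
  P[8L, ] <- piC + piC * piR / piY * e2 - piC / piY * eY   # T->C
  P[5L, ] <- P[7L, ] <- piC * (1 - e2)                     # A,G->C
  P[11L, ] <- piG + piG * piY / piR * e2 + piA / piR * eR  # G->G
  P[9L, ] <- piG + piG * piY / piR * e2 - piG / piR * eR   # A->G
  P[10L, ] <- P[12L, ] <- piG * (1 - e2)                   # C,T->G
  P[16L, ] <- piT + piT * piR / piY * e2 + piC / piY * eY  # T->T
  P[14L, ] <- piT + piT * piR / piY * e2 - piT / piY * eY  # C->T
  P[13L, ] <- P[15L, ] <- piT * (1 - e2)                   # A,G->T
  as.vector(P)
}

#' HKY+gamma log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over compressed site patterns, mixed over
#' equal-weight discrete-gamma rate categories. The alignment should be a
#' complete-deletion matrix (A/C/G/T only); any other character is treated
#' as missing data at that tip.
#'
#' @param tree \code{phylo} tree with branch lengths; tip labels must
#'   match the alignment ids.
#' @param aln A \code{\linkS4class{RegulatoryAlignment}} or character
#'   matrix (rows = taxa).
#' @param params An \code{\link{hkyParams}} object.
#' @return Log-likelihood (numeric scalar).
#' @export
hkyGammaLogLik <- function(tree, aln, params) {
  m <- if (is(aln, "RegulatoryAlignment")) alignmentMatrix(aln) else aln
  pt <- prepTree(tree, rownames(m))
  cp <- compressPatterns(m, rownames(m))
  # tipStates rows must be ordered by the tree's tip numbering (1..nTip)
  states <- matrix(0L, nrow(m), ncol(cp$states))
  states[pt$tipIndex, ] <- cp$states
  .pruningLogLik(pt$tree$edge, states, edgePArray(pt$tree, params),
                 params$baseFreqs, cp$weights,
                 nNode = length(pt$tree$tip.label) + pt$tree$Nnode,
                 root = pt$root, nCat = params$nCategories)
}

# fast path used by the search: patterns precomputed once
logLikFromPrep <- function(tree, prep, params) {
  pt <- prepTree(tree, prep$tipOrder)
  states <- matrix(0L, length(prep$tipOrder), ncol(prep$states))
  states[pt$tipIndex, ] <- prep$states
  .pruningLogLik(pt$tree$edge, states, edgePArray(pt$tree, params),
                 params$baseFreqs, prep$weights,
                 nNode = length(pt$tree$tip.label) + pt$tree$Nnode,
                 root = pt$root, nCat = params$nCategories)
}
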