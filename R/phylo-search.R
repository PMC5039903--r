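# ---- tree utilities ----------------------------------------------------

minBL <- 1e-8
maxBL <- 10

# complete-deletion character matrix from whatever the user hands us
cdMatrix <- function(aln) {
  if (is(aln, "RegulatoryAlignment")) {
    m <- alignmentMatrix(aln)
    if (!all(m %in% c("A", "C", "G", "T")))
      m <- alignmentMatrix(completeDeletion(aln)@trimmed)
    m
  } else {
    stopifnot(is.matrix(aln))
    aln
  }
}

# tip-label sets below each internal edge; canonical bipartition keys
splitKeys <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tree$tip.label)
  desc <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  ref <- sort(tree$tip.label)[1L]
  keys <- character(0); nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= nTip) next
    side <- desc[[ch]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > nTip - 2L) next  # trivial
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  list(keys = keys, nodes = nodes)
}

# the two NNI rearrangements around one internal edge (edge row index);
# branch lengths travel with their child subtree. Returns the candidate
# trees plus the edge rows local re-optimisation should touch.
nniCandidates <- function(tree, edgeRow) {
  u <- tree$edge[edgeRow, 1L]; v <- tree$edge[edgeRow, 2L]
  nTip <- length(tree$tip.label)
  if (v <= nTip) return(list())
  vKids <- which(tree$edge[, 1L] == v)
  uKids <- setdiff(which(tree$edge[, 1L] == u), edgeRow)
  if (length(vKids) < 2L || length(uKids) < 1L) return(list())
  a <- uKids[1L]
  local <- unique(c(edgeRow, a, vKids,
                    which(tree$edge[, 2L] == u)))
  lapply(vKids[1:2], function(cRow) {
    tr <- tree
    tr$edge[a, 1L] <- v
    tr$edge[cRow, 1L] <- u
    list(tree = tr, rows = local)
  })
}

#' All nearest-neighbor-interchange rearrangements of a tree
#'
#' @param tree An (unrooted) \code{phylo} tree.
#' @return List of \code{phylo} trees, two per internal edge.
#' @export
nniNeighbors <- function(tree) {
  lapply(.nniMoves(tree), `[[`, "tree")
}

.nniMoves <- function(tree) {
  nTip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2L] > nTip)
  out <- list()
  for (e in internal) out <- c(out, nniCandidates(tree, e))
  out
}

# ---- maximum-likelihood search -----------------------------------------

optimizeBranchLengths <- function(tree, prep, params, brentTol = 1e-6,
                                  rows = seq_len(nrow(tree$edge))) {
  cur <- logLikFromPrep(tree, prep, params)
  for (e in rows) {
    f <- function(t) {
      tree$edge.length[e] <- t
      logLikFromPrep(tree, prep, params)
    }
    opt <- optimize(f, c(minBL, maxBL), maximum = TRUE, tol = brentTol)
    if (opt$objective >= cur) {
      tree$edge.length[e] <- opt$maximum
      cur <- opt$objective
    }
  }
  tree
}

optimizeScalarParam <- function(tree, prep, params, what, interval,
                               tol = 1e-4) {
  f <- function(x) {
    params[[what]] <- exp(x)
    logLikFromPrep(tree, prep, params)
  }
  opt <- optimize(f, log(interval), maximum = TRUE, tol = tol)
  params[[what]] <- exp(opt$maximum)
  params
}

nniSweep <- function(tree, prep, params, brentTol = 1e-3) {
  improved <- TRUE
  ll <- logLikFromPrep(tree, prep, params)
  while (improved) {
    improved <- FALSE
    for (move in .nniMoves(tree)) {
      cand <- optimizeBranchLengths(move$tree, prep, params, brentTol,
                                    rows = move$rows)
      llc <- logLikFromPrep(cand, prep, params)
      if (llc > ll + 1e-9) {
        # accepted move: polish all branch lengths before continuing
        tree <- optimizeBranchLengths(cand, prep, params, brentTol)
        ll <- logLikFromPrep(tree, prep, params)
        improved <- TRUE
        break   # restart the sweep from the improved tree
      }
    }
  }
  list(tree = tree, logLik = ll)
}

#' Fit a maximum-likelihood HKY+gamma tree
#'
#' Starts from a neighbor-joining tree on K80 distances (or
#' \code{init}), then alternates (a) per-branch length optimisation by
#' bounded Brent search, (b) bounded 1-D searches for kappa and, unless
#' fixed, the gamma shape alpha, and (c) NNI sweeps accepting improvements,
#' until a full cycle improves the log-likelihood by less than \code{tol}.
#' Base frequencies are the empirical counts of the complete-deletion
#' matrix.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}} (complete deletion
#'   is applied if needed) or an A/C/G/T character matrix.
#' @param init Optional starting \code{phylo} tree.
#' @param fixedAlpha If non-NULL, the gamma shape is held at this value
#'   instead of being optimised.
#' @param nCategories Discrete-gamma categories (default 4).
#' @param kappaInit,alphaInit Starting values for the 1-D searches.
#' @param maxCycles Maximum optimisation cycles (default 20).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-4).
#' @param optimizeTopology Set \code{FALSE} to keep the starting topology.
#' @return An \code{\linkS4class{MLFit}}.
#' @export
fitMLTree <- function(aln, init = NULL, fixedAlpha = NULL, nCategories = 4L,
                      kappaInit = 2, alphaInit = 1, maxCycles = 20L,
                      tol = 1e-4, optimizeTopology = TRUE) {
  m <- cdMatrix(aln)
  if (nrow(m) < 4L) stop("ML tree search needs at least 4 taxa")
  cp <- compressPatterns(m, rownames(m))
  prep <- list(states = cp$states, weights = cp$weights,
               tipOrder = rownames(m))
  params <- hkyParams(kappa = kappaInit, baseFreqs = empiricalBaseFreqs(m),
                      alpha = if (is.null(fixedAlpha)) alphaInit else fixedAlpha,
                      nCategories = nCategories)
  tree <- if (is.null(init)) njTree(k80DistanceMatrix(m)) else init
  tree <- ape::unroot(tree)
  tree$edge.length <- pmax(tree$edge.length, minBL)
  ll <- logLikFromPrep(tree, prep, params)
  converged <- FALSE
  for (cycle in seq_len(maxCycles)) {
    llPrev <- ll
    tree <- optimizeBranchLengths(tree, prep, params)
    params <- optimizeScalarParam(tree, prep, params, "kappa", c(0.05, 100))
    if (is.null(fixedAlpha))
      params <- optimizeScalarParam(tree, prep, params, "alpha", c(0.05, 50))
    if (optimizeTopology) {
      sw <- nniSweep(tree, prep, params)
      tree <- sw$tree
    }
    ll <- logLikFromPrep(tree, prep, params)
    if (ll - llPrev < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ML search did not converge in ", maxCycles,
            " cycles; returning best tree so far")
  new("MLFit", tree = tree, params = unclass(params), logLik = ll,
      nSitesUsed = ncol(m), converged = converged)
}

#' Nonparametric bootstrap support for an ML tree
#'
#' Resamples alignment columns with replacement, refits each replicate
#' (branch lengths + NNI, starting from the reference ML tree, with the
#' fitted substitution parameters held fixed), and reports for every
#' internal split of the reference tree the percentage of replicates that
#' contain it.
#'
#' @param aln The alignment used for the fit (complete deletion is applied
#'   if needed).
#' @param fit The reference \code{\linkS4class{MLFit}}.
#' @param nReplicates Number of bootstrap replicates (>= 1).
#' @param seed RNG seed (mandatory: replicate resampling must be
#'   reproducible).
#' @return List with \code{tree} (the reference tree with support
#'   percentages as internal node labels), \code{supports} (data.frame:
#'   split key, support), \code{replicates} (data.frame: replicate index,
#'   refitted tree as newick — the bootstrap log), and \code{nReplicates}.
#' @export
bootstrapSupport <- function(aln, fit, nReplicates = 100L, seed) {
  if (missing(seed)) stop("bootstrapSupport requires an explicit seed")
  nReplicates <- as.integer(nReplicates)
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  m <- cdMatrix(aln)
  params <- do.call(hkyParams, fit@params[c("kappa", "baseFreqs", "alpha",
                                            "nCategories")])
  refSplits <- splitKeys(fit@tree)
  counts <- setNames(integer(length(refSplits$keys)), refSplits$keys)
  repTrees <- character(nReplicates)
  set.seed(seed)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    mr <- m[, cols, drop = FALSE]
    cp <- compressPatterns(mr, rownames(mr))
    prep <- list(states = cp$states, weights = cp$weights,
                 tipOrder = rownames(mr))
    tr <- fit@tree
    tr <- optimizeBranchLengths(tr, prep, params, brentTol = 1e-3)
    tr <- nniSweep(tr, prep, params)$tree
    got <- splitKeys(tr)$keys
    hit <- refSplits$keys %in% got
    counts[hit] <- counts[hit] + 1L
    trOut <- tr
    trOut$edge.length <- round(trOut$edge.length, 6)
    repTrees[r] <- ape::write.tree(trOut)
  }
  support <- 100 * counts / nReplicates
  tree <- fit@tree
  nTip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  labels[refSplits$nodes - nTip] <- sprintf("%g", support)
  tree$node.label <- labels
  list(tree = tree,
       supports = data.frame(split = refSplits$keys, support = unname(support),
                             row.names = NULL),
       replicates = data.frame(replicate = seq_len(nReplicates),
                               newick = repTrees, row.names = NULL),
       nReplicates = nReplicates)
}

# ---- newick round-trip -------------------------------------------------

#' Read a newick tree
#' @param path File path (or a newick string via \code{text}).
#' @param text Optional newick string instead of a file.
#' @return \code{phylo} tree.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick input")
  tr
}

#' Write a tree as newick (branch lengths rounded to 6 decimals,
#' supports as internal node labels)
#' @param tree \code{phylo} tree.
#' @param path Output path.
#' @export
writeNewick <- function(tree, path) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
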