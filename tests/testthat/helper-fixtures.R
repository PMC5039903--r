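# small in-code fixture builders shared across the suite

`%or%` <- function(a, b) if (is.null(a)) b else a

mkMeta <- function(ids, group = "Haplorhini", behavior = "Diurnal",
                   species = ids) {
  data.frame(id = ids, species = species,
             group = rep_len(group, length(ids)),
             behavior = rep_len(behavior, length(ids)),
             stringsAsFactors = FALSE)
}

# alignment from a named character vector of equal-length strings
mkAln <- function(seqs, groups = NULL, behaviors = NULL) {
  ids <- names(seqs)
  md <- mkMeta(ids,
               group = groups %or% rep("Haplorhini", length(ids)),
               behavior = behaviors %or% rep("Diurnal", length(ids)))
  validateAlignment(seqs, md)
}

# random gap-free alignment with given gap columns overridden
randomAln <- function(nseq, ncol, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), nseq * ncol, replace = TRUE),
              nseq, ncol)
  rownames(m) <- sprintf("s%02d", seq_len(nseq))
  m
}

alnFromMatrix <- function(m, groups = NULL, behaviors = NULL) {
  seqs <- setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  mkAln(seqs, groups = groups, behaviors = behaviors)
}

# the published per-species GC percentages (one decimal) used by the
# group-contrast checks
speciesGCTable <- function() {
  c(Human = 58.5, Per1Ai = 58.6, Chimp = 58.6, Gorilla = 58.1,
    Orangutan = 58.9, Gibbon = 58.8, Macaque = 58.6, Per1Marmoset = 57.3,
    Per1Owl = 57.7, Tarsier = 57.4, Per1RL = 58.8, Per1GG = 54.8,
    Bushbaby = 54.9, Per1LG = 55.5, Mouse = 53.9)
}

# brute-force HKY+gamma likelihood by explicit summation over all
# internal-node state assignments (independent oracle for the pruning)
bruteForceLogLik <- function(tree, m, params) {
  tree <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  rates <- discreteGammaRates(params$alpha, params$nCategories)
  Plist <- lapply(rates, function(r)
    lapply(seq_len(nrow(tree$edge)), function(e)
      hkyTransitionProbs(tree$edge.length[e], params$baseFreqs,
                         params$kappa, r)))
  states <- match(m, c("A", "C", "G", "T"))
  dim(states) <- dim(m)
  intN <- (nTip + 1L):nNode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(intN))))
  tipIdx <- match(rownames(m), tree$tip.label)
  ll <- 0
  for (s in seq_len(ncol(m))) {
    Ls <- 0
    for (ci in seq_along(rates)) {
      for (gi in seq_len(nrow(grid))) {
        asn <- integer(nNode)
        asn[tipIdx] <- states[, s]
        asn[intN] <- grid[gi, ]
        pr <- params$baseFreqs[asn[nTip + 1L]]
        for (e in seq_len(nrow(tree$edge))) {
          pr <- pr * Plist[[ci]][[e]][asn[tree$edge[e, 1L]],
                                      asn[tree$edge[e, 2L]]]
          if (pr == 0) break
        }
        Ls <- Ls + pr / length(rates)
      }
    }
    ll <- ll + log(Ls)
  }
  ll
}

# random bifurcating tree with exponential branch lengths
randomTree <- function(nTip, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTip, br = function(n) stats::rexp(n, 8))
  tr$tip.label <- sprintf("t%d", seq_len(nTip))
  tr
}

# six-taxon strong-signal simulation shared by the phylogeny checks
strongSignalSim <- function(seed = 7, length = 5000L) {
  md <- mkMeta(LETTERS[1:6],
               group = rep(c("Haplorhini", "Strepsirrhini"), each = 3),
               behavior = rep(c("Diurnal", "Nocturnal"), each = 3))
  nwk <- "((A:0.08,B:0.08):0.06,(C:0.08,D:0.08):0.06,(E:0.12,F:0.12):0.06);"
  cfg <- simulationConfig(tree = nwk, metadata = md, length = length,
                          kappa = 3, alpha = 1.9765, seed = seed)
  list(sim = simulateAlignment(cfg), newick = nwk, metadata = md)
}
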