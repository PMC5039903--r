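# --- distances and NJ ---------------------------------------------------

test_that("K80 distances match the closed form and flag saturation", {
  m <- matrix("A", 2, 20, dimnames = list(c("x", "y"), NULL))
  m[1, ] <- c(rep("A", 10), rep("C", 10))
  m[2, ] <- m[1, ]
  expect_equal(unname(k80DistanceMatrix(m)["x", "y"]), 0)

  # 20 sites, 2 transitions (A->G), 1 transversion (A->T): P=0.1, Q=0.05
  m[2, 1:2] <- "G"
  m[2, 11] <- "A"   # C->A is a transversion
  d <- k80DistanceMatrix(m)
  expect_equal(unname(d["x", "y"]), 0.17018, tolerance = 1e-4)

  # saturated pair: log argument <= 0
  s <- matrix(c(rep(c("A", "G"), 10), rep(c("G", "A"), 10)), 2, 20,
              byrow = TRUE, dimnames = list(c("x", "y"), NULL))
  ds <- suppressWarnings(k80DistanceMatrix(s))
  expect_equal(unname(ds["x", "y"]), 5)
  expect_true(attr(ds, "saturated")["x", "y"])
})

test_that("NJ is exact on an additive matrix and clamps negatives", {
  # tree ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(d)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d),
                                                           colnames(d)]),
               unname(d), tolerance = 1e-9)
  # split AB|CD present
  keys <- cisScan:::splitKeys(tr)$keys
  expect_true(any(vapply(keys, function(k)
    setequal(strsplit(k, "|", fixed = TRUE)[[1]], c("C", "D")) ||
      setequal(strsplit(k, "|", fixed = TRUE)[[1]], c("A", "B")), TRUE)))

  # all-equal off-diagonals resolve with zero internal length
  de <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(de) <- 0
  tre <- njTree(de)
  internal <- tre$edge[, 2] > length(tre$tip.label)
  expect_true(all(abs(tre$edge.length[internal]) < 1e-12))

  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

# --- likelihood ---------------------------------------------------------

test_that("two-taxon likelihood limits match closed forms", {
  # zero-distance limit: identical single site -> ln(1/4)
  tr <- ape::read.tree(text = "(a:0.0000001,b:0.0000001);")
  m <- matrix("A", 2, 1, dimnames = list(c("a", "b"), NULL))
  pm <- hkyParams(kappa = 1, baseFreqs = rep(0.25, 4), alpha = Inf,
                  nCategories = 1)
  expect_equal(hkyGammaLogLik(tr, m, pm), log(0.25), tolerance = 1e-6)

  # kappa=1, equal frequencies, no rate variation == JC69 closed form
  d <- 0.17
  tr2 <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  m2 <- matrix(c("A", "A", "C", "C", "G", "A", "T", "C"), 2, 4,
               dimnames = list(c("a", "b"), NULL))  # 2 same, 2 different
  pSame <- 0.25 + 0.75 * exp(-4 * d / 3)
  pDiff <- 0.25 * (1 - exp(-4 * d / 3))
  expect_equal(hkyGammaLogLik(tr2, m2, pm),
               2 * log(0.25 * pSame) + 2 * log(0.25 * pDiff),
               tolerance = 1e-9)
})

test_that("pruning equals brute-force enumeration over internal states", {
  set.seed(31)
  cases <- expand.grid(nTip = 3:5, nSite = c(2, 4))
  for (k in seq_len(nrow(cases))) {
    tr <- randomTree(cases$nTip[k], seed = 100 + k)
    m <- matrix(sample(c("A", "C", "G", "T"),
                       cases$nTip[k] * cases$nSite[k], TRUE),
                cases$nTip[k], cases$nSite[k],
                dimnames = list(tr$tip.label, NULL))
    pm <- hkyParams(kappa = runif(1, 0.5, 5),
                    baseFreqs = {
                      f <- runif(4, 0.5, 2); f / sum(f)
                    },
                    alpha = runif(1, 0.3, 3), nCategories = 4)
    expect_equal(hkyGammaLogLik(tr, m, pm), bruteForceLogLik(tr, m, pm),
                 tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant under rerooting and row order", {
  tr <- randomTree(6, seed = 41)
  set.seed(42)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 50, TRUE), 6, 50,
              dimnames = list(tr$tip.label, NULL))
  pm <- hkyParams(kappa = 2.3, baseFreqs = c(0.3, 0.2, 0.27, 0.23),
                  alpha = 1.2)
  ll <- hkyGammaLogLik(tr, m, pm)
  un <- ape::unroot(tr)
  expect_equal(hkyGammaLogLik(un, m, pm), ll, tolerance = 1e-8)
  rr <- ape::root(un, outgroup = "t3", resolve.root = TRUE)
  expect_equal(hkyGammaLogLik(rr, m, pm), ll, tolerance = 1e-8)
  expect_equal(hkyGammaLogLik(tr, m[sample(6), ], pm), ll, tolerance = 1e-10)
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- randomTree(5, seed = 51)
  set.seed(52)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 200, TRUE), 5, 200,
              dimnames = list(tr$tip.label, NULL))
  freqs <- c(0.28, 0.24, 0.26, 0.22)
  pm <- hkyParams(kappa = 3.1, baseFreqs = freqs, alpha = 0.7,
                  nCategories = 4)
  dat <- phangorn::phyDat(m)
  # phangorn parameterises transitions via the Q upper triangle
  fitp <- phangorn::pml(tr, dat, bf = freqs, Q = c(1, 3.1, 1, 1, 3.1, 1),
                        k = 4, shape = 0.7)
  expect_equal(hkyGammaLogLik(tr, m, pm), as.numeric(fitp$logLik),
               tolerance = 1e-6)
})

test_that("errors on negative branch lengths and bad inputs", {
  tr <- ape::read.tree(text = "(a:0.1,b:-0.1);")
  m <- matrix("A", 2, 1, dimnames = list(c("a", "b"), NULL))
  pm <- hkyParams()
  expect_error(hkyGammaLogLik(tr, m, pm), "negative")
  expect_error(hkyParams(kappa = -1))
  expect_error(hkyParams(baseFreqs = c(0.5, 0.5, 0.5, 0.5)))
})

# --- ML search ----------------------------------------------------------

test_that("identical sequences give a zero-length tree at the entropy bound", {
  m <- matrix(rep(c("A", "C", "G", "T"), 25), 1, 100)[rep(1, 4), ]
  rownames(m) <- letters[1:4]
  fit <- suppressWarnings(fitMLTree(m, fixedAlpha = 1))
  expect_lt(max(fit@tree$edge.length), 1e-6)
  freqs <- fit@params$baseFreqs
  expect_equal(fit@logLik, 100 * sum(freqs * log(freqs)), tolerance = 1e-3)
  expect_equal(fit@nSitesUsed, 100L)
})

test_that("the search improves on its NJ start and is a fixed point", {
  ss <- strongSignalSim(seed = 7, length = 1200L)
  aln <- ss$sim$alignment
  m <- cisScan:::cdMatrix(aln)
  start <- njTree(k80DistanceMatrix(m))
  fit <- fitMLTree(aln, fixedAlpha = 1.9765)
  pm <- do.call(hkyParams, fit@params[c("kappa", "baseFreqs", "alpha",
                                        "nCategories")])
  expect_gte(fit@logLik, hkyGammaLogLik(ape::unroot(start), m, pm))
  # refitting from the fitted tree does not move the likelihood
  fit2 <- fitMLTree(aln, init = fit@tree, fixedAlpha = 1.9765)
  expect_equal(fit2@logLik, fit@logLik, tolerance = 1e-2)
  # topology recovered even at this moderate length
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(fit@tree),
                                         ape::unroot(readNewick(text = ss$newick)))),
               0)
})

test_that("bootstrap is deterministic, bounded, and errors on n < 1", {
  ss <- strongSignalSim(seed = 8, length = 800L)
  fit <- fitMLTree(ss$sim$alignment, fixedAlpha = 1.9765)
  expect_error(bootstrapSupport(ss$sim$alignment, fit, 0, seed = 1), ">= 1")
  expect_error(bootstrapSupport(ss$sim$alignment, fit, 10), "seed")
  b1 <- bootstrapSupport(ss$sim$alignment, fit, 10, seed = 5)
  b2 <- bootstrapSupport(ss$sim$alignment, fit, 10, seed = 5)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports$support >= 0 & b1$supports$support <= 100))
  # only reference-tree splits get support entries
  expect_setequal(b1$supports$split, cisScan:::splitKeys(fit@tree)$keys)
})

test_that("NNI rearrangements preserve tips and change one split", {
  tr <- randomTree(6, seed = 61)
  for (cand in nniNeighbors(tr)) {
    expect_setequal(cand$tip.label, tr$tip.label)
    expect_equal(nrow(cand$edge), nrow(tr$edge))
    shared <- intersect(cisScan:::splitKeys(cand)$keys,
                        cisScan:::splitKeys(tr)$keys)
    expect_gte(length(cisScan:::splitKeys(tr)$keys) - length(shared), 1L)
  }
})

# --- monophyly ----------------------------------------------------------

test_that("monophyly verdicts follow the rooted clade structure", {
  tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1,O:3);")
  md <- mkMeta(c("A", "B", "C", "D", "O"),
               group = c(rep("Haplorhini", 2), rep("Strepsirrhini", 2),
                         "outgroup"),
               behavior = c("Diurnal", "Diurnal", "Nocturnal", "Nocturnal",
                            "Nocturnal"))
  res <- monophylyTest(tr, md, "behavior", outgroupId = "O")
  expect_true(all(res$is_monophyletic))
  expect_equal(res$n_intruders, c(0L, 0L))

  # swap one label: diurnal tips A and C no longer form a clade
  md2 <- md
  md2$behavior[md2$id %in% c("B", "C")] <- c("Nocturnal", "Diurnal")
  res2 <- monophylyTest(tr, md2, "behavior", outgroupId = "O")
  expect_false(res2$is_monophyletic[res2$level == "Diurnal"])
  expect_equal(res2$n_intruders[res2$level == "Diurnal"], 2L)

  # single level is trivially monophyletic under the outgroup rooting
  res3 <- monophylyTest(tr, mkMeta(c("A", "B", "C", "D", "O"),
                                   group = md$group, behavior = "Diurnal"),
                        "behavior", outgroupId = "O")
  expect_true(res3$is_monophyletic)
})

test_that("species-tree fixture behaviors are not monophyletic for diurnality", {
  fx <- table1Fixture()
  res <- monophylyTest(fx$tree, fx$metadata, "behavior", outgroupId = "Mouse")
  expect_false(res$is_monophyletic[res$level == "Diurnal"])
  expect_gt(res$n_intruders[res$level == "Diurnal"], 0L)
  # the suborders, by contrast, are clades on the species tree
  bySub <- monophylyTest(fx$tree, fx$metadata, "group", outgroupId = "Mouse")
  expect_true(all(bySub$is_monophyletic))
})
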