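test_that("GC content excludes gaps and ambiguity codes from both sides", {
  expect_equal(gcContent("GGCC"), list(percent = 100, nValid = 4L))
  expect_true(is.na(gcContent("N---N")$percent))
  expect_equal(gcContent("N---N")$nValid, 0L)
  # hand count on a sequencing primer: 16 of 22 bases are G or C
  p <- gcContent("GCCCCCTCGCCTCCATTGACGG")
  expect_equal(p$nValid, 22L)
  expect_equal(p$percent, 100 * 16 / 22, tolerance = 1e-12)
  # S (G-or-C het) is excluded, not counted as half
  expect_equal(gcContent("GSAT")$nValid, 3L)
  expect_equal(gcContent("GSAT")$percent, 100 / 3, tolerance = 1e-12)
})

test_that("GC content is invariant under reverse complement and gaps", {
  set.seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    gapped <- paste(sample(c(strsplit(s, "")[[1]], rep("-", 15))), collapse = "")
    expect_equal(gcContent(rc)$percent, gcContent(s)$percent)
    expect_equal(gcContent(gapped)$percent, gcContent(s)$percent)
  }
})

test_that("sliding windows cover full windows only at the stated starts", {
  a500 <- alnFromMatrix(randomAln(3, 500, 1))
  w <- slidingWindowGC(a500)
  expect_equal(w$start, 0L)
  expect_equal(w$end, 500L)

  a1000 <- alnFromMatrix(randomAln(3, 1000, 2))
  w <- slidingWindowGC(a1000)
  expect_equal(length(w$start), 21L)         # floor((1000-500)/25)+1
  expect_equal(max(w$start), 500L)
  expect_error(slidingWindowGC(a500, window = 501), "exceeds")
})

test_that("an all-gap row in a window is excluded from group statistics", {
  m <- randomAln(6, 60, 3)
  m[6, ] <- "-"
  aln <- alnFromMatrix(m, behaviors = rep(c("Diurnal", "Nocturnal"), each = 3))
  win <- groupWindowTests(aln, window = 60, step = 10)
  expect_true(is.na(slidingWindowGC(aln, 60, 10)$gc[1, 6]))
  expect_equal(win$n_B, 2L)   # the gapped nocturnal sequence dropped
  expect_true(win$testable)
})

test_that("Welch test matches hand-evaluated cases and handles degeneracy", {
  w <- welchTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -1.224745, tolerance = 1e-6)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, 0.2878641, tolerance = 1e-6)
  # identical groups
  expect_equal(welchTTest(c(1, 2, 3), c(1, 2, 3))[c("t", "p")],
               list(t = 0, p = 1))
  # both constant
  expect_equal(welchTTest(c(2, 2), c(2, 2))[c("t", "p")], list(t = 0, p = 1))
  expect_equal(welchTTest(c(3, 3), c(2, 2))$p, 0)
  expect_error(welchTTest(1, c(1, 2)), "at least 2")
})

test_that("Welch p is symmetric under group swap; t changes sign", {
  set.seed(4)
  for (i in 1:8) {
    a <- rnorm(5); b <- rnorm(7, mean = 0.5)
    w1 <- welchTTest(a, b); w2 <- welchTTest(b, a)
    expect_equal(w1$p, w2$p)
    expect_equal(w1$t, -w2$t)
    expect_equal(w1$df, w2$df)
  }
})

test_that("published per-species GC values reproduce the group contrasts", {
  md <- table1Fixture()$metadata
  gc <- speciesGCTable()
  bySuborder <- groupGCFromTable(gc, md, c("group", "Haplorhini",
                                           "Strepsirrhini"))
  expect_equal(bySuborder$mean_A, 58.3)
  expect_equal(bySuborder$mean_B, 56.0)
  expect_equal(bySuborder$p, 0.09546, tolerance = 1e-3)
  byBehavior <- groupGCFromTable(gc, md)
  expect_equal(byBehavior$p, 0.01579, tolerance = 1e-3)
  expect_equal(byBehavior$n_A, 9L)    # outgroup mouse excluded
  expect_equal(byBehavior$n_B, 5L)
})

test_that("Bonferroni threshold is alpha over the testable-window count", {
  # identical rows: every window testable, t = 0, nothing significant
  m0 <- randomAln(1, 2975, 6)
  m <- m0[rep(1, 6), , drop = FALSE]
  rownames(m) <- sprintf("s%d", 1:6)
  aln <- alnFromMatrix(m, behaviors = rep(c("Diurnal", "Nocturnal"), 3))
  win <- groupWindowTests(aln)     # 100 windows of 500 by 25
  expect_equal(attr(win, "m"), 100L)
  expect_equal(unique(win$p_threshold), 5e-4)
  expect_true(all(win$t == 0))
  expect_false(any(win$significant))
})

test_that("core merging follows the step-adjacency rule", {
  fake <- function(starts, window = 500L, step = 25L) {
    n <- length(starts)
    df <- data.frame(start = starts, end = starts + window,
                     mean_A = rep(60, n), mean_B = rep(55, n),
                     significant = rep(TRUE, n), testable = rep(TRUE, n))
    attr(df, "step") <- step
    df
  }
  cores <- detectCoreRegions(fake(c(1000, 1025, 1050, 2000)))
  expect_equal(cores$start, c(1000, 2000))
  expect_equal(cores$end, c(1550, 2500))
  expect_equal(cores$n_windows, c(3L, 1L))
  expect_equal(cores$mean_delta_gc, c(5, 5))

  # a missing intermediate start breaks the run
  broken <- detectCoreRegions(fake(c(0, 50)))
  expect_equal(nrow(broken), 2L)

  none <- fake(integer(0))
  expect_equal(nrow(detectCoreRegions(none)), 0L)
})

test_that("whole-sequence GC equals the weighted mean of tiling windows", {
  set.seed(12)
  m <- randomAln(4, 1500, 13)
  m[2, sample(1500, 100)] <- "-"
  aln <- alnFromMatrix(m)
  w <- slidingWindowGC(aln, window = 500, step = 500)   # non-overlapping
  for (id in alignmentIds(aln)) {
    whole <- gcContent(as.character(sequences(aln)[[id]]))
    agg <- sum(w$gc[, id] * w$nValid[, id]) / sum(w$nValid[, id])
    expect_equal(agg, whole$percent, tolerance = 1e-9)
  }
})

test_that("Bonferroni scan controls family-wise error on exchangeable taxa", {
  # star phylogeny: tips are i.i.d. given the site profile, which is the
  # regime the per-window Welch test assumes; 100 null replicates
  ids <- sprintf("t%02d", 1:12)
  star <- paste0("(", paste(sprintf("%s:0.15", ids), collapse = ","), ");")
  md <- mkMeta(ids, behavior = rep(c("Diurnal", "Nocturnal"), each = 6))
  nrep <- 100
  fam <- logical(nrep)
  for (r in seq_len(nrep)) {
    cfg <- simulationConfig(tree = star, metadata = md, length = 2000L,
                            kappa = 3, alpha = 1.9765, seed = 20000 + r)
    sim <- simulateAlignment(cfg)
    win <- groupWindowTests(sim$alignment, window = 500L, step = 100L)
    fam[r] <- any(win$significant)
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / nrep)
  expect_lte(mean(fam), bound)
})
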