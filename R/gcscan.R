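#' GC content of a residue string
#'
#' Percentage of G+C among unambiguous bases. Gaps and all IUPAC ambiguity
#' codes are excluded from both numerator and denominator; with no valid
#' base the value is undefined (\code{NA}).
#'
#' @param residues A character string (or \code{DNAString}) over the
#'   alignment alphabet.
#' @return List with \code{percent} (NA when undefined) and \code{nValid},
#'   the count of A/C/G/T bases used.
#' @examples
#' gcContent("GGCC")            # 100, nValid 4
#' gcContent("N---N")$percent   # NA
#' @export
gcContent <- function(residues) {
  ch <- strsplit(toupper(as.character(residues)), "", fixed = TRUE)[[1L]]
  nGC <- sum(ch == "G" | ch == "C")
  nValid <- sum(ch %in% c("A", "C", "G", "T"))
  list(percent = if (nValid == 0L) NA_real_ else 100 * nGC / nValid,
       nValid = nValid)
}

#' Per-sequence GC content over sliding windows
#'
#' Windows start at 0, step, 2*step, ... and only full windows are used
#' (the last start is the largest multiple of \code{step} with
#' \code{start + window <= ncol}). Within each window, gaps and ambiguity
#' codes are excluded per sequence; a sequence with no valid base in a
#' window gets \code{NA}.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @param window Window size in alignment columns (default 500).
#' @param step Step between window starts (default 25).
#' @return List with \code{start}, \code{end} (0-based half-open),
#'   \code{gc} (windows x sequences matrix of percentages) and
#'   \code{nValid} (matching matrix of valid-base counts).
#' @export
slidingWindowGC <- function(aln, window = 500L, step = 25L) {
  stopifnot(is(aln, "RegulatoryAlignment"))
  nc <- alignmentWidth(aln)
  if (window > nc) stop(sprintf("window (%d) exceeds alignment width (%d)",
                                window, nc))
  if (step < 1L) stop("step must be >= 1")
  m <- alignmentMatrix(aln)
  isGC <- t(m == "G" | m == "C")          # columns x sequences
  isOK <- t(matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m)))
  cgc <- apply(isGC, 2L, cumsum)
  cok <- apply(isOK, 2L, cumsum)
  starts <- seq.int(0L, nc - window, by = step)
  winSum <- function(cs) {
    hi <- cs[starts + window, , drop = FALSE]
    lo <- rbind(0, cs)[starts + 1L, , drop = FALSE]
    hi - lo
  }
  gcSum <- winSum(cgc)
  okSum <- winSum(cok)
  gc <- 100 * gcSum / okSum
  gc[okSum == 0L] <- NA_real_
  colnames(gc) <- colnames(okSum) <- alignmentIds(aln)
  list(start = starts, end = starts + window, gc = gc,
       nValid = okSum, window = as.integer(window), step = as.integer(step))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom, computed by \code{stats::t.test}. Degenerate inputs the stock
#' test refuses are defined here: two constant samples with equal means
#' give t = 0, p = 1; constant samples with different means give an
#' infinite statistic and p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welchTTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welchTTest needs at least 2 values per side")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

ci95HalfWidth <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  qt(0.975, n - 1L) * sd(x) / sqrt(n)
}

#' Two-group Welch contrast for every sliding window
#'
#' For each window, summarises per-group GC (mean, sd, n, 95\% CI
#' half-width of the mean), runs Welch's t-test between the two contrast
#' levels, and applies a Bonferroni family-wise threshold
#' \code{alpha / m}, where \code{m} counts only testable windows (both
#' sides with >= 2 defined GC values). Sequences whose metadata has
#' \code{in_primate_tests = FALSE} (the outgroup) never enter the contrast.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @param contrast Character vector of length 3: the metadata field
#'   (\code{"behavior"} or \code{"group"}) and its two levels, side A
#'   first, e.g. \code{c("behavior", "Diurnal", "Nocturnal")}.
#' @param window,step Window geometry (defaults 500 / 25).
#' @param alpha Family-wise significance level (default 0.05).
#' @param windows Optional precomputed \code{\link{slidingWindowGC}} result.
#' @return \code{data.frame}, one row per window: coordinates, per-side
#'   \code{n_A/mean_A/sd_A/ci95_A} (and \code{_B}), \code{t}, \code{df},
#'   \code{p_raw}, \code{testable}, \code{p_threshold}, \code{significant}.
#'   Attributes \code{m} (tested-window count), \code{alpha},
#'   \code{contrast}, \code{step}, \code{window}.
#' @export
groupWindowTests <- function(aln, contrast = c("behavior", "Diurnal", "Nocturnal"),
                             window = 500L, step = 25L, alpha = 0.05,
                             windows = NULL) {
  stopifnot(length(contrast) == 3L)
  md <- sampleData(aln)
  field <- contrast[1L]
  if (!field %in% c("behavior", "group"))
    stop("contrast field must be 'behavior' or 'group'")
  use <- md$in_primate_tests
  idsA <- md$id[use & md[[field]] == contrast[2L]]
  idsB <- md$id[use & md[[field]] == contrast[3L]]
  if (length(idsA) < 2L || length(idsB) < 2L)
    stop(sprintf("contrast level with fewer than 2 members: %s=%d, %s=%d",
                 contrast[2L], length(idsA), contrast[3L], length(idsB)))
  if (is.null(windows)) windows <- slidingWindowGC(aln, window, step)
  gcA <- windows$gc[, idsA, drop = FALSE]
  gcB <- windows$gc[, idsB, drop = FALSE]
  nw <- length(windows$start)
  out <- data.frame(start = windows$start, end = windows$end,
                    n_A = NA_integer_, mean_A = NA_real_, sd_A = NA_real_,
                    ci95_A = NA_real_,
                    n_B = NA_integer_, mean_B = NA_real_, sd_B = NA_real_,
                    ci95_B = NA_real_,
                    t = NA_real_, df = NA_real_, p_raw = NA_real_,
                    testable = FALSE)
  for (i in seq_len(nw)) {
    a <- gcA[i, ][!is.na(gcA[i, ])]
    b <- gcB[i, ][!is.na(gcB[i, ])]
    out$n_A[i] <- length(a); out$n_B[i] <- length(b)
    if (length(a)) { out$mean_A[i] <- mean(a); out$sd_A[i] <- sd(a)
                     out$ci95_A[i] <- ci95HalfWidth(a) }
    if (length(b)) { out$mean_B[i] <- mean(b); out$sd_B[i] <- sd(b)
                     out$ci95_B[i] <- ci95HalfWidth(b) }
    if (length(a) >= 2L && length(b) >= 2L) {
      w <- welchTTest(a, b)
      out$t[i] <- w$t; out$df[i] <- w$df; out$p_raw[i] <- w$p
      out$testable[i] <- TRUE
    }
  }
  m <- sum(out$testable)
  out$p_threshold <- ifelse(out$testable, if (m > 0L) alpha / m else NA_real_,
                            NA_real_)
  out$significant <- out$testable & !is.na(out$p_raw) &
    out$p_raw < out$p_threshold
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "contrast") <- contrast
  attr(out, "window") <- windows$window
  attr(out, "step") <- windows$step
  out
}

#' Whole-sequence two-group GC contrast
#'
#' The non-windowed analogue of \code{\link{groupWindowTests}}: one GC
#' value per sequence over the full alignment (gaps/ambiguities excluded),
#' group means at one-decimal reporting precision, and a Welch test.
#'
#' @inheritParams groupWindowTests
#' @return List: \code{per_sequence} (id, gc, n_valid), \code{mean_A},
#'   \code{mean_B} (one decimal), \code{t}, \code{df}, \code{p},
#'   \code{contrast}.
#' @export
groupGCSummary <- function(aln, contrast = c("behavior", "Diurnal", "Nocturnal")) {
  md <- sampleData(aln)
  seqs <- as.character(sequences(aln))
  vals <- lapply(seqs, gcContent)
  per <- data.frame(id = md$id,
                    gc = vapply(vals, `[[`, numeric(1), "percent"),
                    n_valid = vapply(vals, `[[`, numeric(1), "nValid"))
  groupGCSummaryFromValues(setNames(per$gc, per$id), md, contrast,
                           per_sequence = per)
}

# one-decimal reporting with conventional half-up rounding (58.25 -> 58.3),
# matching how summary tables are printed in the field
roundHalfUp <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

# shared path used both for computed GC and externally supplied values
# (e.g. a published per-species GC table)
groupGCSummaryFromValues <- function(gcByID, md, contrast, per_sequence = NULL) {
  field <- contrast[1L]
  use <- md$in_primate_tests
  a <- gcByID[md$id[use & md[[field]] == contrast[2L]]]
  b <- gcByID[md$id[use & md[[field]] == contrast[3L]]]
  w <- welchTTest(a, b)
  list(per_sequence = per_sequence,
       mean_A = roundHalfUp(mean(a, na.rm = TRUE)),
       mean_B = roundHalfUp(mean(b, na.rm = TRUE)),
       n_A = sum(!is.na(a)), n_B = sum(!is.na(b)),
       t = w$t, df = w$df, p = w$p, contrast = contrast)
}

#' Contrast a published per-sequence GC table between two groups
#'
#' Runs the same group-summary path as \code{\link{groupGCSummary}} on
#' externally supplied GC percentages (e.g. a per-species table from a
#' publication) instead of computing them from sequences.
#'
#' @param gc Named numeric vector of GC percentages, names = sequence ids.
#' @param metadata Metadata \code{data.frame}
#'   (\code{\link{readSampleMetadata}} schema).
#' @param contrast As in \code{\link{groupWindowTests}}.
#' @export
groupGCFromTable <- function(gc, metadata,
                             contrast = c("behavior", "Diurnal", "Nocturnal")) {
  if (!"in_primate_tests" %in% names(metadata))
    metadata <- validateSampleMetadata(metadata)
  groupGCSummaryFromValues(gc, metadata, contrast)
}

#' Merge runs of significant windows into core regions
#'
#' Maximal runs of significant windows whose successive starts differ by
#' exactly \code{step} are merged; each core spans from the first window's
#' start to the last window's end, and carries the mean (side A - side B)
#' GC difference over its member windows.
#'
#' @param windowStats Result of \code{\link{groupWindowTests}}, sorted by
#'   start.
#' @param step Window step; defaults to the attribute stored on
#'   \code{windowStats}.
#' @return \code{data.frame} with columns \code{start}, \code{end},
#'   \code{n_windows}, \code{mean_delta_gc}; zero rows when nothing is
#'   significant.
#' @export
detectCoreRegions <- function(windowStats, step = attr(windowStats, "step")) {
  sig <- windowStats[windowStats$significant %in% TRUE, , drop = FALSE]
  empty <- data.frame(start = integer(), end = integer(),
                      n_windows = integer(), mean_delta_gc = numeric())
  if (nrow(sig) == 0L) return(empty)
  if (is.unsorted(sig$start)) sig <- sig[order(sig$start), , drop = FALSE]
  runId <- cumsum(c(1L, as.integer(diff(sig$start) != step)))
  do.call(rbind, lapply(split(sig, runId), function(d)
    data.frame(start = d$start[1L], end = d$end[nrow(d)],
               n_windows = nrow(d),
               mean_delta_gc = mean(d$mean_A - d$mean_B))))
}

#' Write core regions as BED3+score
#'
#' 0-based half-open intervals; the score column holds the mean GC
#' difference (side A - side B) over the core's windows.
#'
#' @param cores Result of \code{\link{detectCoreRegions}}.
#' @param path Output path.
#' @param chrom Name used in the BED chrom column (default
#'   \code{"alignment"}).
#' @export
writeCoresBed <- function(cores, path, chrom = "alignment") {
  if (nrow(cores)) {
    df <- data.frame(chrom = chrom, start = cores$start, end = cores$end,
                     name = sprintf("core_%d", seq_len(nrow(cores))),
                     score = sprintf("%.4f", cores$mean_delta_gc))
  } else df <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(df))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}
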