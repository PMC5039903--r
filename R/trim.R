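#' Per-column gap fraction of an alignment
#'
#' Ambiguity codes (N, S, ...) are not gaps; only \code{-} counts.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @return Numeric vector, one value in [0, 1] per column.
#' @export
columnGapFraction <- function(aln) {
  stopifnot(is(aln, "RegulatoryAlignment"))
  unname(colMeans(alignmentMatrix(aln) == "-"))
}

#' Remove gap-rich columns (gappyout-style trimming)
#'
#' In \code{fixed} mode every column whose gap fraction exceeds
#' \code{gMax} is dropped. In \code{auto} mode the cut-off is chosen from
#' the data: the distinct gap scores (1 - gap fraction) are sorted
#' ascending, the curve (fraction of columns removed, gap score) is formed,
#' slopes between consecutive points are computed, and the cut is placed at
#' the point of maximum increase between consecutive slopes; columns with
#' gap score strictly below the cut score are removed. With fewer than
#' three distinct gap scores no cut is identifiable and all columns are
#' kept.
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @param mode \code{"fixed"} (default) or \code{"auto"}.
#' @param gMax Maximum tolerated gap fraction in fixed mode (default 0.2).
#' @return A \code{\linkS4class{TrimResult}}.
#' @export
trimGappyout <- function(aln, mode = c("fixed", "auto"), gMax = 0.2) {
  mode <- match.arg(mode)
  gf <- columnGapFraction(aln)
  if (mode == "fixed") {
    keep <- which(gf <= gMax) - 1L
  } else {
    score <- 1 - gf
    s <- sort(unique(score))
    if (length(s) < 3L) {
      keep <- seq_along(gf) - 1L
    } else {
      # removed fraction if we cut at score s_i (strictly-below removal)
      r <- vapply(s, function(si) mean(score < si), numeric(1))
      slope <- diff(s) / diff(r)
      jump <- diff(slope)                    # increase at interior point i+1
      cutScore <- s[which.max(jump) + 1L]
      keep <- which(score >= cutScore) - 1L
    }
  }
  if (length(keep) == 0L)
    stop(sprintf("trimGappyout(mode='%s'%s) removed every column",
                 mode, if (mode == "fixed") sprintf(", gMax=%g", gMax) else ""))
  new("TrimResult", trimmed = subsetColumns(aln, keep),
      keptColumns = as.integer(keep), gapFraction = gf,
      method = paste0("gappyout-", mode))
}

#' Retain only columns with unambiguous bases in every sequence
#'
#' The complete-deletion matrix used for tree building: a column survives
#' only if every row holds one of A, C, G, T (no gaps, no ambiguity codes).
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @return A \code{\linkS4class{TrimResult}}.
#' @export
completeDeletion <- function(aln) {
  stopifnot(is(aln, "RegulatoryAlignment"))
  m <- alignmentMatrix(aln)
  okm <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  keep <- which(colSums(okm) == nrow(m)) - 1L
  if (length(keep) == 0L)
    stop("complete deletion removed every column")
  new("TrimResult", trimmed = subsetColumns(aln, keep),
      keptColumns = as.integer(keep), gapFraction = columnGapFraction(aln),
      method = "complete-deletion")
}

#' Per-sequence ungapped lengths of a trimmed alignment
#'
#' Companion report to \code{\link{trimGappyout}}: for each sequence both
#' the trimmed alignment column count and the number of non-gap residues
#' the sequence retains after trimming.
#'
#' @param trim A \code{\linkS4class{TrimResult}}.
#' @return \code{data.frame} with columns \code{id}, \code{aligned_length},
#'   \code{ungapped_length}.
#' @export
trimmedLengths <- function(trim) {
  stopifnot(is(trim, "TrimResult"))
  m <- alignmentMatrix(trim@trimmed)
  data.frame(id = rownames(m),
             aligned_length = ncol(m),
             ungapped_length = as.integer(rowSums(m != "-")),
             row.names = NULL)
}

#' Write the trimmed-to-original column map as TSV
#'
#' Two 0-based columns: \code{trimmed_index}, \code{original_index}.
#'
#' @param trim A \code{\linkS4class{TrimResult}}.
#' @param path Output path.
#' @export
writeKeptColumns <- function(trim, path) {
  df <- data.frame(trimmed_index = seq_along(trim@keptColumns) - 1L,
                   original_index = trim@keptColumns)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
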