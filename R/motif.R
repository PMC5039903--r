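revComp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Find exact motif occurrences in a (possibly gapped) sequence
#'
#' Matches are located on the gap-stripped sequence; positions are 0-based
#' ungapped coordinates and overlapping hits are reported. A palindromic
#' motif (its own reverse complement, like the E-box CACGTG) is searched on
#' one strand only; otherwise both strands are scanned and the strand
#' recorded.
#'
#' @param residues Character string or \code{DNAString}; gaps allowed.
#' @param motif Motif over A/C/G/T (default the E-box \code{"CACGTG"}).
#' @return \code{data.frame} with columns \code{position} (0-based,
#'   ungapped) and \code{strand}.
#' @export
findMotifSites <- function(residues, motif = "CACGTG") {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over A/C/G/T")
  ungapped <- gsub("-", "", toupper(as.character(residues)), fixed = TRUE)
  scan1 <- function(pat) {
    if (nchar(ungapped) < nchar(pat)) return(integer())
    Biostrings::start(Biostrings::matchPattern(pat,
                                               Biostrings::DNAString(ungapped))) - 1L
  }
  fwd <- scan1(motif)
  rc <- revComp(motif)
  if (rc == motif) {
    out <- data.frame(position = fwd,
                      strand = rep("+", length(fwd)))
  } else {
    rev <- scan1(rc)
    out <- data.frame(position = c(fwd, rev),
                      strand = rep(c("+", "-"), c(length(fwd), length(rev))))
    out <- out[order(out$position), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# 0-based ungapped reference positions -> 0-based alignment columns
ungappedToColumns <- function(refResidues, positions0) {
  ch <- strsplit(toupper(as.character(refResidues)), "", fixed = TRUE)[[1L]]
  cols <- which(ch != "-") - 1L          # alignment column of each ungapped pos
  cols[positions0 + 1L]
}

#' Project reference motif hits through the alignment and classify taxa
#'
#' For every exact hit of \code{motif} in the reference sequence, the hit's
#' residues are mapped to alignment columns (reference gap columns are
#' skipped by construction) and every taxon's characters at those columns
#' are extracted and classified: \code{conserved} (identical to the motif),
#' \code{substituted} (A/C/G/T mismatches, listed as offset:from>to),
#' \code{ambiguous} (contains an IUPAC ambiguity code, offsets listed), or
#' \code{gapped} (contains a gap).
#'
#' @param aln A \code{\linkS4class{RegulatoryAlignment}}.
#' @param refId Reference sequence id (default: first sequence).
#' @param motif Motif string (default \code{"CACGTG"}).
#' @return List of motif reports (class \code{MotifReport}); each has
#'   \code{motifId} ("E-box_1", ... for the default motif), \code{refId},
#'   \code{refStart} (0-based ungapped), \code{strand}, \code{columns}
#'   (0-based alignment columns), and \code{perTaxon}, a \code{data.frame}
#'   with \code{id}, \code{observed}, \code{class}, \code{detail}.
#' @export
motifConservation <- function(aln, refId = alignmentIds(aln)[1L],
                              motif = "CACGTG") {
  stopifnot(is(aln, "RegulatoryAlignment"))
  if (!refId %in% alignmentIds(aln)) stop("refId not in alignment: ", refId)
  m <- alignmentMatrix(aln)
  ref <- paste(m[refId, ], collapse = "")
  hits <- findMotifSites(ref, motif)
  tag <- if (toupper(motif) == "CACGTG") "E-box" else motif
  motifCh <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  k <- length(motifCh)
  reports <- vector("list", nrow(hits))
  for (h in seq_len(nrow(hits))) {
    cols <- ungappedToColumns(ref, hits$position[h] + 0:(k - 1L))
    target <- if (hits$strand[h] == "+") motifCh
              else strsplit(revComp(motif), "", fixed = TRUE)[[1L]]
    obs <- m[, cols + 1L, drop = FALSE]
    per <- data.frame(id = rownames(obs),
                      observed = apply(obs, 1L, paste, collapse = ""),
                      class = NA_character_, detail = "", row.names = NULL)
    for (i in seq_len(nrow(per))) {
      ch <- obs[i, ]
      if (any(ch == "-")) {
        per$class[i] <- "gapped"
        per$detail[i] <- paste(which(ch == "-") - 1L, collapse = ",")
      } else if (any(!ch %in% c("A", "C", "G", "T"))) {
        amb <- which(!ch %in% c("A", "C", "G", "T")) - 1L
        per$class[i] <- "ambiguous"
        per$detail[i] <- paste(amb, collapse = ",")
      } else if (all(ch == target)) {
        per$class[i] <- "conserved"
      } else {
        d <- which(ch != target)
        per$class[i] <- "substituted"
        per$detail[i] <- paste(sprintf("%d:%s>%s", d - 1L, target[d], ch[d]),
                               collapse = ";")
      }
    }
    rep1 <- list(motifId = sprintf("%s_%d", tag, h), refId = refId,
                 refStart = hits$position[h], strand = hits$strand[h],
                 columns = cols, motif = paste(target, collapse = ""),
                 perTaxon = per)
    class(rep1) <- "MotifReport"
    reports[[h]] <- rep1
  }
  reports
}

#' @export
print.MotifReport <- function(x, ...) {
  cat(sprintf("%s at %s:%d (%s strand), columns [%d,%d]\n", x$motifId,
              x$refId, x$refStart, x$strand, min(x$columns), max(x$columns)))
  print(table(x$perTaxon$class))
  invisible(x)
}

#' Flatten motif reports into one table
#'
#' @param reports List returned by \code{\link{motifConservation}}.
#' @return \code{data.frame} with columns \code{motif_id}, \code{taxon},
#'   \code{observed}, \code{classification}, \code{detail}.
#' @export
motifReportTable <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(motif_id = r$motifId, taxon = r$perTaxon$id,
               observed = r$perTaxon$observed,
               classification = r$perTaxon$class,
               detail = r$perTaxon$detail, row.names = NULL)))
}

#' Does motif variation partition the taxa by a trait?
#'
#' For each motif offset, \code{TRUE} iff the observed characters split
#' perfectly by trait level: both levels are represented and no character
#' is shared across levels. Taxa classified \code{ambiguous} or
#' \code{gapped} at the motif are excluded, as are outgroup rows
#' (\code{in_primate_tests = FALSE}). The overall verdict is \code{TRUE}
#' iff any offset partitions.
#'
#' @param report One \code{MotifReport} from
#'   \code{\link{motifConservation}}.
#' @param metadata Metadata \code{data.frame}.
#' @param trait Metadata field, \code{"behavior"} (default) or
#'   \code{"group"}.
#' @return List with \code{perOffset} (logical vector, one per motif
#'   position) and \code{overall}.
#' @export
traitPartition <- function(report, metadata, trait = "behavior") {
  if (!"in_primate_tests" %in% names(metadata))
    metadata <- validateSampleMetadata(metadata)
  per <- report$perTaxon
  keep <- per$class %in% c("conserved", "substituted") &
    per$id %in% metadata$id[metadata$in_primate_tests]
  per <- per[keep, , drop = FALSE]
  k <- nchar(report$motif)
  lv <- metadata[[trait]][match(per$id, metadata$id)]
  levels <- unique(lv)
  perOffset <- logical(k)
  if (nrow(per) > 0L && length(levels) == 2L) {
    obs <- do.call(rbind, strsplit(per$observed, "", fixed = TRUE))
    for (j in seq_len(k)) {
      s1 <- unique(obs[lv == levels[1L], j])
      s2 <- unique(obs[lv == levels[2L], j])
      perOffset[j] <- length(s1) > 0L && length(s2) > 0L &&
        length(intersect(s1, s2)) == 0L
    }
  }
  list(perOffset = perOffset, overall = any(perOffset), levels = levels)
}
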