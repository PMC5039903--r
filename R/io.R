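#' Read an aligned (or unaligned) multi-FASTA of DNA sequences
#'
#' Residues are uppercased; only IUPAC DNA codes
#' (\code{ACGT RYSWKM BDHV N}) and the gap character \code{-} are accepted.
#' \code{U} is rejected: the package handles genomic DNA only.
#'
#' @param path Path to a FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}, one element per record,
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- toupper(gsub("[ \t\r]", "", as.character(raw)))
  if (any(!nzchar(res))) stop("empty sequence for id ", ids[!nzchar(res)][1L])
  for (i in seq_along(res)) {
    ch <- strsplit(res[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% ALLOWED_CHARS)
    if (length(bad))
      stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                   ch[bad[1L]], ids[i], bad[1L]))
  }
  seqs <- Biostrings::DNAStringSet(res)
  names(seqs) <- ids
  seqs
}

#' Write sequences as canonical FASTA
#'
#' Uppercase residues wrapped at 60 columns, so that write/read round-trips
#' are byte-stable.
#'
#' @param seqs A named \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read the per-sequence sample metadata table
#'
#' A tab-separated table with header \code{id<TAB>species<TAB>group<TAB>behavior};
#' lines starting with \code{#} are skipped. \code{group} must be one of
#' Haplorhini, Strepsirrhini or outgroup; \code{behavior} Diurnal or
#' Nocturnal. Outgroup rows are marked \code{in_primate_tests = FALSE} and
#' are excluded from group statistical contrasts.
#'
#' @param path Path to the TSV file.
#' @return A \code{data.frame} with columns \code{id}, \code{species},
#'   \code{group}, \code{behavior}, \code{in_primate_tests}.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  md <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("id", "species", "group", "behavior")
  if (!identical(names(md)[seq_along(need)], need))
    stop("metadata header must be: ", paste(need, collapse = "\t"))
  validateSampleMetadata(md[need])
}

validateSampleMetadata <- function(md) {
  if (any(is.na(md$id) | !nzchar(md$id))) stop("metadata row with missing id")
  if (anyDuplicated(md$id))
    stop("duplicate metadata id(s): ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  badg <- setdiff(unique(md$group), GROUP_LEVELS)
  if (length(badg))
    stop("unknown group value(s): ", paste(badg, collapse = ", "),
         " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")")
  badb <- setdiff(unique(md$behavior), BEHAVIOR_LEVELS)
  if (length(badb))
    stop("unknown behavior value(s): ", paste(badb, collapse = ", "),
         " (allowed: ", paste(BEHAVIOR_LEVELS, collapse = ", "), ")")
  md$in_primate_tests <- md$group != "outgroup"
  md
}

#' Write a sample metadata table as TSV
#'
#' @param md Metadata \code{data.frame} as returned by
#'   \code{\link{readSampleMetadata}}.
#' @param path Output path.
#' @export
writeSampleMetadata <- function(md, path) {
  write.table(md[, c("id", "species", "group", "behavior")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair sequences with metadata into a validated alignment
#'
#' Checks that all residue strings have identical length and that sequence
#' ids and metadata ids match one-to-one; mismatches are reported
#' exhaustively in the error message.
#'
#' @param records A named \code{DNAStringSet} (from \code{\link{readFasta}})
#'   or named character vector of aligned sequences.
#' @param metadata Metadata \code{data.frame}
#'   (\code{\link{readSampleMetadata}}).
#' @return A \code{\linkS4class{RegulatoryAlignment}}.
#' @export
validateAlignment <- function(records, metadata) {
  if (is.character(records)) {
    nm <- names(records)
    records <- Biostrings::DNAStringSet(toupper(records))
    names(records) <- nm
  }
  if (!"in_primate_tests" %in% names(metadata))
    metadata <- validateSampleMetadata(metadata)
  ids <- names(records)
  w <- Biostrings::width(records)
  if (length(unique(w)) > 1L) {
    tab <- paste(sprintf("%s=%d", ids, w), collapse = ", ")
    stop("ragged alignment, per-sequence lengths: ", tab)
  }
  onlyFasta <- setdiff(ids, metadata$id)
  onlyMeta <- setdiff(metadata$id, ids)
  if (length(onlyFasta) || length(onlyMeta))
    stop("alignment/metadata id mismatch",
         if (length(onlyFasta)) paste0("; in FASTA only: ",
                                       paste(onlyFasta, collapse = ", ")),
         if (length(onlyMeta)) paste0("; in metadata only: ",
                                      paste(onlyMeta, collapse = ", ")))
  md <- metadata[match(ids, metadata$id), , drop = FALSE]
  rownames(md) <- NULL
  obj <- new("RegulatoryAlignment", sequences = records, sampleData = md)
  validObject(obj)
  obj
}
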