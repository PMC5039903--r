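#' @import methods
NULL

ALLOWED_CHARS <- c("A", "C", "G", "T",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N", "-")
GROUP_LEVELS <- c("Haplorhini", "Strepsirrhini", "outgroup")
BEHAVIOR_LEVELS <- c("Diurnal", "Nocturnal")

#' RegulatoryAlignment: an aligned regulatory region with sample annotation
#'
#' The central container of the package: an equal-width DNA alignment
#' (IUPAC codes plus \code{-} gaps, stored uppercase) together with one
#' metadata row per sequence giving species, clade group and
#' diurnal/nocturnal behavior. All column coordinates used by the package
#' are 0-based, half-open.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of equal width, named
#'   by sequence id.
#' @slot sampleData A \code{data.frame} with columns \code{id},
#'   \code{species}, \code{group} (Haplorhini/Strepsirrhini/outgroup),
#'   \code{behavior} (Diurnal/Nocturnal) and \code{in_primate_tests}
#'   (FALSE for outgroup rows), one row per sequence, same order.
#'
#' @seealso \code{\link{validateAlignment}} to construct one from parsed
#'   records and metadata.
#' @export
setClass("RegulatoryAlignment",
  representation(sequences = "ANY", sampleData = "data.frame"))

setValidity("RegulatoryAlignment", function(object) {
  msgs <- character()
  seqs <- object@sequences
  if (!is(seqs, "DNAStringSet"))
    return("'sequences' must be a DNAStringSet")
  if (length(seqs) < 2L)
    msgs <- c(msgs, "an alignment needs at least 2 sequences")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L)
    msgs <- c(msgs, sprintf("ragged alignment: widths %s",
                            paste(unique(w), collapse = ", ")))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    msgs <- c(msgs, "every sequence must have a nonempty id")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate sequence id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  md <- object@sampleData
  need <- c("id", "species", "group", "behavior", "in_primate_tests")
  if (!all(need %in% names(md)))
    msgs <- c(msgs, sprintf("sampleData must have columns %s",
                            paste(need, collapse = ", ")))
  else if (!is.null(ids) && !identical(md$id, ids))
    msgs <- c(msgs, "sampleData ids must match sequence names in order")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn RegulatoryAlignment the aligned sequences as a DNAStringSet
#' @param x,object A \code{RegulatoryAlignment}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @export
setMethod("sequences", "RegulatoryAlignment", function(x) x@sequences)

#' @describeIn RegulatoryAlignment the per-sequence metadata table
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @export
setMethod("sampleData", "RegulatoryAlignment", function(x) x@sampleData)

#' @describeIn RegulatoryAlignment number of alignment columns
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))

#' @export
setMethod("alignmentWidth", "RegulatoryAlignment",
          function(x) unique(Biostrings::width(x@sequences))[1L])

#' @describeIn RegulatoryAlignment sequence ids, in alignment order
#' @export
setGeneric("alignmentIds", function(x) standardGeneric("alignmentIds"))

#' @export
setMethod("alignmentIds", "RegulatoryAlignment", function(x) names(x@sequences))

#' @export
setMethod("show", "RegulatoryAlignment", function(object) {
  md <- object@sampleData
  cat(sprintf("RegulatoryAlignment: %d sequences x %d columns\n",
              length(object@sequences), alignmentWidth(object)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (%d)", names(table(md$group)), table(md$group)),
                    collapse = ", ")))
  cat(sprintf("  behavior: %s\n",
              paste(sprintf("%s (%d)", names(table(md$behavior)), table(md$behavior)),
                    collapse = ", ")))
})

# character matrix view (rows = sequences, single characters), uppercase
alignmentMatrix <- function(x) {
  m <- as.matrix(x@sequences)
  rownames(m) <- names(x@sequences)
  m
}

# subset alignment columns by 0-based original indices (strictly increasing)
subsetColumns <- function(x, keep0) {
  m <- alignmentMatrix(x)[, keep0 + 1L, drop = FALSE]
  seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
  names(seqs) <- rownames(m)
  new("RegulatoryAlignment", sequences = seqs, sampleData = x@sampleData)
}

#' TrimResult: a trimmed alignment plus its column provenance
#'
#' @slot trimmed The trimmed \code{\linkS4class{RegulatoryAlignment}}.
#' @slot keptColumns Integer vector of 0-based original column indices,
#'   strictly increasing; maps trimmed column \code{i} (0-based) to
#'   original column \code{keptColumns[i + 1]}.
#' @slot gapFraction Per-original-column fraction of rows that are gaps.
#' @slot method Character tag for how the columns were chosen.
#' @export
setClass("TrimResult",
  representation(trimmed = "RegulatoryAlignment", keptColumns = "integer",
                 gapFraction = "numeric", method = "character"))

setValidity("TrimResult", function(object) {
  k <- object@keptColumns
  if (length(k) && any(diff(k) <= 0L))
    return("keptColumns must be strictly increasing")
  if (length(k) != alignmentWidth(object@trimmed))
    return("keptColumns length must equal the trimmed column count")
  TRUE
})

#' @export
setMethod("show", "TrimResult", function(object) {
  cat(sprintf("TrimResult (%s): kept %d of %d columns\n", object@method,
              length(object@keptColumns), length(object@gapFraction)))
})

#' MLFit: a fitted maximum-likelihood phylogeny
#'
#' @slot tree An \link[ape]{ape} \code{phylo} tree (unrooted, branch
#'   lengths in expected substitutions/site).
#' @slot params Fitted model parameters (an \code{HKYParams} list:
#'   \code{kappa}, \code{baseFreqs}, \code{alpha}, \code{nCategories}).
#' @slot logLik Maximised log-likelihood.
#' @slot nSitesUsed Number of complete-deletion alignment columns used.
#' @slot converged Logical: did the search cycle converge?
#' @export
setClass("MLFit",
  representation(tree = "ANY", params = "list", logLik = "numeric",
                 nSitesUsed = "integer", converged = "logical"))

#' @export
setMethod("show", "MLFit", function(object) {
  cat(sprintf("MLFit: %d tips, logLik = %.4f, %d sites (complete deletion)\n",
              length(object@tree$tip.label), object@logLik, object@nSitesUsed))
  cat(sprintf("  HKY+G: kappa = %.4f, alpha = %.4f (%d categories)%s\n",
              object@params$kappa, object@params$alpha,
              object@params$nCategories,
              if (object@converged) "" else "  [not converged]"))
})
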