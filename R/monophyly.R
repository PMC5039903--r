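#' Does a trait's tip set form a clade?
#'
#' Roots the tree at the outgroup, then for each level of the trait finds
#' the smallest clade containing all the level's tips;
#' \code{n_intruders} is the clade size minus the level size, and the
#' level is monophyletic iff no intruders remain. Outgroup rows
#' (\code{in_primate_tests = FALSE}) do not contribute tips to trait
#' levels; they only anchor the rooting.
#'
#' @param tree Unrooted \code{phylo} tree whose tips appear in
#'   \code{metadata$id}.
#' @param metadata Metadata \code{data.frame}
#'   (\code{\link{readSampleMetadata}} schema).
#' @param trait Metadata field, \code{"behavior"} (default) or
#'   \code{"group"}.
#' @param outgroupId Tip used to root the tree.
#' @return \code{data.frame}, one row per trait level: \code{level},
#'   \code{n_tips}, \code{clade_size}, \code{n_intruders},
#'   \code{is_monophyletic}.
#' @export
monophylyTest <- function(tree, metadata, trait = "behavior", outgroupId) {
  if (!"in_primate_tests" %in% names(metadata))
    metadata <- validateSampleMetadata(metadata)
  if (!outgroupId %in% tree$tip.label)
    stop("outgroupId is not a tip: ", outgroupId)
  rooted <- ape::root(tree, outgroup = outgroupId, resolve.root = TRUE)
  md <- metadata[metadata$id %in% tree$tip.label &
                   metadata$in_primate_tests, , drop = FALSE]
  levels <- sort(unique(md[[trait]]))
  rows <- lapply(levels, function(lv) {
    tips <- md$id[md[[trait]] == lv]
    if (length(tips) == 0L) stop("empty trait level: ", lv)
    if (length(tips) == 1L) {
      cladeSize <- 1L
    } else {
      mrca <- ape::getMRCA(rooted, tips)
      cladeSize <- length(ape::extract.clade(rooted, mrca)$tip.label)
    }
    data.frame(level = lv, n_tips = length(tips),
               clade_size = cladeSize,
               n_intruders = cladeSize - length(tips),
               is_monophyletic = cladeSize == length(tips))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
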