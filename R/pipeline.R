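#' Run the full comparative pipeline on an aligned regulatory region
#'
#' Stages: validate input, gappyout-style trimming, whole-sequence and
#' sliding-window GC contrasts with Bonferroni control, core-region
#' detection, motif conservation + trait partition, complete deletion,
#' ML tree (HKY+gamma) with bootstrap supports, and trait-monophyly tests.
#' All tabular outputs use 0-based half-open coordinates in
#' trimmed-alignment space; the kept-column map is written for
#' back-projection.
#'
#' @param fasta,metadata Paths to the aligned FASTA and the sample
#'   metadata TSV; alternatively pass a ready
#'   \code{\linkS4class{RegulatoryAlignment}} as \code{alignment}.
#' @param alignment Optional pre-built alignment (overrides the paths).
#' @param outDir Output directory (created if missing).
#' @param window,step,alpha Window-scan settings (defaults 500 / 25 /
#'   0.05).
#' @param trimMode,gMax Trimming settings (see \code{\link{trimGappyout}}).
#' @param contrasts List of contrasts for the whole-sequence GC summary;
#'   the first \code{behavior} contrast also drives the window scan.
#' @param motif Motif to survey (default \code{"CACGTG"}).
#' @param refId Motif reference sequence id (default: first sequence).
#' @param outgroupId Tip used to root the tree for the monophyly test
#'   (default: the first \code{in_primate_tests = FALSE} row; skipped when
#'   there is none).
#' @param fixedAlpha Gamma shape held fixed in the ML fit (default 1.9765;
#'   \code{NULL} to optimise it).
#' @param bootstrapN Bootstrap replicates (default 100; 0 skips the
#'   bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @param fitTree Set \code{FALSE} to skip the phylogeny stage.
#' @return Invisibly, a list with every stage's result objects and the
#'   output file paths.
#' @export
runPipeline <- function(fasta = NULL, metadata = NULL, alignment = NULL,
                        outDir, window = 500L, step = 25L, alpha = 0.05,
                        trimMode = "fixed", gMax = 0.2,
                        contrasts = list(c("behavior", "Diurnal", "Nocturnal"),
                                         c("group", "Haplorhini",
                                           "Strepsirrhini")),
                        motif = "CACGTG", refId = NULL, outgroupId = NULL,
                        fixedAlpha = 1.9765, bootstrapN = 100L, seed = 1L,
                        fitTree = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logCon)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  say("cisScan pipeline: window=%d step=%d alpha=%g trim=%s seed=%d",
      window, step, alpha, trimMode, seed)

  aln <- stage("io_metadata", {
    if (is.null(alignment)) {
      recs <- readFasta(fasta)
      md <- readSampleMetadata(metadata)
      validateAlignment(recs, md)
    } else alignment
  })
  say("alignment: %d sequences x %d columns", length(alignmentIds(aln)),
      alignmentWidth(aln))

  trim <- stage("trimming", trimGappyout(aln, mode = trimMode, gMax = gMax))
  say("trimming (%s): kept %d / %d columns", trim@method,
      length(trim@keptColumns), length(trim@gapFraction))
  writeKeptColumns(trim, file.path(outDir, "kept_columns.tsv"))
  taln <- trim@trimmed

  behaviorContrast <- contrasts[[which(vapply(contrasts, `[`, "", 1L) ==
                                         "behavior")[1L]]]
  summaries <- stage("gc_scan", lapply(contrasts, function(ct)
    groupGCSummary(taln, ct)))
  names(summaries) <- vapply(contrasts, paste, "", collapse = "_")
  win <- stage("gc_scan", groupWindowTests(taln, behaviorContrast,
                                           window = window, step = step,
                                           alpha = alpha))
  cores <- detectCoreRegions(win)
  m <- attr(win, "m")
  say("window scan: %d windows, m=%d testable, Bonferroni level %.3g, %d significant, %d core(s)",
      nrow(win), m, alpha / max(m, 1L), sum(win$significant), nrow(cores))
  write.table(win, file.path(outDir, "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeCoresBed(cores, file.path(outDir, "cores.bed"))

  if (is.null(refId)) refId <- alignmentIds(taln)[1L]
  reports <- stage("motif", motifConservation(taln, refId, motif))
  partitions <- lapply(reports, traitPartition, metadata = sampleData(taln))
  say("motif scan: %d %s site(s) in reference %s; trait partition: %s",
      length(reports), motif, refId,
      paste(vapply(partitions, function(p) as.character(p$overall), ""),
            collapse = ","))
  if (length(reports))
    write.table(motifReportTable(reports), file.path(outDir, "motifs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  fit <- boot <- mono <- NULL
  if (fitTree) {
    fit <- stage("phylo", fitMLTree(taln, fixedAlpha = fixedAlpha))
    say("ML tree: logLik=%.2f, %d complete-deletion sites, kappa=%.3f",
        fit@logLik, fit@nSitesUsed, fit@params$kappa)
    treeOut <- fit@tree
    if (bootstrapN > 0L) {
      boot <- stage("phylo", bootstrapSupport(taln, fit,
                                              nReplicates = bootstrapN,
                                              seed = seed))
      treeOut <- boot$tree
      say("bootstrap: %d replicates, supports %s", bootstrapN,
          paste(round(boot$supports$support), collapse = ","))
      write.table(boot$replicates,
                  file.path(outDir, "bootstrap_replicates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeNewick(treeOut, file.path(outDir, "tree.nwk"))
    md <- sampleData(taln)
    if (is.null(outgroupId) && any(!md$in_primate_tests))
      outgroupId <- md$id[!md$in_primate_tests][1L]
    if (!is.null(outgroupId)) {
      mono <- stage("phylo", monophylyTest(fit@tree, md,
                                           trait = behaviorContrast[1L],
                                           outgroupId = outgroupId))
      say("monophyly (%s, rooted at %s): %s", behaviorContrast[1L],
          outgroupId,
          paste(sprintf("%s=%s", mono$level, mono$is_monophyletic),
                collapse = " "))
    }
  }

  summaryJson <- list(
    n_sequences = length(alignmentIds(aln)),
    alignment_columns = alignmentWidth(aln),
    trimmed_columns = alignmentWidth(taln),
    contrasts = lapply(summaries, function(s)
      list(contrast = paste(s$contrast, collapse = "/"),
           mean_A = s$mean_A, mean_B = s$mean_B,
           n_A = s$n_A, n_B = s$n_B, t = s$t, df = s$df, p = s$p)),
    window = window, step = step, alpha = alpha,
    m_tested_windows = m,
    bonferroni_level = alpha / max(m, 1L),
    n_significant_windows = sum(win$significant),
    cores = if (nrow(cores)) cores else NULL,
    motif = motif,
    motif_trait_partition = vapply(partitions, function(p) p$overall, TRUE),
    seed = seed)
  if (!is.null(fit)) {
    summaryJson$tree <- list(logLik = fit@logLik,
                             n_sites_used = fit@nSitesUsed,
                             kappa = fit@params$kappa,
                             alpha_shape = fit@params$alpha)
    if (!is.null(mono)) summaryJson$monophyly <- mono
  }
  jsonlite::write_json(summaryJson, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(alignment = aln, trim = trim, windows = win, cores = cores,
                 summaries = summaries, motifs = reports,
                 partitions = partitions, fit = fit, bootstrap = boot,
                 monophyly = mono, outDir = outDir,
                 summaryPath = file.path(outDir, "summary.json")))
}

#' Write a simulated dataset to disk
#'
#' FASTA + metadata TSV + truth JSON, the on-disk form consumed by
#' \code{\link{runPipeline}}.
#'
#' @param sim Result of \code{\link{simulateAlignment}}.
#' @param outDir Output directory.
#' @return Invisibly, the three paths.
#' @export
writeSimulation <- function(sim, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outDir, "alignment.fasta")
  md <- file.path(outDir, "metadata.tsv")
  tj <- file.path(outDir, "truth.json")
  writeFasta(sequences(sim$alignment), fa)
  writeSampleMetadata(sampleData(sim$alignment), md)
  jsonlite::write_json(unclass(sim$truth), tj, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fasta = fa, metadata = md, truth = tj))
}
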