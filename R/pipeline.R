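# End-to-end pipeline driver.

#' Run the full targeted RRBS pipeline
#'
#' Chains reference construction, three-letter alignment and methylation
#' calling over one genome and one read set, optionally simulating the
#' reads first. When simulator truth is available the evaluation metrics
#' (alignment accuracy, CpG recall, R-squared against truth, and
#' optionally the autocorrelation contrast with and without artificial-C
#' exclusion) are computed as part of the run report.
#'
#' When `simulate = TRUE` the reference is built with the simulator's
#' fragment range, adapter and spacer so that simulated reads originate
#' from fragments present in the reference; otherwise the explicit
#' `size_range`/`adapter`/`spacer` arguments apply.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param fasta alternatively, a genome FASTA path.
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param fastq alternatively, a FASTQ path.
#' @param simulate simulate reads with [simulate_rrbs()] instead.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param size_range reference size-selection range; defaults to
#'   `c(40, 250)`, or to the simulator's fragment range when simulating.
#' @param adapter,spacer reference construction parameters.
#' @param k,M aligner seed length and mismatch limit.
#' @param exclude_artificial mask end-repair cytosines during calling.
#' @param compute_autocorr also compute the exclusion-on/off
#'   autocorrelation tables (requires calling twice).
#' @param autocorr_dmax maximum pair distance in bp.
#' @param outdir if non-NULL, write reference files, SAM, call TSV +
#'   bedGraph, simulated FASTQ/truth and a plain-text run log there.
#' @return an `rrbs_run` object: list with `ref`, `alignments`, `pileup`,
#'   `calls`, `merged_calls`, `report`, and when relevant `sim`,
#'   `calls_keep`, `merged_keep`, `autocorr`.
#' @export
run_rrbs_pipeline <- function(genome = NULL, fasta = NULL, reads = NULL,
                              fastq = NULL, simulate = FALSE,
                              sim = sim_config(), size_range = NULL,
                              adapter = DEFAULT_ADAPTER, spacer = "A",
                              k = 20L, M = 2L, exclude_artificial = TRUE,
                              compute_autocorr = FALSE,
                              autocorr_dmax = 100L, outdir = NULL) {
  if (is.null(genome)) {
    if (is.null(fasta)) stop("supply a genome or a FASTA path")
    genome <- read_genome_fasta(fasta)
  }
  genome <- check_genome(genome)

  simobj <- NULL
  if (simulate) {
    simobj <- simulate_rrbs(genome, sim)
    reads <- simobj$reads
    if (is.null(size_range)) size_range <- c(sim$frag_min, sim$frag_max)
    adapter <- sim$adapter
    spacer <- sim$spacer
  } else {
    if (is.null(reads)) {
      if (is.null(fastq)) stop("supply reads, a FASTQ path, or simulate")
      reads <- read_fastq(fastq)
    }
    reads <- as.data.table(reads)
    if (is.null(size_range)) size_range <- c(40, 250)
  }

  ref <- build_reference(genome, size_range = size_range,
                         adapter = adapter, spacer = spacer)
  index <- build_index(ref, k)
  aln <- align_reads(reads, ref, index = index, M = M)
  pile <- pileup_alignments(aln, reads, ref)
  calls <- call_methylation(pile, ref,
                            exclude_artificial = exclude_artificial)
  merged <- merge_strands(calls)

  report <- list(
    n_reads = nrow(reads),
    n_fragments = nrow(ref$fragments),
    n_entries = nrow(ref$entries),
    n_unique = sum(aln$status == "unique"),
    n_multi_discarded = sum(aln$status == "multi_fragment_discarded"),
    n_unaligned = sum(aln$status == "unaligned"),
    n_cpg_calls = nrow(merged),
    exclude_artificial = exclude_artificial,
    size_range = ref$size_range, k = as.integer(k), M = as.integer(M))

  res <- list(ref = ref, alignments = aln, pileup = pile, calls = calls,
              merged_calls = merged, sim = simobj)

  L <- if (nrow(reads) > 0L) max(nchar(reads$seq)) else NA_integer_
  if (!is.null(simobj)) {
    acc <- alignment_accuracy(aln, simobj$truth_reads)
    report$pct_unique <- unname(acc["pct_unique"])
    report$pct_correct <- unname(acc["pct_correct"])
    report$recall <- methylation_recall(merged, ref, L)
    joined <- merge(merged, simobj$truth_cpg,
                    by.x = c("chrom", "gpos"), by.y = c("chrom", "pos"))
    report$n_cpg_compared <- nrow(joined)
    report$mean_called_ratio <- if (nrow(merged)) mean(merged$ratio)
                                else NA_real_
    report$r_squared <- if (nrow(joined) >= 3L)
      r_squared(joined$ratio, joined$state) else NA_real_
  }

  if (compute_autocorr) {
    calls_keep <- call_methylation(pile, ref, exclude_artificial = FALSE)
    merged_keep <- merge_strands(calls_keep)
    ac_on <- meth_autocorrelation(merged, d_max = autocorr_dmax)
    ac_off <- meth_autocorrelation(merged_keep, d_max = autocorr_dmax)
    res$calls_keep <- calls_keep
    res$merged_keep <- merged_keep
    res$autocorr <- list(exclusion_on = ac_on, exclusion_off = ac_off)
    report$mean_autocorr_on <- mean(ac_on$r, na.rm = TRUE)
    report$mean_autocorr_off <- mean(ac_off$r, na.rm = TRUE)
  }

  res$report <- report
  res <- structure(res, class = "rrbs_run")
  if (!is.null(outdir)) .write_run(res, reads, outdir)
  res
}

# Write all pipeline artifacts to a directory.
.write_run <- function(run, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_reference(run$ref, outdir)
  write_sam(run$alignments, reads, run$ref,
            file.path(outdir, "alignments.sam"))
  write_calls(run$calls, tsv = file.path(outdir, "calls.tsv"),
              bedgraph = file.path(outdir, "calls.bedGraph"))
  if (!is.null(run$calls_keep)) {
    write_calls(run$calls_keep,
                tsv = file.path(outdir, "calls_keep_artificial.tsv"),
                bedgraph = file.path(outdir,
                                     "calls_keep_artificial.bedGraph"))
  }
  if (!is.null(run$sim)) {
    write_fastq(run$sim$reads, file.path(outdir, "simulated.fastq"))
    write_truth(run$sim, outdir)
  }
  rep <- run$report
  lines <- vapply(names(rep), function(nm) {
    paste0(nm, "\t", paste(format(rep[[nm]], digits = 10), collapse = ","))
  }, character(1))
  con <- file(file.path(outdir, "run_log.tsv"), "wb")
  writeLines(lines, con)
  close(con)
  invisible(outdir)
}

#' @export
print.rrbs_run <- function(x, ...) {
  r <- x$report
  cat("rrbs_run\n")
  cat(sprintf("  reads:        %d (unique %d | multi-discarded %d | unaligned %d)\n",
              r$n_reads, r$n_unique, r$n_multi_discarded, r$n_unaligned))
  cat(sprintf("  fragments:    %d in [%g, %g] bp\n", r$n_fragments,
              r$size_range[1], r$size_range[2]))
  cat(sprintf("  CpG calls:    %d dyads (artificial Cs %s)\n", r$n_cpg_calls,
              if (r$exclude_artificial) "excluded" else "kept"))
  if (!is.null(r$pct_unique)) {
    cat(sprintf("  %%unique:      %.2f\n", r$pct_unique))
    cat(sprintf("  %%correct:     %.2f\n", r$pct_correct))
    cat(sprintf("  recall:       %.2f%%\n", r$recall))
    cat(sprintf("  R^2 vs truth: %.4f (n = %d)\n", r$r_squared,
                r$n_cpg_compared))
  }
  if (!is.null(r$mean_autocorr_on)) {
    cat(sprintf("  mean autocorr d=1..%d: %.3f (exclusion on) vs %.3f (off)\n",
                length(x$autocorr$exclusion_on$distance),
                r$mean_autocorr_on, r$mean_autocorr_off))
  }
  invisible(x)
}
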