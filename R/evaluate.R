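# Evaluation metrics: alignment accuracy, recall, R-squared against truth,
# methylation autocorrelation and fragment uniqueness.

#' Alignment accuracy against simulator truth
#'
#' `pct_unique` is the percentage of reads with a unique placement;
#' `pct_correct` additionally requires the lifted genomic start, chromosome
#' and strand to equal the simulator's origin record. Only exact-position
#' agreement counts.
#'
#' @param alignments output of [align_reads()].
#' @param truth_reads per-read origin records from [simulate_rrbs()].
#' @return named numeric: `pct_unique`, `pct_correct` (both in percent of
#'   all reads).
#' @export
alignment_accuracy <- function(alignments, truth_reads) {
  aln <- as.data.table(alignments)
  tr <- as.data.table(truth_reads)
  if (!all(aln$read_id %in% tr$read_id)) {
    stop("read id(s) missing from the truth table")
  }
  total <- nrow(aln)
  if (total == 0L) return(c(pct_unique = NA_real_, pct_correct = NA_real_))
  uniq <- merge(aln[status == "unique"],
                tr[, .(read_id, t_chrom = chrom, t_strand = strand, g_start)],
                by = "read_id")
  correct <- uniq[chrom == t_chrom & strand == t_strand & pos0 == g_start]
  c(pct_unique = 100 * nrow(uniq) / total,
    pct_correct = 100 * nrow(correct) / total)
}

# CpG dyads reachable by an L bp read on either strand of any fragment in
# the reference, excluding the per-strand artificial cytosine (a dyad only
# reachable through the fill-in C does not count as expected).
expected_cpgs <- function(ref, L) {
  e <- ref$entries
  if (nrow(e) == 0L) {
    return(data.table(chrom = character(0), pos = integer(0)))
  }
  hits <- gregexpr("CG", e$repaired_seq, fixed = TRUE)
  idx <- lapply(hits, function(h) {
    if (h[1L] == -1L) integer(0) else as.integer(h) - 1L
  })
  dy <- data.table(row = rep(seq_len(nrow(e)), lengths(idx)),
                   i = unlist(idx))
  dy[, fl := e$frag_len[row]]
  dy <- dy[i <= pmin(L - 1L, fl - 1L)]
  dy[, chrom := e$chrom[row]]
  dy[, pos := ifelse(e$strand[row] == "+", e$frag_start[row] + i,
                     e$frag_end[row] - i)]
  unique(dy[, .(chrom, pos)], by = c("chrom", "pos"))
}

#' CpG recall
#'
#' Number of CpG dyads with coverage of at least 1 divided by the total
#' expected CpGs, in percent. The expected set is defined as the CpG dyads
#' lying within the first `L` bases of either strand of any size-selected
#' fragment (union over fragments), i.e. the dyads an `L` bp directional
#' read starting at a cut site could genuinely reach.
#'
#' @param merged_calls dyad-level calls from [merge_strands()].
#' @param ref the `rrbs_reference`.
#' @param L read length in bp.
#' @return recall in percent, or `NA` if the expected set is empty.
#' @export
methylation_recall <- function(merged_calls, ref, L) {
  expd <- expected_cpgs(ref, as.integer(L))
  if (nrow(expd) == 0L) return(NA_real_)
  calls <- as.data.table(merged_calls)[coverage >= 1L]
  100 * nrow(calls) / nrow(expd)
}

#' Squared Pearson correlation
#'
#' @param est,truth paired numeric vectors (commonly: called ratios and
#'   binary truth states over covered CpGs).
#' @return `cor(est, truth)^2`, or `NA` with a warning when fewer than 3
#'   pairs are available or either vector has zero variance.
#' @export
r_squared <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  ok <- !is.na(est) & !is.na(truth)
  est <- est[ok]
  truth <- truth[ok]
  if (length(est) < 3L) {
    warning("fewer than 3 pairs; R-squared undefined")
    return(NA_real_)
  }
  if (var(est) == 0 || var(truth) == 0) {
    warning("zero variance; R-squared undefined")
    return(NA_real_)
  }
  cor(est, truth)^2
}

#' Methylation autocorrelation by genomic distance
#'
#' For each distance d in `1..d_max`, collects all pairs of called CpG
#' dyads on the same chromosome exactly d bp apart and reports the Pearson
#' correlation of their methylation ratios together with the pair count.
#' Real methylation is locally clustered, so nearby CpGs should correlate;
#' artificial end-repair cytosines depress methylation at fragment
#' junctions and visibly degrade this curve, which is the diagnostic this
#' function reproduces when run on calls made with and without
#' artificial-C exclusion.
#'
#' @param merged_calls dyad-level calls from [merge_strands()] (+ strand C
#'   coordinates).
#' @param d_max maximum distance in bp.
#' @param min_cov minimum dyad coverage to include.
#' @return `data.table` with `distance`, `r` (NA when fewer than 3 pairs
#'   or zero variance), `n_pairs`.
#' @export
meth_autocorrelation <- function(merged_calls, d_max = 100L, min_cov = 1L) {
  cc <- as.data.table(merged_calls)[coverage >= min_cov,
                                    .(chrom, gpos, ratio)]
  out <- data.table(distance = seq_len(d_max), r = NA_real_, n_pairs = 0L)
  if (nrow(cc) == 0L) return(out)
  setkey(cc, chrom, gpos)
  for (d in seq_len(d_max)) {
    right <- cc[, .(chrom, gpos = gpos - d, ratio2 = ratio)]
    pairs <- cc[right, on = c("chrom", "gpos"), nomatch = NULL]
    np <- nrow(pairs)
    set(out, d, "n_pairs", np)
    if (np >= 3L && var(pairs$ratio) > 0 && var(pairs$ratio2) > 0) {
      set(out, d, "r", cor(pairs$ratio, pairs$ratio2))
    }
  }
  out[]
}

#' Fragment uniqueness before and after three-letter conversion
#'
#' Among size-selected fragments, the percentage whose top-strand sequence
#' occurs in two or more fragments, computed on the raw sequences and
#' again after C-to-T conversion. Conversion is many-to-one, so the
#' converted percentage is always at least the raw one; the gap measures
#' how much mappability is lost to the reduced three-letter alphabet.
#' By default every member of a duplicate group is counted (2 identical
#' fragments among 4 gives 50%); `counting = "group"` counts each
#' duplicate group once instead.
#'
#' @param fragments digested fragments.
#' @param s_min,s_max size-selection range in bp.
#' @param counting `"member"` (default) or `"group"`.
#' @return named numeric: `pct_duplicate_raw`, `pct_duplicate_converted`,
#'   `n_fragments`; the percentages are `NA` for an empty selection.
#' @export
fragment_uniqueness <- function(fragments, s_min = 40L, s_max = 250L,
                                counting = c("member", "group")) {
  counting <- match.arg(counting)
  sel <- size_select(as.data.table(fragments), s_min, s_max)
  n <- nrow(sel)
  if (n == 0L) {
    return(c(pct_duplicate_raw = NA_real_,
             pct_duplicate_converted = NA_real_, n_fragments = 0))
  }
  pct_dup <- function(seqs) {
    cnt <- data.table(s = seqs)[, .N, by = s]
    if (counting == "member") {
      100 * sum(cnt$N[cnt$N >= 2L]) / n
    } else {
      100 * sum(cnt$N >= 2L) / n
    }
  }
  c(pct_duplicate_raw = pct_dup(sel$seq),
    pct_duplicate_converted = pct_dup(chartr("C", "T", sel$seq)),
    n_fragments = n)
}
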