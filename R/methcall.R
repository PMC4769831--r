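# Pileup of pre-converted reads on fragment entries and artificial-C-aware
# CpG methylation calling in genome coordinates.

#' Pile up original read bases on fragment entries
#'
#' For every uniquely aligned read, tallies the original (pre-converted)
#' read bases over the positions of its entry's repaired sequence. Bases
#' falling in the spacer/adapter tail contribute nothing; at each
#' reference-C position, C (methylated), T (unmethylated) and other
#' (sequencing error) bases are counted separately. Identical
#' (read sequence, placement) groups are tallied once and weighted, so
#' duplicated reads cost nothing extra.
#'
#' @param alignments output of [align_reads()]; only `status == "unique"`
#'   rows are used.
#' @param reads the reads table with original sequences.
#' @param ref the `rrbs_reference`.
#' @return `data.table` with `entry`, `pos` (0-based on the repaired
#'   sequence), `count_meth`, `count_unmeth`, `count_other` for every
#'   covered reference-C position.
#' @export
pileup_alignments <- function(alignments, reads, ref) {
  e <- ref$entries
  aln <- as.data.table(alignments)[status == "unique"]
  empty <- data.table(entry = integer(0), pos = integer(0),
                      count_meth = integer(0), count_unmeth = integer(0),
                      count_other = integer(0))
  if (nrow(aln) == 0L) return(empty)
  if (any(aln$offset + aln$mlen > e$adapter_start[aln$entry])) {
    stop("internal error: alignment overruns its entry")
  }
  u <- merge(aln[, .(read_id, entry, offset)],
             as.data.table(reads)[, .(read_id, seq)], by = "read_id")
  grp <- u[, .(w = .N), by = .(seq, entry, offset)]
  # genomic-origin span of the read on the repaired sequence
  grp[, mlen := pmin(nchar(seq), e$adapter_start[entry] - offset)]
  grp <- grp[mlen > 0L]
  if (nrow(grp) == 0L) return(empty)
  seg <- strsplit(substr(grp$seq, 1L, grp$mlen), "", fixed = TRUE)
  long <- data.table(g = rep(seq_len(nrow(grp)), grp$mlen),
                     base = unlist(seg))
  long[, entry := grp$entry[g]]
  long[, pos := grp$offset[g] + rowid(g) - 1L]
  # flattened repaired sequences for indexed reference-base lookup
  flat <- unlist(strsplit(e$repaired_seq, "", fixed = TRUE))
  starts <- cumsum(c(0L, e$repaired_len))
  long[, refb := flat[starts[entry] + pos + 1L]]
  long <- long[refb == "C"]
  if (nrow(long) == 0L) return(empty)
  long[, w := grp$w[g]]
  counts <- long[, .(count_meth = sum(w[base == "C"]),
                     count_unmeth = sum(w[base == "T"]),
                     count_other = sum(w[!(base %chin% c("C", "T"))])),
                 by = .(entry, pos)]
  setorder(counts, entry, pos)
  counts[]
}

# Vectorised cytosine context lookup from the genome (CpG/CHG/CHH).
.context <- function(chrom, gpos, strand, genome) {
  g <- unname(genome[chrom])
  plus <- strand == "+"
  b1 <- ifelse(plus, substr(g, gpos + 2L, gpos + 2L),
               substr(g, gpos, gpos))
  b2 <- ifelse(plus, substr(g, gpos + 3L, gpos + 3L),
               substr(g, gpos - 1L, gpos - 1L))
  tgt <- ifelse(plus, "G", "C")
  ifelse(b1 == tgt, "CpG", ifelse(b2 == tgt, "CHG", "CHH"))
}

#' Call cytosine methylation in genome coordinates
#'
#' Lifts per-entry pileups to genomic positions and reports, for every
#' covered reference cytosine, the methylation ratio
#' `count_meth / (count_meth + count_unmeth)`. With
#' `exclude_artificial = TRUE` (the default) the end-repair fill-in
#' cytosine of each strand entry -- which lifts to a genuine genomic CpG
#' at the fragment junction but is never methylated in the library --
#' contributes nothing; the genuine opposite-strand evidence for the same
#' CpG still counts. Bases other than C/T at a reference C are excluded
#' from both numerator and denominator. Setting
#' `exclude_artificial = FALSE` reproduces the biased "before removal"
#' condition.
#'
#' @param pileup output of [pileup_alignments()].
#' @param ref the `rrbs_reference`.
#' @param exclude_artificial mask the fill-in cytosines (default TRUE).
#' @param context `"CpG"` (default) restricts the report to CpG-context
#'   cytosines; `"all"` reports CHG/CHH as well.
#' @return `data.table` with `chrom`, `gpos` (0-based genomic position of
#'   the C), `strand`, `context`, `count_meth`, `count_unmeth`, `coverage`,
#'   `ratio`, ordered by (chrom, gpos, strand).
#' @export
call_methylation <- function(pileup, ref, exclude_artificial = TRUE,
                             context = c("CpG", "all")) {
  context <- match.arg(context)
  e <- ref$entries
  p <- as.data.table(pileup)
  empty <- data.table(chrom = character(0), gpos = integer(0),
                      strand = character(0), context = character(0),
                      count_meth = integer(0), count_unmeth = integer(0),
                      coverage = integer(0), ratio = numeric(0))
  if (nrow(p) == 0L) return(empty)
  p <- copy(p)
  if (exclude_artificial) {
    p <- p[pos != e$artificial_c_index[entry]]
  }
  if (nrow(p) == 0L) return(empty)
  p[, strand := e$strand[entry]]
  p[, chrom := e$chrom[entry]]
  p[, gpos := ifelse(strand == "+", e$frag_start[entry] + pos,
                     e$frag_end[entry] + 1L - pos)]
  calls <- p[, .(count_meth = sum(count_meth),
                 count_unmeth = sum(count_unmeth)),
             by = .(chrom, gpos, strand)]
  calls[, coverage := count_meth + count_unmeth]
  calls <- calls[coverage > 0L]
  calls[, context := .context(chrom, gpos, strand, ref$genome)]
  if (context == "CpG") calls <- calls[context == "CpG"]
  calls[, ratio := count_meth / coverage]
  setcolorder(calls, c("chrom", "gpos", "strand", "context", "count_meth",
                       "count_unmeth", "coverage", "ratio"))
  setorder(calls, chrom, gpos, strand)
  calls[]
}

#' Merge strand calls into CpG dyad calls
#'
#' Pools the + strand C at position p with the - strand C at p + 1 of the
#' same CpG dyad: counts are summed and the dyad is reported at the +
#' strand C coordinate. Evidence is conserved: total merged coverage
#' equals total input coverage. Only CpG-context calls are merged.
#'
#' @param calls output of [call_methylation()].
#' @return `data.table` with `chrom`, `gpos`, `count_meth`, `count_unmeth`,
#'   `coverage`, `ratio` per dyad.
#' @export
merge_strands <- function(calls) {
  cp <- as.data.table(calls)[context == "CpG"]
  plus <- cp[strand == "+", .(chrom, gpos, cm_p = count_meth,
                              cu_p = count_unmeth)]
  minus <- cp[strand == "-", .(chrom, gpos = gpos - 1L, cm_m = count_meth,
                               cu_m = count_unmeth)]
  m <- merge(plus, minus, by = c("chrom", "gpos"), all = TRUE)
  for (col in c("cm_p", "cu_p", "cm_m", "cu_m")) {
    set(m, which(is.na(m[[col]])), col, 0L)
  }
  m[, count_meth := cm_p + cm_m]
  m[, count_unmeth := cu_p + cu_m]
  m[, c("cm_p", "cu_p", "cm_m", "cu_m") := NULL]
  m[, coverage := count_meth + count_unmeth]
  m[, ratio := count_meth / coverage]
  setorder(m, chrom, gpos)
  m[]
}

#' Write methylation calls
#'
#' Writes a TSV (1-based positions, with counts so ratios round-trip
#' exactly) and a bedGraph (0-based half-open intervals, ratio as value).
#'
#' @param calls output of [call_methylation()].
#' @param tsv,bedgraph output paths; either may be NULL to skip.
#' @return invisibly, the written paths.
#' @export
write_calls <- function(calls, tsv = NULL, bedgraph = NULL) {
  calls <- as.data.table(calls)
  has_strand <- "strand" %in% names(calls)
  out <- character(0)
  if (!is.null(tsv)) {
    tab <- data.table(chrom = calls$chrom, pos = calls$gpos + 1L,
                      strand = if (has_strand) calls$strand else "+",
                      context = if ("context" %in% names(calls))
                        calls$context else "CpG",
                      count_meth = calls$count_meth,
                      count_unmeth = calls$count_unmeth,
                      ratio = calls$ratio)
    fwrite(tab, tsv, sep = "\t")
    out <- c(out, tsv)
  }
  if (!is.null(bedgraph)) {
    lines <- sprintf("%s\t%d\t%d\t%s", calls$chrom, calls$gpos,
                     calls$gpos + 1L, format(calls$ratio, trim = TRUE,
                                             digits = 15))
    con <- file(bedgraph, "wb")
    writeLines(lines, con)
    close(con)
    out <- c(out, bedgraph)
  }
  invisible(out)
}

#' Read a methylation-call TSV back
#'
#' Inverse of the TSV written by [write_calls()]; positions return to
#' 0-based and ratios are recomputed from counts, so the round trip is
#' exact.
#'
#' @param path TSV file.
#' @return `data.table` in the layout of [call_methylation()].
#' @export
read_calls <- function(path) {
  tab <- fread(path, sep = "\t")
  calls <- data.table(chrom = as.character(tab$chrom),
                      gpos = as.integer(tab$pos) - 1L,
                      strand = as.character(tab$strand),
                      context = as.character(tab$context),
                      count_meth = as.integer(tab$count_meth),
                      count_unmeth = as.integer(tab$count_unmeth))
  calls[, coverage := count_meth + count_unmeth]
  calls[, ratio := count_meth / coverage]
  setcolorder(calls, c("chrom", "gpos", "strand", "context", "count_meth",
                       "count_unmeth", "coverage", "ratio"))
  calls[]
}
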