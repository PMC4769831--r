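# Construction of the alignable fragment reference: end repair, adapter
# annealing and three-letter conversion.

#' Model end repair of MspI fragments
#'
#' MspI digestion leaves 5'-CG overhangs; end repair fills in the recessed
#' 3' ends, appending an (unmethylated) CG to each strand. For a fragment
#' `[start, end)` the repaired top strand is `fragment.seq + "CG"` and
#' covers genomic `[start, end + 2)`; the repaired bottom strand is its
#' reverse complement. The filled-in cytosine sits at 0-based index
#' `length(repaired) - 2` on each strand and lifts to a genuine genomic
#' CpG (the downstream cut site's CpG on the top strand, the upstream one
#' on the bottom strand) -- the source of the end-repair bias this package
#' removes at calling time.
#'
#' @param fragments size-selected fragments from [digest_genome()].
#' @return `data.table` of alignable entries, two rows (strands `+`/`-`)
#'   per fragment, with columns `entry_id`, `fragment_id`, `chrom`,
#'   `frag_start`, `frag_end`, `frag_len`, `strand`, `repaired_seq`,
#'   `repaired_len`, `artificial_c_index`.
#' @export
end_repair <- function(fragments) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L) {
    return(data.table(entry_id = character(0), fragment_id = integer(0),
                      chrom = character(0), frag_start = integer(0),
                      frag_end = integer(0), frag_len = integer(0),
                      strand = character(0), repaired_seq = character(0),
                      repaired_len = integer(0),
                      artificial_c_index = integer(0)))
  }
  top <- fragments[, .(fragment_id, chrom, frag_start = start,
                       frag_end = end, frag_len = end - start,
                       strand = "+", repaired_seq = paste0(seq, "CG"))]
  bot <- copy(top)[, `:=`(strand = "-", repaired_seq = revcomp(repaired_seq))]
  entries <- rbind(top, bot)
  setorder(entries, fragment_id, strand)
  entries[, repaired_len := nchar(repaired_seq)]
  entries[, artificial_c_index := repaired_len - 2L]
  entries[, entry_id := sprintf("%s:%d-%d:%s", chrom, frag_start, frag_end,
                                strand)]
  setcolorder(entries, c("entry_id", "fragment_id", "chrom", "frag_start",
                         "frag_end", "frag_len", "strand", "repaired_seq",
                         "repaired_len", "artificial_c_index"))
  entries[]
}

#' Anneal spacer/adapter and convert to three-letter space
#'
#' Appends the A-tailing spacer and the sequencing adapter to each repaired
#' strand and records where the non-genomic tail begins (`adapter_start`,
#' equal to the repaired length). The full entry is then bisulfite
#' converted in silico by replacing every C with T -- adapter bases
#' included, since reads are also fully converted before matching, so the
#' methylation state of the physical adapter is irrelevant to alignment.
#'
#' @param entries output of [end_repair()].
#' @param adapter non-empty DNA adapter sequence.
#' @param spacer A-tailing spacer, `"A"` by default; may be `""`.
#' @return the entries table with `adapter_start`, `full_seq` and
#'   `converted_seq` columns added.
#' @export
attach_and_convert <- function(entries, adapter = DEFAULT_ADAPTER,
                               spacer = "A") {
  if (length(adapter) != 1L || !.valid_dna(adapter)) {
    stop("adapter must be a single non-empty DNA string")
  }
  if (length(spacer) != 1L || (nzchar(spacer) && !.valid_dna(spacer))) {
    stop("spacer must be a (possibly empty) DNA string")
  }
  entries <- copy(as.data.table(entries))
  entries[, adapter_start := nchar(repaired_seq)]
  entries[, full_seq := paste0(repaired_seq, spacer, adapter)]
  entries[, converted_seq := chartr("C", "T", full_seq)]
  entries[]
}

#' Build the targeted RRBS alignment reference
#'
#' Runs the full reference-construction pipeline: CCGG digestion, size
#' selection, end repair, adapter annealing and three-letter conversion.
#' The result holds both strands of every retained fragment together with
#' the artificial-base and adapter annotations needed to exclude
#' non-biological cytosines during methylation calling.
#'
#' @param genome named character vector, `DNAStringSet`, or path handled by
#'   the caller via [read_genome_fasta()].
#' @param size_range length-2 numeric, inclusive fragment-size bounds in bp.
#' @param adapter,spacer see [attach_and_convert()].
#' @return an object of class `rrbs_reference`: a list with `entries`,
#'   `fragments`, `genome`, `seqlengths`, `size_range`, `adapter`, `spacer`.
#' @examples
#' ref <- build_reference(c(chr1 = "TTCCGGAACGTACCGGTT"), size_range = c(4, 50))
#' ref$entries$repaired_seq
#' @export
build_reference <- function(genome, size_range = c(40, 250),
                            adapter = DEFAULT_ADAPTER, spacer = "A") {
  genome <- check_genome(genome)
  frags <- digest_genome(genome)
  sel <- size_select(frags, size_range[1], size_range[2])
  if (nrow(sel) == 0L) {
    warning("no fragments within size range [", size_range[1], ", ",
            size_range[2], "]; reference is empty")
  }
  entries <- attach_and_convert(end_repair(sel), adapter = adapter,
                                spacer = spacer)
  structure(
    list(entries = entries, fragments = sel, genome = genome,
         seqlengths = setNames(nchar(genome), names(genome)),
         size_range = as.numeric(size_range), adapter = adapter,
         spacer = spacer),
    class = "rrbs_reference")
}

#' @export
print.rrbs_reference <- function(x, ...) {
  cat("rrbs_reference\n")
  cat("  genome:      ", length(x$genome), " sequence(s), ",
      sum(x$seqlengths), " bp\n", sep = "")
  cat("  size range:  [", x$size_range[1], ", ", x$size_range[2],
      "] bp\n", sep = "")
  cat("  fragments:   ", nrow(x$fragments), "\n", sep = "")
  cat("  entries:     ", nrow(x$entries), " (two strands per fragment)\n",
      sep = "")
  cat("  adapter:     ", x$adapter, "\n", sep = "")
  invisible(x)
}

#' Write reference files
#'
#' Writes the converted alignable entries as FASTA (entry names encode
#' chrom, fragment interval and strand) and a metadata TSV with per-entry
#' genomic coordinates and artificial-base/adapter annotations.
#'
#' @param ref an `rrbs_reference`.
#' @param dir output directory, created if missing.
#' @return invisibly, the two file paths.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "rrbs_reference"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "reference_entries.fa")
  tsv <- file.path(dir, "reference_entries.tsv")
  if (nrow(ref$entries) > 0L) {
    write_fasta(setNames(ref$entries$converted_seq, ref$entries$entry_id), fa)
  } else {
    writeLines(character(0), fa)
  }
  meta <- ref$entries[, .(entry_id, chrom, frag_start, frag_end, strand,
                          frag_len, artificial_c_index, adapter_start)]
  fwrite(meta, tsv, sep = "\t")
  invisible(c(fasta = fa, tsv = tsv))
}
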