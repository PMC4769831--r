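# In-silico MspI digestion and size selection.

#' Digest a genome at CCGG motifs
#'
#' MspI recognises CCGG and cuts between the two cytosines on each strand,
#' leaving 5'-CG overhangs. In coordinates, a motif starting at 0-based
#' position `m` contributes a cut point at `m + 1`; a fragment is the
#' interval between two consecutive cut points on the same chromosome, so
#' every fragment's top strand starts with `CGG` and ends with `C`.
#' Terminal pieces of the chromosome (before the first cut or after the
#' last) have only one MspI end, cannot be adapter-ligated on both sides,
#' and are not fragments. Motifs overlapping an N never match, and
#' fragments containing N are dropped.
#'
#' @param genome named character vector (or `DNAStringSet`) of uppercase
#'   DNA over A/C/G/T/N.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open cut-to-cut interval), `seq` (top strand), `length`
#'   (`end - start`) and `fragment_id`, in genomic order. Zero or one CCGG
#'   site on every chromosome yields an empty table.
#' @examples
#' digest_genome(c(chr1 = "TTCCGGAACGTACCGGTT"))
#' @export
digest_genome <- function(genome) {
  genome <- check_genome(genome)
  pieces <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    m <- Biostrings::matchPattern("CCGG", Biostrings::DNAString(s),
                                  fixed = TRUE)
    sites <- Biostrings::start(m) - 1L  # 0-based motif index
    if (length(sites) < 2L) return(NULL)
    cuts <- sites + 1L
    st <- cuts[-length(cuts)]
    en <- cuts[-1L]
    data.table(chrom = ch, start = st, end = en,
               seq = substring(s, st + 1L, en))
  })
  frags <- rbindlist(pieces)
  if (nrow(frags) == 0L) {
    frags <- data.table(chrom = character(0), start = integer(0),
                        end = integer(0), seq = character(0))
  }
  frags <- frags[!grepl("N", seq, fixed = TRUE)]
  frags[, length := end - start]
  frags[, fragment_id := seq_len(.N)]
  frags[]
}

#' Size-select fragments
#'
#' Keeps fragments whose genomic cut-to-cut length (before end repair) lies
#' within `[s_min, s_max]`, bounds inclusive, mimicking the gel size
#' selection of the RRBS protocol (typically 40-250 bp). Order is preserved
#' and fragment ids are kept stable.
#'
#' @param fragments output of [digest_genome()].
#' @param s_min,s_max inclusive length bounds in bp, `0 < s_min <= s_max`.
#' @return filtered `data.table`.
#' @export
size_select <- function(fragments, s_min, s_max) {
  if (!is.numeric(s_min) || !is.numeric(s_max) || length(s_min) != 1L ||
      length(s_max) != 1L || s_min <= 0 || s_min > s_max) {
    stop("invalid size range: need 0 < s_min <= s_max")
  }
  fragments <- as.data.table(fragments)
  fragments[length >= s_min & length <= s_max]
}
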