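# SAM emission in genome coordinates.

# Reverse each string in a character vector (for quality strings of
# reverse-strand records).
.strrev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write alignments as SAM
#'
#' One record per read. Unique placements are emitted in genome
#' coordinates: bottom-strand reads are reverse-complemented with the
#' reverse flag set, and non-genomic read bases (spacer/adapter tail) are
#' soft-clipped per the CIGAR computed at lift-over. Discarded and
#' unaligned reads are emitted with the unmapped flag and a `ZD` tag
#' recording the reason, so no read silently disappears.
#'
#' @param alignments output of [align_reads()].
#' @param reads the reads table the alignments came from (`read_id`,
#'   `seq`, optional `qual`).
#' @param ref the `rrbs_reference` used for alignment (for `@SQ` lines).
#' @param path output SAM file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(alignments, reads, ref, path) {
  reads <- as.data.table(reads)
  if (!"qual" %in% names(reads)) reads[, qual := strrep("I", nchar(seq))]
  aln <- merge(as.data.table(alignments),
               reads[, .(read_id, seq, qual)], by = "read_id", sort = FALSE)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$seqlengths),
                   as.integer(ref$seqlengths)),
           paste0("@PG\tID:rrbspipe\tPN:rrbspipe\tVN:",
                  as.character(packageVersion("rrbspipe"))))
  n <- nrow(aln)
  recs <- character(n)
  if (n > 0L) {
    mapped <- aln$status == "unique"
    minus <- mapped & aln$strand == "-"
    flag <- ifelse(mapped, ifelse(minus, 16L, 0L), 4L)
    seq_out <- aln$seq
    qual_out <- aln$qual
    if (any(minus)) {
      seq_out[minus] <- revcomp(seq_out[minus])
      qual_out[minus] <- .strrev(qual_out[minus])
    }
    rname <- ifelse(mapped, aln$chrom, "*")
    posn <- ifelse(mapped, aln$pos0 + 1L, 0L)
    mapq <- ifelse(mapped, 255L, 0L)
    cig <- ifelse(mapped, aln$cigar, "*")
    tag <- ifelse(mapped, paste0("NM:i:", aln$mismatches),
                  paste0("ZD:Z:", ifelse(aln$status == "unaligned",
                                         "unaligned", "multi_fragment")))
    recs <- paste(aln$read_id, flag, rname, posn, mapq, cig, "*", 0L, 0L,
                  seq_out, qual_out, tag, sep = "\t")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, recs), con)
  invisible(path)
}
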