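# Independent brute-force oracles used to cross-check the implementation.
library(data.table)

# Position-by-position CCGG scan; fragments from consecutive cut points.
# Deliberately avoids the package's motif-matching path.
naive_digest <- function(seqs) {
  out <- lapply(names(seqs), function(ch) {
    s <- seqs[[ch]]
    n <- nchar(s)
    if (n < 4L) return(NULL)
    window <- substring(s, 1:(n - 3L), 4:n)
    motifs <- which(window == "CCGG") - 1L   # 0-based motif index
    if (length(motifs) < 2L) return(NULL)
    cuts <- motifs + 1L
    st <- cuts[-length(cuts)]
    en <- cuts[-1L]
    data.frame(chrom = ch, start = st, end = en,
               seq = substring(s, st + 1L, en), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), seq = character(0))
  }
  res <- res[!grepl("N", res$seq, fixed = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All-offsets Hamming scan of a converted read against every converted
# entry; returns every placement with <= M mismatches.
naive_hits <- function(conv_read, ref, M) {
  rl <- nchar(conv_read)
  rchars <- strsplit(conv_read, "")[[1]]
  hits <- list()
  for (e in seq_len(nrow(ref$entries))) {
    s <- ref$entries$converted_seq[e]
    echars <- strsplit(s, "")[[1]]
    for (off in 0:(nchar(s) - rl)) {
      mm <- sum(echars[(off + 1):(off + rl)] != rchars)
      if (mm <= M) {
        hits[[length(hits) + 1L]] <- data.frame(entry = e, offset = off,
                                                mismatches = mm)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(entry = integer(0), offset = integer(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# Per-read per-position tally of original bases over reference-C positions.
naive_pileup <- function(alignments, reads, ref) {
  aln <- merge(as.data.frame(alignments[alignments$status == "unique", ]),
               as.data.frame(reads), by = "read_id")
  acc <- list()
  for (r in seq_len(nrow(aln))) {
    e <- aln$entry[r]
    ref_chars <- strsplit(ref$entries$repaired_seq[e], "")[[1]]
    read_chars <- strsplit(aln$seq[r], "")[[1]]
    for (j in seq_along(read_chars)) {
      pos <- aln$offset[r] + j - 1L
      if (pos >= ref$entries$adapter_start[e]) break
      if (ref_chars[pos + 1L] != "C") next
      key <- paste(e, pos)
      if (is.null(acc[[key]])) acc[[key]] <- c(C = 0L, T = 0L, other = 0L)
      b <- read_chars[j]
      slot <- if (b == "C") "C" else if (b == "T") "T" else "other"
      acc[[key]][slot] <- acc[[key]][slot] + 1L
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(entry = integer(0), pos = integer(0),
                      count_meth = integer(0), count_unmeth = integer(0),
                      count_other = integer(0)))
  }
  keys <- do.call(rbind, strsplit(names(acc), " "))
  res <- data.frame(entry = as.integer(keys[, 1]),
                    pos = as.integer(keys[, 2]),
                    count_meth = vapply(acc, `[[`, integer(1), "C"),
                    count_unmeth = vapply(acc, `[[`, integer(1), "T"),
                    count_other = vapply(acc, `[[`, integer(1), "other"))
  res <- res[order(res$entry, res$pos), ]
  rownames(res) <- NULL
  res
}

# Enumerate the CpG dyads an L bp fragment-start read can genuinely reach,
# by walking each strand's repaired sequence character by character.
naive_expected_cpgs <- function(ref, L) {
  seen <- character(0)
  for (e in seq_len(nrow(ref$entries))) {
    chars <- strsplit(ref$entries$repaired_seq[e], "")[[1]]
    fl <- ref$entries$frag_len[e]
    plus <- ref$entries$strand[e] == "+"
    for (i in 0:(length(chars) - 2L)) {
      if (i > L - 1L || i > fl - 1L) break
      if (chars[i + 1L] == "C" && chars[i + 2L] == "G") {
        dyad <- if (plus) ref$entries$frag_start[e] + i
                else ref$entries$frag_end[e] - i
        seen <- union(seen, paste(ref$entries$chrom[e], dyad))
      }
    }
  }
  seen
}

# Toy genome with two MspI sites around a single 10 bp fragment [3, 13).
toy_genome <- function() c(chr1 = "TTCCGGAACGTACCGGTT")

toy_reference <- function(adapter = "AGATCGGAAG", spacer = "A") {
  build_reference(toy_genome(), size_range = c(4, 50), adapter = adapter,
                  spacer = spacer)
}
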