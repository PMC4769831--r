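# Three-letter seed-and-extend alignment of reads to the fragment
# reference, multi-mapping resolution and genome-coordinate lift-over.

#' Convert reads to three-letter space
#'
#' Replaces every C with T so that bisulfite-induced C/T transitions do not
#' count as mismatches; the original sequence must be kept by the caller
#' for methylation extraction. Conversion is idempotent.
#'
#' @param seq character vector of read sequences (N allowed; N never
#'   matches during alignment). Empty reads are passed through with a
#'   warning -- they are later reported unaligned.
#' @return converted character vector.
#' @export
convert_read <- function(seq) {
  if (any(!nzchar(seq))) warning("empty read sequence(s); will be unaligned")
  chartr("C", "T", toupper(seq))
}

#' Build an exact-match k-mer index over converted entries
#'
#' Maps every k-mer of every converted entry to its (entry, offset)
#' postings. Used to seed alignment with the first k bases of each
#' converted read; since directional RRBS reads start at a fragment's 5'
#' CGG, the seed almost always hits offset 0 of the read's own entries.
#'
#' @param ref an `rrbs_reference` with at least one entry.
#' @param k seed length in bp, at least 8 and no longer than the shortest
#'   converted entry.
#' @return an `rrbs_index` object.
#' @export
build_index <- function(ref, k = 20L) {
  stopifnot(inherits(ref, "rrbs_reference"))
  k <- as.integer(k)
  if (nrow(ref$entries) == 0L) stop("reference has no entries to index")
  if (k < 8L) stop("seed length k must be >= 8")
  conv <- ref$entries$converted_seq
  if (k > min(nchar(conv))) {
    stop("seed length k exceeds the shortest reference entry")
  }
  posts <- lapply(seq_along(conv), function(i) {
    s <- conv[i]
    st <- seq_len(nchar(s) - k + 1L)
    data.table(kmer = substring(s, st, st + k - 1L), entry = i,
               offset = st - 1L)
  })
  idx <- rbindlist(posts)
  setkey(idx, kmer)
  structure(list(postings = idx, k = k), class = "rrbs_index")
}

#' @export
print.rrbs_index <- function(x, ...) {
  cat("rrbs_index: k =", x$k, "-", nrow(x$postings), "postings\n")
  invisible(x)
}

# Hamming distance between equal-length string pairs.
.hamming <- function(a, b) {
  out <- integer(length(a))
  for (i in seq_along(a)) {
    out[i] <- sum(charToRaw(a[i]) != charToRaw(b[i]))
  }
  out
}

# Candidate hits for a vector of converted read sequences. Returns a
# data.table (u = read index, entry, offset, mismatches, fragment_id,
# start0). Reads shorter than k yield no candidates.
.candidates <- function(conv, index, ref, M) {
  e <- ref$entries
  k <- index$k
  len <- nchar(conv)
  eligible <- which(len >= k)
  empty <- data.table(u = integer(0), entry = integer(0),
                      offset = integer(0), mismatches = integer(0),
                      fragment_id = integer(0), start0 = logical(0))
  if (length(eligible) == 0L) return(empty)
  q <- data.table(kmer = substr(conv[eligible], 1L, k), u = eligible)
  cand <- index$postings[q, on = "kmer", nomatch = NULL,
                         allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(empty)
  elen <- nchar(e$converted_seq)
  cand <- cand[offset + len[u] <= elen[entry]]
  if (nrow(cand) == 0L) return(empty)
  seg <- substr(e$converted_seq[cand$entry], cand$offset + 1L,
                cand$offset + len[cand$u])
  rd <- conv[cand$u]
  mmv <- integer(nrow(cand))
  inexact <- seg != rd
  if (any(inexact)) mmv[inexact] <- .hamming(seg[inexact], rd[inexact])
  cand[, mismatches := mmv]
  cand <- cand[mismatches <= M]
  cand <- unique(cand, by = c("u", "entry", "offset"))
  cand[, fragment_id := e$fragment_id[entry]]
  cand[, start0 := offset == 0L]
  cand[, kmer := NULL]
  cand[]
}

#' Find candidate placements for one converted read
#'
#' Seeds with the first k bases and extends ungapped over the full read
#' length; every placement with at most `M` mismatches where the read fits
#' entirely within an entry is reported. Reads are matched forward-only
#' against both strand entries (directional protocol).
#'
#' @param conv_seq a single converted read sequence.
#' @param index an `rrbs_index`.
#' @param ref the `rrbs_reference` the index was built from.
#' @param M maximum mismatches.
#' @return `data.table` of candidate hits with columns `entry_id`,
#'   `fragment_id`, `strand`, `offset`, `mismatches`, `start0`.
#' @export
align_read <- function(conv_seq, index, ref, M = 2L) {
  stopifnot(length(conv_seq) == 1L, inherits(index, "rrbs_index"))
  cand <- .candidates(conv_seq, index, ref, M)
  e <- ref$entries
  cand[, .(entry_id = e$entry_id[entry], fragment_id, strand = e$strand[entry],
           entry, offset, mismatches, start0)]
}

#' Resolve candidate hits of one read
#'
#' Reads hitting more than one distinct fragment are discarded (the two
#' strand entries of a fragment count as the same fragment). Among hits on
#' a single fragment the placement whose start coincides with the fragment
#' start is preferred; remaining ties break by fewest mismatches, then
#' smallest offset, then top strand.
#'
#' @param hits candidate table from [align_read()] (columns `fragment_id`,
#'   `offset`, `mismatches`, `start0`, `strand` required).
#' @return list with `status` (`"unique"`, `"multi_fragment_discarded"` or
#'   `"unaligned"`) and `hit` (single-row data.table or NULL).
#' @export
resolve_hits <- function(hits) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) {
    return(list(status = "unaligned", hit = NULL))
  }
  if (uniqueN(hits$fragment_id) > 1L) {
    return(list(status = "multi_fragment_discarded", hit = NULL))
  }
  setorder(hits, -start0, mismatches, offset, strand)
  list(status = "unique", hit = hits[1L])
}

# Vectorised genome lift-over for chosen hits. best must carry entry,
# offset, mismatches and a read length vector rlen. The appended CG keeps
# genomic coordinates (it fills in genuine genomic positions at the cut
# site); spacer/adapter bases have none and are soft-clipped.
.lift <- function(best, rlen, ref) {
  e <- ref$entries
  ent <- best$entry
  m <- pmin(rlen, e$adapter_start[ent] - best$offset)
  clipn <- rlen - m
  strand <- e$strand[ent]
  plus <- strand == "+"
  pos0 <- ifelse(plus, e$frag_start[ent] + best$offset,
                 e$frag_end[ent] + 2L - best$offset - m)
  cig <- ifelse(clipn > 0L,
                ifelse(plus, paste0(m, "M", clipn, "S"),
                       paste0(clipn, "S", m, "M")),
                paste0(m, "M"))
  data.table(entry = ent, entry_id = e$entry_id[ent],
             fragment_id = e$fragment_id[ent], strand = strand,
             offset = best$offset, mismatches = best$mismatches,
             chrom = e$chrom[ent], pos0 = as.integer(pos0),
             mlen = as.integer(m), clip = as.integer(clipn), cigar = cig)
}

#' Lift a resolved placement to genome coordinates
#'
#' Top-strand placements start at `frag_start + offset` on `+`; bottom
#' strand placements are mirrored through the fragment and reported on `-`.
#' Bases beyond the repaired fragment (spacer and adapter) are soft-clipped.
#'
#' @param entry integer row index of the entry in `ref$entries`.
#' @param offset 0-based placement offset on the entry.
#' @param read_length read length in bp.
#' @param ref the `rrbs_reference`.
#' @param mismatches mismatch count to carry through.
#' @return single-row `data.table` with `chrom`, `pos0` (0-based leftmost
#'   genomic position of the matched span), `strand`, `cigar`, `mlen`,
#'   `clip`.
#' @export
lift_to_genome <- function(entry, offset, read_length, ref, mismatches = 0L) {
  e <- ref$entries
  if (entry < 1L || entry > nrow(e) || offset < 0L ||
      offset + read_length > nchar(e$converted_seq[entry])) {
    stop("inconsistent alignment metadata in lift_to_genome")
  }
  .lift(data.table(entry = as.integer(entry), offset = as.integer(offset),
                   mismatches = as.integer(mismatches)),
        as.integer(read_length), ref)
}

#' Align a batch of reads to the fragment reference
#'
#' Converts reads to three-letter space, finds candidate placements via the
#' k-mer seed index, resolves multi-mapping (multi-fragment reads are
#' discarded; fragment-start placements are preferred) and lifts unique
#' placements to genome coordinates. Identical read sequences are aligned
#' once and the result broadcast, which makes error-free simulated data
#' essentially free to align.
#'
#' @param reads data.frame with `read_id` and `seq` (and optionally `qual`).
#' @param ref an `rrbs_reference`.
#' @param index optional prebuilt `rrbs_index`; built on the fly otherwise.
#' @param k seed length used when `index` is NULL.
#' @param M maximum mismatches per placement.
#' @return `data.table` with one row per read: `read_id`, `status`,
#'   `entry`, `entry_id`, `fragment_id`, `strand`, `offset`, `mismatches`,
#'   `chrom`, `pos0`, `mlen`, `clip`, `cigar`. Non-unique reads carry NA
#'   placement fields.
#' @export
align_reads <- function(reads, ref, index = NULL, k = 20L, M = 2L) {
  stopifnot(inherits(ref, "rrbs_reference"))
  reads <- as.data.table(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    stop("reads must have read_id and seq columns")
  }
  if (is.null(index)) index <- build_index(ref, k)
  useq <- unique(reads$seq)
  uconv <- convert_read(useq)
  nu <- length(useq)

  cand <- .candidates(uconv, index, ref, M)

  status_u <- rep("unaligned", nu)
  best <- NULL
  if (nrow(cand) > 0L) {
    cand[, nfrag := uniqueN(fragment_id), by = u]
    status_u[unique(cand[nfrag > 1L, u])] <- "multi_fragment_discarded"
    single <- cand[nfrag == 1L]
    if (nrow(single) > 0L) {
      single[, strand := ref$entries$strand[entry]]
      setorder(single, u, -start0, mismatches, offset, strand)
      chosen <- single[!duplicated(u)]
      status_u[chosen$u] <- "unique"
      best <- cbind(u = chosen$u,
                    .lift(chosen, nchar(useq)[chosen$u], ref))
    }
  }

  res <- data.table(u = seq_len(nu), status = status_u)
  if (!is.null(best)) {
    res <- merge(res, best, by = "u", all.x = TRUE, sort = TRUE)
  } else {
    res[, `:=`(entry = NA_integer_, entry_id = NA_character_,
               fragment_id = NA_integer_, strand = NA_character_,
               offset = NA_integer_, mismatches = NA_integer_,
               chrom = NA_character_, pos0 = NA_integer_,
               mlen = NA_integer_, clip = NA_integer_,
               cigar = NA_character_)]
  }
  map <- match(reads$seq, useq)
  out <- res[map]
  out[, u := NULL]
  out[, read_id := reads$read_id]
  setcolorder(out, c("read_id", "status"))
  out[]
}
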