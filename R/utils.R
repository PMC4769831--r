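# Sequence utilities, genome and read IO.

#' Default sequencing adapter
#'
#' First 33 bases of the Illumina TruSeq read-1 adapter. Used when building
#' the fragment reference and when simulating adapter read-through. The
#' reference must be rebuilt if a library was prepared with a different
#' adapter.
#' @export
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

.valid_dna <- function(x) {
  nzchar(x) & !grepl("[^ACGTN]", x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalise a genome to a named uppercase character vector over {A,C,G,T,N}.
check_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || length(genome) == 0L) {
    stop("genome must be a non-empty named character vector or DNAStringSet")
  }
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every genome sequence must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names in genome: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  genome <- toupper(genome)
  if (!all(.valid_dna(genome))) {
    stop("genome sequences must be non-empty and contain only A/C/G/T/N")
  }
  genome
}

#' Generate a random synthetic genome
#'
#' Draws i.i.d. bases at a given GC content. At the default GC of 0.55 a
#' CCGG motif occurs roughly every 175 bp, which yields on the order of
#' 3,000 size-selectable MspI fragments per megabase -- a convenient density
#' for exercising the RRBS pipeline end to end.
#'
#' @param length bases per chromosome.
#' @param n_chrom number of chromosomes (named `chr1`, `chr2`, ...).
#' @param gc GC content in `[0, 1]`.
#' @param seed optional integer seed; when given the result is reproducible
#'   and the caller's RNG state is left untouched.
#' @return named character vector of DNA sequences.
#' @export
random_genome <- function(length = 1e5, n_chrom = 1L, gc = 0.55, seed = NULL) {
  stopifnot(length >= 1, n_chrom >= 1, gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function() {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(names(probs), length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
  }
  seqs <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  setNames(seqs, paste0("chr", seq_len(n_chrom)))
}

#' Read a genome FASTA
#'
#' @param path FASTA file (gzip allowed). Sequence names are truncated at the
#'   first whitespace.
#' @return named uppercase character vector.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) stop("duplicate sequence names in FASTA: ", path)
  check_genome(setNames(as.character(x), nm))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Minimal four-line-record parser; gzip is handled transparently.
#'
#' @param path FASTQ file.
#' @return `data.table` with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ (line count): ", path)
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.table(read_id = character(0), seq = character(0),
                      qual = character(0)))
  }
  idx <- seq_len(n)
  data.table(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[4L * idx - 3L])),
    seq = toupper(lines[4L * idx - 2L]),
    qual = lines[4L * idx])
}

#' Write reads as FASTQ
#'
#' @param reads data.frame with `read_id`, `seq`, `qual`.
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  reads <- as.data.table(reads)
  n <- nrow(reads)
  out <- character(4L * n)
  if (n > 0L) {
    idx <- seq_len(n)
    out[4L * idx - 3L] <- paste0("@", reads$read_id)
    out[4L * idx - 2L] <- reads$seq
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- reads$qual
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
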