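# Directional RRBS read simulator with per-CpG methylation truth.

#' Simulator configuration
#'
#' Defaults reflect a typical directional RRBS experiment: 50 bp reads
#' drawn from a pool of 30-250 bp MspI fragments with mean sampled length
#' 70 bp, and a per-CpG methylation probability of 20%. Bisulfite
#' conversion is complete and sequencing error-free by default; both are
#' configurable for robustness testing.
#'
#' @param n_reads number of reads to simulate.
#' @param read_length read length L in bp.
#' @param meth_prob probability a CpG dyad is methylated (binary state,
#'   shared by both strands of the dyad).
#' @param frag_min,frag_max eligible fragment-length range in bp.
#' @param frag_mean target mean of the sampled fragment length in bp
#'   (achieved by truncated-exponential weighting over the pool).
#' @param adapter,spacer sequences appended after the repaired fragment;
#'   reads shorter than fragment+spacer+adapter are padded by repeating
#'   the adapter.
#' @param truth_mode `"iid"` draws each dyad state independently;
#'   `"mosaic"` draws one state per fixed-width genomic block (mean state
#'   is still `meth_prob`), emulating the clustered methylation of real
#'   genomes for autocorrelation analyses.
#' @param block_len block width in bp for `truth_mode = "mosaic"`.
#' @param uniform_weights ignore `frag_mean` and sample fragments
#'   uniformly.
#' @param conv_efficiency probability an unmethylated C is converted
#'   (1 = complete conversion).
#' @param error_rate per-base substitution error rate on the final read.
#' @param qual_char constant phred quality character (default `"I"`, Q40).
#' @param seed integer RNG seed; the whole simulation is reproducible
#'   given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_reads = 1e5, read_length = 50L, meth_prob = 0.2,
                       frag_min = 30L, frag_max = 250L, frag_mean = 70,
                       adapter = DEFAULT_ADAPTER, spacer = "A",
                       truth_mode = c("iid", "mosaic"), block_len = 500L,
                       uniform_weights = FALSE, conv_efficiency = 1,
                       error_rate = 0, qual_char = "I", seed = 1L) {
  truth_mode <- match.arg(truth_mode)
  stopifnot(n_reads >= 0, read_length >= 1,
            meth_prob >= 0, meth_prob <= 1,
            frag_min <= frag_mean, frag_mean <= frag_max, frag_min > 0,
            conv_efficiency >= 0, conv_efficiency <= 1,
            error_rate >= 0, error_rate < 1, block_len >= 1,
            nchar(qual_char) == 1L)
  if (!.valid_dna(adapter)) stop("adapter must be a non-empty DNA string")
  structure(list(
    n_reads = as.integer(n_reads), read_length = as.integer(read_length),
    meth_prob = meth_prob, frag_min = as.integer(frag_min),
    frag_max = as.integer(frag_max), frag_mean = frag_mean,
    adapter = adapter, spacer = spacer, truth_mode = truth_mode,
    block_len = as.integer(block_len), uniform_weights = uniform_weights,
    conv_efficiency = conv_efficiency, error_rate = error_rate,
    qual_char = qual_char, seed = as.integer(seed)), class = "sim_config")
}

#' Assign binary methylation truth to CpG dyads
#'
#' Every CpG dyad touched by an eligible fragment's repaired strands
#' (dyads whose + strand C lies in `[start, end]`, which includes the
#' junction CpGs at both cut sites) receives one binary state, shared by
#' both strand cytosines of the dyad. Uses the current RNG stream;
#' [simulate_rrbs()] seeds it.
#'
#' @param fragments eligible (size-selected) fragments.
#' @param meth_prob per-dyad methylation probability.
#' @param truth_mode,block_len see [sim_config()].
#' @return `data.table` with `chrom`, `pos` (0-based + strand C of the
#'   dyad) and `state` (0/1), one row per dyad.
#' @export
assign_truth <- function(fragments, meth_prob, truth_mode = "iid",
                         block_len = 500L) {
  fragments <- as.data.table(fragments)
  if (nrow(fragments) == 0L) {
    return(data.table(chrom = character(0), pos = integer(0),
                      state = integer(0)))
  }
  hits <- gregexpr("CG", paste0(fragments$seq, "CG"), fixed = TRUE)
  nhit <- lengths(hits)
  dy <- data.table(chrom = rep(fragments$chrom, nhit),
                   pos = rep(fragments$start, nhit) + unlist(hits) - 1L)
  dy <- unique(dy, by = c("chrom", "pos"))
  setorder(dy, chrom, pos)
  if (truth_mode == "iid") {
    dy[, state := rbinom(.N, 1L, meth_prob)]
  } else {
    dy[, block := pos %/% as.integer(block_len)]
    blocks <- unique(dy[, .(chrom, block)])
    blocks[, state := rbinom(.N, 1L, meth_prob)]
    dy <- merge(dy, blocks, by = c("chrom", "block"), sort = FALSE)
    dy[, block := NULL]
    setorder(dy, chrom, pos)
  }
  dy[]
}

#' Length-calibrated fragment sampler
#'
#' Builds sampling weights over the eligible fragments so that the
#' expected sampled fragment length equals `frag_mean`. Weights follow a
#' truncated-exponential law `w(len) = exp(-lambda * len)` with `lambda`
#' solved numerically; `lambda = 0` (uniform) is the fallback when the
#' pool mean already matches, and `uniform = TRUE` forces it.
#'
#' @param fragments digested fragments.
#' @param frag_min,frag_max eligibility range in bp (inclusive).
#' @param frag_mean target mean sampled length.
#' @param uniform force uniform weights.
#' @return list with `fragments` (eligible subset), `prob` (sampling
#'   probabilities) and `lambda`.
#' @export
fragment_sampler <- function(fragments, frag_min = 30L, frag_max = 250L,
                             frag_mean = 70, uniform = FALSE) {
  eligible <- size_select(as.data.table(fragments), frag_min, frag_max)
  if (nrow(eligible) == 0L) {
    stop("no fragments within [", frag_min, ", ", frag_max, "] bp")
  }
  len <- eligible$length
  if (uniform || length(unique(len)) == 1L) {
    return(list(fragments = eligible,
                prob = rep(1 / nrow(eligible), nrow(eligible)),
                lambda = 0))
  }
  if (frag_mean <= min(len) || frag_mean >= max(len)) {
    stop("target mean ", frag_mean, " not attainable for pool lengths [",
         min(len), ", ", max(len), "]")
  }
  wmean <- function(lambda) {
    s <- -lambda * len
    wt <- exp(s - max(s))
    sum(wt * len) / sum(wt) - frag_mean
  }
  lambda <- uniroot(wmean, c(-1, 1), extendInt = "yes", tol = 1e-10)$root
  s <- -lambda * len
  wt <- exp(s - max(s))
  list(fragments = eligible, prob = wt / sum(wt), lambda = lambda)
}

# Emitted read strings for one strand of every fragment, given truth.
# entries: one strand's rows from end_repair(); returns length-L reads.
.emit_strand <- function(entries, truth, config) {
  L <- config$read_length
  rep_seq <- entries$repaired_seq
  nch <- entries$repaired_len
  sp <- strsplit(rep_seq, "", fixed = TRUE)
  long <- data.table(f = rep(seq_len(nrow(entries)), nch),
                     i = sequence(nch) - 1L, ch = unlist(sp))
  long[, nxt := shift(ch, -1L, fill = ""), by = f]
  fl <- entries$frag_len[long$f]
  plus <- entries$strand[1L] == "+"
  # genomic + strand position of the dyad this C belongs to (CpG Cs only)
  long[, dyad := if (plus) entries$frag_start[f] + i
       else entries$frag_end[f] - i]
  long[, chrom := entries$chrom[f]]
  isC <- long$ch == "C"
  genuine_cpg <- isC & long$nxt == "G" & long$i < fl
  lsub <- long[genuine_cpg, .(chrom, pos = dyad)]
  st <- as.data.table(truth)[lsub, on = c("chrom", "pos"), x.state]
  if (anyNA(st)) stop("truth table does not cover all fragment CpGs")
  newch <- long$ch
  newch[isC] <- "T"                      # full conversion, incl. artificial C
  newch[which(genuine_cpg)[st == 1L]] <- "C"  # methylated CpGs protected
  frag_part <- long[, .(s = paste(newch[.I], collapse = "")), by = f]$s
  mol <- paste0(frag_part, config$spacer, config$adapter)
  while (any(nchar(mol) < L)) {          # pad policy: repeat the adapter
    short <- nchar(mol) < L
    mol[short] <- paste0(mol[short], config$adapter)
  }
  substr(mol, 1L, L)
}

#' Simulate one read from a fragment
#'
#' Models the library molecule for the chosen strand: repaired fragment
#' (its appended CG unmethylated), A-tail spacer and adapter; applies the
#' bisulfite transform (a C at a methylated CpG stays C, every other
#' fragment C and the artificial C read as T, adapter/spacer bases are
#' emitted unchanged); and returns the first L bases.
#'
#' @param fragment single-row fragment (from [digest_genome()]).
#' @param strand `"+"` or `"-"`.
#' @param truth truth table covering the fragment's dyads (see
#'   [assign_truth()]).
#' @param config a [sim_config()].
#' @return list with `seq` (the read) and the origin record (`chrom`,
#'   `fragment_id`, `strand`, `g_start`, `g_end` of the genomic span).
#' @export
make_read <- function(fragment, strand, truth, config) {
  fragment <- as.data.table(fragment)
  stopifnot(nrow(fragment) == 1L, strand %in% c("+", "-"))
  want <- strand
  entries <- end_repair(fragment)
  entries <- entries[entries$strand == want]
  rd <- .emit_strand(entries, as.data.table(truth), config)
  m <- min(config$read_length, fragment$length + 2L)
  g_start <- if (strand == "+") fragment$start else fragment$end + 2L - m
  list(seq = rd, chrom = fragment$chrom, fragment_id = fragment$fragment_id,
       strand = strand, g_start = as.integer(g_start),
       g_end = as.integer(g_start + m))
}

# Optional read-level noise: incomplete conversion re-introduces C at
# positions that were converted from C, sequencing errors substitute
# uniformly. Operates on the emitted reads given the noise-free reads and
# the corresponding pre-bisulfite molecules.
.apply_noise <- function(reads, molecules, config) {
  L <- config$read_length
  n <- length(reads)
  if (n == 0L) return(reads)
  rmat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)), nrow = L)
  if (config$conv_efficiency < 1) {
    mmat <- matrix(unlist(strsplit(substr(molecules, 1L, L), "",
                                   fixed = TRUE)), nrow = L)
    convertible <- mmat == "C" & rmat == "T"
    fail <- convertible & matrix(runif(L * n) < 1 - config$conv_efficiency,
                                 nrow = L)
    rmat[fail] <- "C"
  }
  if (config$error_rate > 0) {
    err <- matrix(runif(L * n) < config$error_rate, nrow = L)
    idx <- which(err)
    if (length(idx)) {
      shift_by <- sample(1:3, length(idx), replace = TRUE)
      bases <- c("A", "C", "G", "T")
      cur <- match(rmat[idx], bases)
      cur[is.na(cur)] <- 1L
      rmat[idx] <- bases[(cur - 1L + shift_by) %% 4L + 1L]
    }
  }
  apply(rmat, 2L, paste, collapse = "")
}

#' Simulate a directional RRBS experiment
#'
#' Digests the genome, assigns binary methylation truth to every CpG dyad
#' of the eligible fragments, samples fragments with length-calibrated
#' weights and a uniform strand, and emits reads that always start at the
#' fragment's 5' CGG. Reads from fragments shorter than the read length
#' run through the artificial CG, the A-tail and into the adapter, exactly
#' as in a real library. Fully reproducible given `config$seed`.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param config a [sim_config()].
#' @return an `rrbs_sim` object: list with `reads` (read_id, seq, qual),
#'   `truth_cpg`, `truth_reads`, `fragments` (the eligible pool),
#'   `sampler`, `config`.
#' @export
simulate_rrbs <- function(genome, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  genome <- check_genome(genome)
  frags <- digest_genome(genome)
  sampler <- fragment_sampler(frags, config$frag_min, config$frag_max,
                              config$frag_mean,
                              uniform = config$uniform_weights)
  eligible <- sampler$fragments
  withr::with_seed(config$seed, {
    truth <- assign_truth(eligible, config$meth_prob, config$truth_mode,
                          config$block_len)
    entries <- end_repair(eligible)
    top <- entries[strand == "+"]
    bot <- entries[strand == "-"]
    reads_top <- .emit_strand(top, truth, config)
    reads_bot <- .emit_strand(bot, truth, config)
    n <- config$n_reads
    idx <- sample.int(nrow(eligible), n, replace = TRUE,
                      prob = sampler$prob)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    plus <- strand == "+"
    rd <- ifelse(plus, reads_top[idx], reads_bot[idx])
    if (config$conv_efficiency < 1 || config$error_rate > 0) {
      mol_top <- paste0(top$repaired_seq, config$spacer, config$adapter)
      mol_bot <- paste0(bot$repaired_seq, config$spacer, config$adapter)
      rd <- .apply_noise(rd, ifelse(plus, mol_top[idx], mol_bot[idx]),
                         config)
    }
    m <- pmin(config$read_length, eligible$length[idx] + 2L)
    g_start <- ifelse(plus, eligible$start[idx],
                      eligible$end[idx] + 2L - m)
    reads <- data.table(
      read_id = sprintf("sim%08d", seq_len(n)),
      seq = rd,
      qual = strrep(config$qual_char, config$read_length))
    truth_reads <- data.table(
      read_id = reads$read_id,
      fragment_id = eligible$fragment_id[idx],
      chrom = eligible$chrom[idx], strand = strand,
      g_start = as.integer(g_start), g_end = as.integer(g_start + m))
  })
  structure(list(reads = reads, truth_cpg = truth,
                 truth_reads = truth_reads, fragments = eligible,
                 sampler = sampler, config = config), class = "rrbs_sim")
}

#' @export
print.rrbs_sim <- function(x, ...) {
  cat("rrbs_sim:", nrow(x$reads), "reads of", x$config$read_length,
      "bp from", nrow(x$fragments), "fragments;",
      nrow(x$truth_cpg), "CpG dyads (mean state",
      sprintf("%.3f", mean(x$truth_cpg$state)), ")\n")
  invisible(x)
}

#' Write simulator truth tables
#'
#' @param sim an `rrbs_sim`.
#' @param dir output directory; writes `truth_cpg.tsv` (1-based dyad
#'   positions) and `truth_reads.tsv`.
#' @return invisibly, the file paths.
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpg <- file.path(dir, "truth_cpg.tsv")
  rds <- file.path(dir, "truth_reads.tsv")
  fwrite(sim$truth_cpg[, .(chrom, pos = pos + 1L, state)], cpg, sep = "\t")
  fwrite(sim$truth_reads, rds, sep = "\t")
  invisible(c(cpg = cpg, reads = rds))
}
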