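test_that("read conversion replaces C with T and is idempotent", {
  expect_equal(convert_read("CGGAACGTAT"), "TGGAATGTAT")
  expect_equal(convert_read("TTTT"), "TTTT")
  expect_equal(convert_read(convert_read("CGCGCG")), convert_read("CGCGCG"))
  expect_warning(convert_read(""), "empty")
})

test_that("the k-mer index posts every substring at its true offset", {
  ref <- toy_reference()
  idx <- build_index(ref, k = 8L)
  # first k-mer of the top entry posts at offset 0
  first <- substr(ref$entries$converted_seq[1], 1, 8)
  post <- idx$postings[kmer == first]
  expect_true(any(post$entry == 1L & post$offset == 0L))
  # every sampled substring is recoverable
  withr::with_seed(42, for (i in 1:20) {
    e <- sample(nrow(ref$entries), 1)
    s <- ref$entries$converted_seq[e]
    off <- sample(0:(nchar(s) - 8L), 1)
    p <- idx$postings[kmer == substr(s, off + 1, off + 8)]
    expect_true(any(p$entry == e & p$offset == off))
  })
})

test_that("index construction validates its inputs", {
  ref <- toy_reference()
  expect_error(build_index(ref, k = 4L), ">= 8")
  expect_error(build_index(ref, k = 1000L), "shortest")
  empty <- suppressWarnings(build_reference(c(chr1 = "ACGTACGT")))
  expect_error(build_index(empty), "no entries")
})

test_that("candidate search respects the mismatch limit", {
  ref <- toy_reference()
  idx <- build_index(ref, k = 8L)
  read <- substr(ref$entries$converted_seq[1], 1, 14)
  hits <- align_read(read, idx, ref, M = 0L)
  expect_true(nrow(hits) >= 1L)
  expect_true(any(hits$offset == 0L & hits$mismatches == 0L))
  # mutate a base beyond the seed region
  mut <- read
  substr(mut, 12, 12) <- if (substr(read, 12, 12) == "A") "G" else "A"
  expect_equal(nrow(align_read(mut, idx, ref, M = 0L)), 0L)
  h2 <- align_read(mut, idx, ref, M = 2L)
  expect_true(any(h2$offset == 0L & h2$mismatches == 1L))
})

test_that("candidate search equals a brute-force Hamming scan", {
  g <- random_genome(8e3, seed = 77)
  ref <- build_reference(g, size_range = c(30, 250))
  idx <- build_index(ref, k = 12L)
  withr::with_seed(99, {
    for (i in 1:15) {
      e <- sample(nrow(ref$entries), 1)
      s <- ref$entries$converted_seq[e]
      off <- sample(0:(nchar(s) - 30L), 1)
      read <- substr(s, off + 1L, off + 30L)
      # optionally mutate one base beyond the seed
      if (i %% 2 == 0) substr(read, 20, 20) <-
          setdiff(c("A", "G", "T"), substr(read, 20, 20))[1]
      got <- align_read(read, idx, ref, M = 2L)
      want <- naive_hits(read, ref, M = 2L)
      # restrict the oracle to placements whose seed matches exactly
      seed_ok <- as.logical(mapply(function(we, wo) {
        substr(ref$entries$converted_seq[we], wo + 1L, wo + 12L) ==
          substr(read, 1, 12)
      }, want$entry, want$offset))
      want <- want[seed_ok, , drop = FALSE]
      setkey(got <- data.table::as.data.table(
        got[, c("entry", "offset", "mismatches")]), entry, offset)
      setkey(want <- data.table::as.data.table(want), entry, offset)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  })
})

test_that("multi-fragment hits are discarded, same-fragment strands are not", {
  hits <- data.table::data.table(
    fragment_id = c(1L, 2L), offset = c(0L, 3L), mismatches = c(0L, 0L),
    start0 = c(TRUE, FALSE), strand = c("+", "+"))
  expect_equal(resolve_hits(hits)$status, "multi_fragment_discarded")
  # two strand entries of the same fragment are the same fragment
  hits2 <- data.table::data.table(
    fragment_id = c(1L, 1L), offset = c(0L, 0L), mismatches = c(0L, 0L),
    start0 = c(TRUE, TRUE), strand = c("-", "+"))
  r2 <- resolve_hits(hits2)
  expect_equal(r2$status, "unique")
  expect_equal(r2$hit$strand, "+")  # tie-break prefers the top strand
  expect_equal(resolve_hits(hits2[0])$status, "unaligned")
})

test_that("fragment-start placements are preferred over internal ones", {
  hits <- data.table::data.table(
    fragment_id = 1L, offset = c(7L, 0L), mismatches = c(0L, 2L),
    start0 = c(FALSE, TRUE), strand = "+")
  r <- resolve_hits(hits)
  expect_equal(r$hit$offset, 0L)
  # without a start placement: fewest mismatches, then smallest offset
  hits2 <- data.table::data.table(
    fragment_id = 1L, offset = c(9L, 5L, 3L), mismatches = c(0L, 0L, 1L),
    start0 = FALSE, strand = "+")
  expect_equal(resolve_hits(hits2)$hit$offset, 5L)
})

test_that("lift-over converts entry placements to genome coordinates", {
  ref <- toy_reference()  # fragment [3, 13) on chr1
  top <- which(ref$entries$strand == "+")
  l1 <- lift_to_genome(top, 0L, 8L, ref)
  expect_equal(l1$pos0, 3L)       # SAM POS 4
  expect_equal(l1$cigar, "8M")
  # 14 bp read over the 10 bp fragment: appended CG keeps genomic
  # coordinates, spacer+adapter are soft-clipped
  l2 <- lift_to_genome(top, 0L, 14L, ref)
  expect_equal(l2$cigar, "12M2S")
  expect_equal(l2$mlen, 12L)
  bot <- which(ref$entries$strand == "-")
  l3 <- lift_to_genome(bot, 0L, 8L, ref)
  expect_equal(l3$strand, "-")
  expect_equal(l3$pos0, 13L + 2L - 8L)  # mirrored through the fragment end
  expect_equal(l3$cigar, "8M")
  expect_error(lift_to_genome(top, 50L, 14L, ref), "inconsistent")
})

test_that("error-free simulated reads align uniquely to their origin", {
  g <- random_genome(5e4, seed = 21)
  cfg <- sim_config(n_reads = 3000, seed = 8)
  sim <- simulate_rrbs(g, cfg)
  ref <- build_reference(g, size_range = c(cfg$frag_min, cfg$frag_max),
                         adapter = cfg$adapter, spacer = cfg$spacer)
  aln <- align_reads(sim$reads, ref, M = 0L)
  expect_true(mean(aln$status == "unique") > 0.99)
  acc <- alignment_accuracy(aln, sim$truth_reads)
  expect_equal(acc[["pct_correct"]], acc[["pct_unique"]])
  # aligning the fully converted copy of each read gives identical results
  conv_reads <- data.table::copy(sim$reads)[, seq := convert_read(seq)]
  aln2 <- align_reads(conv_reads, ref, M = 0L)
  expect_equal(aln2$status, aln$status)
  expect_equal(aln2$pos0, aln$pos0)
})

test_that("reads shorter than the seed are unaligned", {
  ref <- toy_reference()
  aln <- align_reads(data.frame(read_id = "r1", seq = "TGGAA"), ref,
                     k = 8L)
  expect_equal(aln$status, "unaligned")
})

test_that("SAM output is structurally valid and complete", {
  g <- random_genome(3e4, seed = 13)
  cfg <- sim_config(n_reads = 500, seed = 2)
  sim <- simulate_rrbs(g, cfg)
  ref <- build_reference(g, size_range = c(30, 250))
  aln <- align_reads(sim$reads, ref)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, sim$reads, ref, sam)
  lines <- readLines(sam)
  hdr <- grep("^@", lines, value = TRUE)
  recs <- grep("^@", lines, value = TRUE, invert = TRUE)
  expect_true(any(startsWith(hdr, "@SQ\tSN:chr1\tLN:30000")))
  expect_equal(length(recs), nrow(sim$reads))
  fields <- strsplit(recs, "\t", fixed = TRUE)
  expect_true(all(lengths(fields) == 12L))
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  pos <- as.integer(vapply(fields, `[[`, "", 4))
  expect_true(all(flag %in% c(0L, 4L, 16L)))
  expect_true(all(pos[flag != 4L] >= 1L))
  expect_true(all(pos[flag != 4L] <= 30000L))
  # reverse-strand records carry the reverse-complemented read
  minus <- which(flag == 16L)[1]
  if (!is.na(minus)) {
    rid <- vapply(fields, `[[`, "", 1)[minus]
    orig <- sim$reads[read_id == rid, seq]
    expect_equal(vapply(fields, `[[`, "", 10)[minus], revcomp(orig))
  }
})
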