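test_that("truth assignment covers every dyad of eligible fragments", {
  g <- random_genome(2e4, seed = 71)
  frags <- size_select(digest_genome(g), 30, 250)
  withr::with_seed(1, truth <- assign_truth(frags, 0.2))
  # one state per dyad, dyads enumerated independently from repaired strands
  ref <- build_reference(g, size_range = c(30, 250))
  expected <- naive_expected_cpgs(ref, L = 10000L)  # unrestricted by L
  expect_equal(nrow(truth), length(expected))
  expect_equal(anyDuplicated(truth[, paste(chrom, pos)]), 0L)
  withr::with_seed(1, t0 <- assign_truth(frags, 0))
  withr::with_seed(1, t1 <- assign_truth(frags, 1))
  expect_true(all(t0$state == 0L))
  expect_true(all(t1$state == 1L))
})

test_that("iid truth states are calibrated to the methylation probability", {
  g <- random_genome(5e5, gc = 0.55, seed = 72)
  frags <- size_select(digest_genome(g), 30, 250)
  withr::with_seed(2, truth <- assign_truth(frags, 0.2))
  expect_gt(nrow(truth), 10000L)
  band <- stats::qnorm(0.995) * sqrt(0.2 * 0.8 / nrow(truth))
  expect_lt(abs(mean(truth$state) - 0.2), band + 1e-12)
})

test_that("mosaic truth keeps the marginal rate but clusters states", {
  g <- random_genome(3e5, seed = 73)
  frags <- size_select(digest_genome(g), 30, 250)
  withr::with_seed(3, truth <- assign_truth(frags, 0.2, "mosaic", 500L))
  expect_lt(abs(mean(truth$state) - 0.2), 0.05)
  # neighbouring dyads (same 500 bp block) share their state
  setkey(truth, chrom, pos)
  same_block <- truth[, .(agree = all(state == state[1]), n = .N),
                      by = .(chrom, block = pos %/% 500L)]
  expect_true(all(same_block$agree))
})

test_that("the fragment sampler hits the target mean length", {
  # two-point pool: weights solve w*40 + (1-w)*240 = 70 => w = 0.85
  frags <- data.table::data.table(
    chrom = "c", start = 0L, end = c(40L, 240L), seq = "x",
    length = c(40L, 240L), fragment_id = 1:2)
  s <- fragment_sampler(frags, 30, 250, 70)
  expect_equal(s$prob[1], 0.85, tolerance = 1e-6)
  withr::with_seed(4, {
    draw <- sample(frags$length, 10000, replace = TRUE, prob = s$prob)
  })
  expect_lt(abs(mean(draw) - 70), 3)
  # single eligible fragment is always sampled
  s1 <- fragment_sampler(frags[1], 30, 250, 70)
  expect_equal(s1$prob, 1)
  # uniform flag ignores the target mean
  su <- fragment_sampler(frags, 30, 250, 70, uniform = TRUE)
  expect_equal(su$prob, c(0.5, 0.5))
  expect_error(fragment_sampler(frags, 1, 10, 5), "no fragments")
})

test_that("make_read applies the bisulfite transform to the molecule", {
  frag <- digest_genome(toy_genome())  # CGGAACGTAC at [3, 13)
  truth <- data.table::data.table(chrom = "chr1", pos = c(3L, 8L, 13L),
                                  state = c(1L, 1L, 0L))
  cfg <- sim_config(n_reads = 1, read_length = 13L,
                    adapter = "AGATCGGAAG", seed = 1)
  rd <- make_read(frag, "+", truth, cfg)
  # methylated CpG Cs survive; the CHG C at index 9 and the artificial C
  # at index 10 read as T; spacer A follows at index 12
  expect_equal(rd$seq, "CGGAACGTATTGA")
  expect_equal(rd$g_start, 3L)
  expect_equal(rd$g_end, 3L + 12L)
  # unmethylated everything: no C left in the fragment-derived prefix
  truth0 <- data.table::copy(truth)[, state := 0L]
  rd0 <- make_read(frag, "+", truth0, cfg)
  expect_false(grepl("C", substr(rd0$seq, 1, 12)))
  # read shorter than the fragment never reaches the adapter
  cfg8 <- sim_config(n_reads = 1, read_length = 8L,
                     adapter = "AGATCGGAAG", seed = 1)
  expect_equal(make_read(frag, "+", truth, cfg8)$seq,
               substr(rd$seq, 1, 8))
})

test_that("bottom-strand reads mirror the fragment and share dyad truth", {
  frag <- digest_genome(toy_genome())
  truth <- data.table::data.table(chrom = "chr1", pos = c(3L, 8L, 13L),
                                  state = c(1L, 0L, 1L))
  cfg <- sim_config(n_reads = 1, read_length = 12L,
                    adapter = "AGATCGGAAG", seed = 1)
  rd <- make_read(frag, "-", truth, cfg)
  # bottom repaired: CGGTACGTTCCG; CpG Cs sit at dyad 13 (i=0, methylated)
  # and dyad 8 (i=5, unmethylated); the non-CpG C at i=9 and the
  # artificial C at i=10 always read T
  expect_equal(rd$seq, "CGGTATGTTTTG")
  expect_equal(rd$g_start, 13L + 2L - 12L)
})

test_that("simulated reads start with CGG or TGG and are reproducible", {
  g <- random_genome(4e4, seed = 74)
  cfg <- sim_config(n_reads = 1000, seed = 42)
  sim1 <- simulate_rrbs(g, cfg)
  sim2 <- simulate_rrbs(g, cfg)
  expect_true(all(substr(sim1$reads$seq, 1, 3) %in% c("CGG", "TGG")))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim1$reads, f1)
  write_fastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  # every read has exactly one origin record
  expect_equal(sim1$truth_reads$read_id, sim1$reads$read_id)
  # FASTQ round trip
  back <- read_fastq(f1)
  expect_equal(back$seq, sim1$reads$seq)
  expect_equal(back$read_id, sim1$reads$read_id)
})

test_that("an empty simulation writes a valid empty FASTQ", {
  g <- random_genome(4e4, seed = 74)
  sim <- simulate_rrbs(g, sim_config(n_reads = 0, seed = 1))
  expect_equal(nrow(sim$reads), 0L)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, f)
  expect_equal(length(readLines(f)), 0L)
  expect_equal(nrow(read_fastq(f)), 0L)
})

test_that("short fragments produce artificial-C and adapter read-through", {
  g <- random_genome(2e5, seed = 75)
  cfg <- sim_config(n_reads = 20000, seed = 6)
  sim <- simulate_rrbs(g, cfg)
  L <- cfg$read_length
  frag_len <- sim$fragments$length[match(sim$truth_reads$fragment_id,
                                         sim$fragments$fragment_id)]
  short <- frag_len <= L - 2L  # molecule reaches artificial CG and beyond
  # the sampler CDF at L - 2 predicts the read-through fraction
  pred <- sum(sim$sampler$prob[sim$fragments$length <= L - 2L])
  expect_lt(abs(mean(short) - pred), 3 * sqrt(pred * (1 - pred) / 20000))
  # reads from short fragments end in adapter sequence
  adapters <- substr(sim$reads$seq[short & sim$truth_reads$strand == "+"],
                     frag_len[short & sim$truth_reads$strand == "+"] + 4L,
                     L)
  expect_true(all(vapply(adapters, function(a)
    startsWith(cfg$adapter, a) || a == "", logical(1))))
})

test_that("incomplete conversion and sequencing error perturb reads", {
  g <- random_genome(3e4, seed = 76)
  cfg0 <- sim_config(n_reads = 500, meth_prob = 0, seed = 9)
  cfg1 <- sim_config(n_reads = 500, meth_prob = 0, seed = 9,
                     conv_efficiency = 0.5)
  base <- simulate_rrbs(g, cfg0)
  noisy <- simulate_rrbs(g, cfg1)
  # with p = 0 and full conversion no fragment C survives; at 50%
  # efficiency retained Cs reappear
  expect_false(any(grepl("C", substr(base$reads$seq, 1, 20))))
  expect_true(any(grepl("C", substr(noisy$reads$seq, 1, 20))))
  cfg2 <- sim_config(n_reads = 500, seed = 9, error_rate = 0.1)
  err <- simulate_rrbs(g, cfg2)
  expect_gt(sum(err$reads$seq != base$reads$seq), 0L)
})
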