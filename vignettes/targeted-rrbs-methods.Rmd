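---
title: "Targeted RRBS alignment and artificial-cytosine-aware methylation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted RRBS alignment and artificial-cytosine-aware methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbspipe)
```

## The model

RRBS libraries are not random shotgun libraries: MspI cuts at CCGG,
between the two cytosines on each strand, so every sequenced fragment is
an interval between two consecutive cut points and every read-1 of a
directional library begins at a fragment's 5' `CGG`. `rrbspipe` encodes
this structure in the reference instead of rediscovering it per read.

For a genome sequence, the cut points are `motif_index + 1` for every
CCGG occurrence; a fragment is `[c_i, c_{i+1})` in 0-based half-open
coordinates. Terminal pieces (one cut end only) cannot receive adapters
on both sides and are excluded. Because MspI leaves 5'-CG overhangs, end
repair fills each recessed 3' end with an *unmethylated* CG; the repaired
top strand of fragment `[s, e)` is therefore `genome[s, e) + "CG"` and
covers genomic `[s, e + 2)`, and the repaired bottom strand is its
reverse complement. The two filled-in cytosines are not hypothetical
bases: the top-strand one lifts to the genomic position `e`, the second C
of the downstream CCGG — a genuine CpG — and the bottom-strand one lifts
to position `s + 1`, the bottom-strand C of the fragment's first CpG.
This is exactly why they bias methylation estimates at fragment-junction
CpGs: they are always read as T (unmethylated) regardless of the genomic
CpG's true state.

Each repaired strand then receives the A-tailing spacer and the
sequencing adapter, and the whole entry is converted C→T. Reads are
converted the same way, so methylation differences cannot cause
mismatches, and reads that run through the fragment into the adapter
still align end-to-end — adapter handling becomes bookkeeping
(`adapter_start` per entry) rather than trimming.

### Assumptions

* Directional, single-end library: read 1 always starts at a fragment 5'
  `CGG` and is aligned forward-only against both strand entries.
* Single enzyme (MspI); double-digest protocols are out of scope.
* Ungapped alignment: RRBS reads are short and indels within a fragment
  are rare; placements are scored by Hamming distance only, qualities
  are ignored.
* Fragments containing N are excluded entirely; conversion and alignment
  semantics for ambiguous bases are undefined and N never matches.

## Alignment and multi-mapping resolution

The aligner is a deliberately simple seed-and-extend scheme: an exact
k-mer index over all converted entries is probed with the first `k`
bases of the converted read (default `k = 20` bp), and each posting is
extended over the full read length, accepting placements with at most
`M = 2` mismatches that fit entirely within the entry. Reads shorter
than `k` are reported unaligned.

Resolution follows the targeted-RRBS logic: a read hitting two or more
*distinct fragments* is discarded outright (the two strand entries of
one fragment count as the same fragment); among placements on a single
fragment, one that starts at the fragment start is preferred, since
directional RRBS reads physically begin at cut sites. Remaining ties
break deterministically: fewest mismatches, then smallest offset, then
top strand. Unique placements are lifted to genome coordinates — top
strand at `frag_start + offset`, bottom strand mirrored through the
fragment — with the appended CG keeping its genuine genomic coordinates
and spacer/adapter bases soft-clipped in the CIGAR.

Because the seed must match exactly, a placement whose only mismatches
fall inside the first `k` bases is invisible to the aligner even though
a full Hamming scan would find it. Error-free reads always carry an
exact seed, so this matters only at elevated error rates; the
equivalence tests against a brute-force all-offsets Hamming scan
therefore inject mutations beyond the seed region.

## Methylation calling

For every uniquely placed read, the *original* (pre-conversion) bases
are piled up over the entry's repaired sequence; bases in the
spacer/adapter tail contribute nothing. At each reference cytosine the
ratio is `#C / (#C + #T)`; read bases other than C/T at a reference C
(sequencing errors) are excluded from numerator and denominator. The
exclusion rule is per strand: the top entry's artificial C (lifting to
the downstream junction CpG) and the bottom entry's artificial C
(lifting to the upstream junction CpG on the bottom strand) are masked,
while the genuine opposite-strand cytosines of those same CpGs still
count. A CpG covered only by artificial evidence is simply not called.
`exclude_artificial = FALSE` reproduces the biased "before removal"
condition for diagnostics. Strand calls are merged into CpG dyads at the
+ strand C coordinate; non-CpG contexts are computed but hidden behind
`context = "all"`, as CpG is the evaluated context.

Coordinates are 0-based half-open internally, 1-based in the TSV report,
and 0-based half-open in bedGraph, following each format's convention.

## The simulator: what it emulates, and what it does not

The simulator reproduces the library chemistry exactly as modelled
above: fragment sampling from the size-selected pool, uniform strand
choice, reads starting at the fragment 5' end, the unmethylated
artificial CG, A-tail and adapter read-through for fragments shorter
than the read, complete bisulfite conversion, and constant Q40
qualities. Defaults are 50 bp reads, a 30–250 bp pool with mean sampled
length 70 bp, and a per-CpG methylation probability of 20%.

Methylation truth is a *binary state per CpG dyad*, shared by both
strand cytosines, drawn once per dyad. This is the reading under which
an exact pipeline can recover truth perfectly (a per-read coin flip
would bound the attainable R² well below 1 at finite coverage). Two
truth models are provided:

* `iid` (default): independent Bernoulli(p) per dyad — the calibration
  model. Neighbouring CpGs are independent, so methylation
  autocorrelation is ~0 by construction.
* `mosaic`: one Bernoulli(p) state per fixed-width genomic block
  (default 500 bp), inherited by all dyads in the block. Marginal rate
  is still p, but nearby CpGs correlate, emulating the clustered
  methylation of real genomes. This is the model under which the
  artificial-C autocorrelation contrast is meaningful: kept artificial
  Cs drag junction CpGs toward 0 irrespective of their block, visibly
  degrading the distance-correlation curve.

The fragment-length weighting is a truncated exponential
`w(len) ∝ exp(-λ·len)` with λ solved (by `uniroot`, centred weights to
avoid overflow) so the expected sampled length equals the target mean;
`uniform_weights = TRUE` bypasses the calibration. The target mean must
lie strictly inside the pool's length range, otherwise the sampler
refuses rather than silently saturating.

What the simulator does **not** model: PCR duplicates and coverage
overdispersion beyond multinomial sampling, CHG/CHH methylation (all
non-CpG cytosines convert), quality-score variation along the read,
indels, incomplete digestion, and real genomes' repeat structure
(synthetic genomes are i.i.d. base draws at a chosen GC content, so
fragment-sequence collisions are far rarer than on a mammalian genome).
Passing round-trip tests on this generator demonstrates the pipeline's
internal correctness — coordinates, masking, resolution rules — not
robustness to every artefact of real libraries. Optional
`conv_efficiency < 1` and `error_rate > 0` switches perturb reads for
robustness testing.

## Numerical and degenerate-input choices

* Size selection is inclusive on the genomic cut-to-cut length (before
  the +2 bp of end repair); a reference built for simulated data uses
  the simulator's own 30–250 bp range so every simulated read has its
  fragment in the reference.
* Zero or one CCGG site is a valid genome with zero fragments, not an
  error; an empty reference warns and writes empty but valid files.
* `r_squared` and per-distance autocorrelation return NA (with a
  warning where user-facing) below 3 pairs or at zero variance, rather
  than a spurious number.
* Duplicate counting in `fragment_uniqueness` counts every member of a
  duplicate group (2 identical among 4 → 50%); `counting = "group"`
  counts groups once. Conversion can only merge sequences, so the
  converted percentage is provably ≥ the raw one.
* CpG recall needs a denominator the protocol itself defines only
  loosely ("expected CpGs"); here it is the union over size-selected
  fragments of CpG dyads reachable within the first L bases of either
  strand *excluding* dyads reachable only through an artificial C. This
  makes 100% recall attainable exactly when every reachable dyad is
  covered.
* All randomness flows through explicit seeds (`withr::with_seed`), and
  every writer emits byte-stable output, so a fixed configuration
  reproduces FASTQ/SAM/TSV/bedGraph byte for byte.

## Problem sizes

The bundled verification runs use synthetic genomes of 0.05–1 Mb at GC
0.55 (≈ 3,500 eligible fragments and ≈ 25,000 covered CpG dyads per Mb)
and up to 200,000 simulated reads — large enough for tight binomial
bands on the calibration checks (the 99% band on the 20% methylation
rate at 25,000 dyads is about ±0.65 points) while keeping a full test
cycle under a minute on a single core. Heavy read duplication in
error-free mode lets the aligner collapse identical reads, so runtime is
dominated by reference indexing, not read count.

## Known limitations

* No paired-end or non-directional support; read 2 geometry (which
  starts at the *other* cut site) is structurally analogous but not
  implemented.
* The built-in aligner is exact-seeded and ungapped; a pluggable
  external end-to-end aligner backend is a natural extension point for
  higher error rates or indels.
* Fragment-uniqueness percentages on real mammalian genomes depend on
  repeat content and cannot be extrapolated from synthetic genomes; the
  function is provided for users with a real genome FASTA at hand.
* Whole-chromosome strings are held in memory; fine to a few hundred Mb,
  not engineered for many-gigabase genomes.
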