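---
title: "Detecting ZW sex-linked regions from coverage, FST and k-mer evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ZW sex-linked regions from coverage, FST and k-mer evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a ZW system females are the heterogametic sex: they carry one Z and one W,
males carry two Z. Sequence present only on the W (the sex-determining
region, SDR) is therefore found in females at haploid copy number 1 and in
males at copy number 0; sequence present only on the Z is found in females
once and in males twice; pseudoautosomal and autosomal sequence is diploid in
both. `zwscan` turns these copy-number expectations, plus two orthogonal
signals (intersexual allelic differentiation and sex-specific k-mers), into
windowed statistics and integrated region calls, and characterizes the
structural hallmarks of the SDR itself.

The package ships a synthetic-data module that builds a miniature ZW genome
with a machine-readable planted truth, so that every stage of the pipeline is
testable end to end without any external data.

# Lines of evidence

## Windowed normalized coverage ratio

For each sample, per-base depths are averaged in nonoverlapping windows of
`w` bp (default 10,000, tiled from position 0; a final partial window is kept
but flagged). Each sample's window means are divided by that sample's mean
depth over a *representative autosome*, removing library-size differences.
The per-window statistic is

\[
r = \log_2(\bar d_F + \varepsilon) - \log_2(\bar d_M + \varepsilon),
\]

where \(\bar d_F, \bar d_M\) are the normalized window means averaged over
female and male samples. Expectations: 0 for diploid windows, about −1 for
Z-specific windows (1 female copy vs 2 male copies), and large positive
values for W-specific windows (1 vs 0).

Choices a user should know:

* **Pseudo-count** `eps = 0.001` (normalized-depth units). It only matters
  where a group mean is near zero: W-specific windows stay finite
  (\(\log_2(0.5/0.001) \approx 9\)) instead of infinite. It is kept small so
  the Z-specific expectation is \(\log_2(0.501/1.001) = -0.999\), i.e. the
  −1 expectation is not visibly distorted; a large pseudo-count (say 0.05)
  would bias it to −0.93.
* **Missing floor** `floor = 0.1`: windows where both group means are below
  it are classed `missing` rather than producing ratios of noise.
* The statistic is computed as a difference of logs so that exchanging the
  sex labels negates it exactly.

## The autosome-resampling band

The null band for \(r\) is obtained by resampling the representative
autosome's window values with replacement 1,000 times; the band is the mean
over replicates of each replicate's 2.5th/97.5th percentiles (a mode using
the replicate means instead is exposed via `stat = "mean"`; neither mode is
canonical, window-value resampling is the default because windows are the
unit of inference throughout). Replicate percentiles use quantile type 6
(plotting position \((n+1)p\)): with 50 windows the default type-7 convention
places the 2.5th/97.5th percentile inside the 2nd/3rd extreme order
statistics, which structurally leaves about 8% of windows outside a nominal
95% band; type 6 restores the nominal level.

## Window classification

* **W-specific**: \(r\) above the band *and* at or above `w_threshold`
  (default +0.5).
* **Z-specific**: \(r\) below the band *and* at or below `z_threshold`
  (default −0.5).
* **PAR/autosomal**: inside the band.
* **ambiguous**: outside the band but inside the hard thresholds.

The hard thresholds exist because the resampling band measures only sampling
noise; with per-base Poisson depth averaged over 10-kb windows and 12 + 12
samples the band is extremely tight (about ±0.002), so roughly 5% of
perfectly diploid windows fall outside it by construction. Hemizygous
regions sit near −1 or far above 0, so requiring half a copy's worth of
signal (±0.5 in log2) separates biology from band noise without losing any
true window. Windows beyond the band but inside the thresholds remain
visible as `ambiguous` rather than being silently dropped.

## Windowed intersexual Weir–Cockerham FST

Allelic differentiation between the sexes is estimated per biallelic site by
the Weir & Cockerham (1984) variance components \(a\) (among populations),
\(b\) (among individuals within populations) and \(c\) (within individuals),
with the two "populations" being the sexes, observed heterozygosity, and
unequal (and per-site missing-data-reduced) sample sizes. The windowed
estimate is the weighted (ratio-of-sums) form
\(\sum a / \sum (a+b+c)\) over the polymorphic sites in the window.
Negative values are reported as-is. Sites with fewer than two called
genotypes in either sex are skipped and counted. Genotypes in hemizygous
regions (a W allele paired with a Z allele but called diploid upstream) are
taken at face value — that is exactly the signal: at a fully sex-linked site
every female is heterozygous and every male homozygous, giving
\(F_{ST} = 0.5\) at equal sample sizes.

The default site filters (biallelic SNPs, per-sex call rate ≥ 0.8) are
exposed as arguments; they are ordinary post-calling filters, not part of
the estimator.

## Sex-specific k-mers

Per individual, reads are decomposed into canonical k-mers (k = 31 by
default, odd so no k-mer equals its own reverse complement; canonical = the
lexicographically smaller of k-mer and reverse complement, computed on a
2-bit encoding in compiled code). A k-mer is *present* in a sample when seen
at least `min_count` times (default 2, suppressing singleton sequencing-error
k-mers). Female-specific k-mers are present in at least
`ceiling(min_female_frac * n_females)` females (default fraction 0.9,
generalizing "present in nearly all females") and at most `max_male_presence`
males (default 0). They are localized on the assembly by exact strandless
dictionary matching and clustered into maximal intervals whose consecutive
hits are at most `max_gap` apart (default 5,000 bp, half a window; the gap
keeps genuinely separated k-mer groups as separate intervals).

## Haplotype structural comparison

The phased Z and W sequences are compared by unique-anchor chaining: k-mers
(k = 21) occurring exactly once in each sequence and matching across them are
merged into maximal exact anchors, the highest-total-length strictly
collinear subset is selected (weighted longest-increasing-subsequence;
overlaps up to 10 bp are tolerated because single-base junction ambiguities
can extend adjacent anchors into each other), and inter-anchor gaps are
interpreted: near-zero on one side with ≥ `min_len` (default 50 bp) on the
other is a haplotype-specific insertion; large on both sides is reported as
a divergent region, never as an insertion. Boundary precision is limited by
the anchor seed length; exact boundaries of biological features are
recovered downstream by the hallmark scanners.

## Structural hallmark scanners

* **Telomere arrays**: all rotations of the canonical plant telomere repeat
  `CCCTAAA` and of its reverse complement (14 variants) are matched; bases
  covered by any variant are merged, runs ≥ 750 bp reported, and classified
  terminal when within 1,000 bp of a sequence end, else interstitial.
* **Terminal inverted repeats**: longest prefix whose reverse complement
  matches the suffix within a mismatch budget (default 0 — reported repeats
  in this class of elements are exact).
* **Target-site duplications**: longest exact direct repeat (2–20 bp)
  immediately abutting the insertion's outer flanks.
* **LTR direct repeats**: local alignment of the element's two terminal
  windows (match 2, mismatch −3, gap open 5, extend 2) yields the
  near-identical arm pair; arm lengths, edit count (mismatches plus indel
  bases) and the element's flanking dinucleotides are reported, with
  `TG.CA` flagged canonical.
* **Retrogene hallmarks**: longest A-run ≥ 10 bp within 500 bp downstream of
  the stop codon, and the longest exact direct-repeat pair ≥ 8 bp with one
  copy just downstream of the poly-A and one within 500 bp upstream of the
  start codon (longest-common-substring via prohibitive-penalty local
  alignment); positive only when both are found.
* **Palindromes**: seed k-mers of the sequence matched against its reverse
  complement, merged along anti-diagonals into maximal exact
  inverted-repeat runs; arms ≥ 1,000 bp with spacer ≤ `max_spacer` are
  reported.

## Integration

Same-class W/Z windows within `merge_gap` (default 20 kb, two windows) are
merged into candidate regions. Each region gets three evidence flags:
coverage (constitutive), FST (an overlapping window exceeds the 97.5th
percentile of autosomal windowed FST — making the usual judgment that
sex-linkage should show elevated FST, made explicit as an autosomal
percentile because no significance rule is canonical), and k-mer (≥ 1
overlapping female-specific k-mer interval). Calls are ranked by evidence
count then peak |log2 ratio|; single-evidence calls are kept but tagged
`weak` — mirroring how a coverage-only spike with no k-mer support is best
treated as a likely artifact rather than silently removed.

# The synthetic-data module

`zw_blueprint()` describes a miniature genome; `build_genomes()` materializes
it. The default (`zw_blueprint_default()`) is three 500-kb backbone
chromosomes (a sex pair, the representative autosome, a second autosome) —
large enough for ≥ 50 10-kb windows per chromosome, small enough that the
whole pipeline runs in a couple of minutes on one CPU. Planted on it:

* a 31,455-bp W-specific SDR insertion with exact 29-bp terminal inverted
  repeats;
* inside the SDR, a 4,923-bp LTR element whose arms are planted identical
  and then given exactly 1 substitution + 1 single-base insertion (arms
  208/209 bp), flanks `TA.TA` (noncanonical), and a retrogene with a 16-bp
  poly-A 99 bp downstream of its stop codon and 13-bp direct repeats
  adjacent to the poly-A and 152 bp upstream of the start codon;
* a 60-kb Z-specific insertion with 14-bp terminal inverted repeats and
  `TTA` target-site duplications (the element class of a *Harbinger*-type
  DNA transposon; its size is kept at coverage-window scale so the Z dip is
  callable — the 1.7-kb scale of such elements is exercised in the tests
  through custom blueprints);
* ~1.1-kb terminal telomere arrays on every chromosome end plus one 119-bp
  interstitial array;
* a palindrome with 1,000-bp arms and a 50-bp spacer on the second autosome.

The reference assembly's sex chromosome is the Z/W *mosaic* (backbone + both
haplotype-specific insertions), mirroring how a haplotype-collapsed
pseudomolecule contains stretches of both parental haplotypes; every planted
feature therefore appears exactly once on the reference, and all evidence
lines share one coordinate system. The two phased haplotypes are also
emitted separately for the structural comparison.

Background sequence is i.i.d. uniform A/C/G/T (a GC fraction is
configurable): the statistics under test depend on copy number and planted
motifs, not on realistic composition. Wherever an exact repeat is planted,
the immediately flanking bases are chosen so the repeat cannot be extended
by chance, which makes "recovered with the exact planted length" a
well-defined property.

Simulators:

* `simulate_depth()` draws per-base depths directly as Poisson with mean
  `target_depth × copy_number(sex)` — read mapping is deliberately not
  emulated; the downstream statistics consume depth.
* `simulate_reads()` draws uniform-start, random-strand, fixed-length reads
  from the haplotypes an individual carries (females Z + W + autosome
  pairs, males 2 × Z + autosome pairs), with an optional uniform
  substitution error rate (default 0; error tolerance in the k-mer stage is
  governed by `min_count`).
* `simulate_variants()` writes a VCF v4.2 with neutral sites (ALT frequency
  uniform on \([\theta, 1-\theta]\), θ interpreted as a minor-allele-
  frequency floor, Hardy–Weinberg genotypes independent of sex — the
  generator is an artifact choice, the original study used real data) and
  fully sex-linked sites inside the planted non-recombining region (every
  female 0/1, every male 0/0, W allele = ALT by fixed convention).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: mappability and GC biases, depth overdispersion
beyond Poisson, indel and structured sequencing errors, linked reads,
population structure within sexes, recombination gradients at the PAR
boundary, and repeat-driven mis-mapping. On real panels the coverage band is
wider and set by biological and technical overdispersion rather than pure
counting noise; the hard class thresholds (±0.5) are then doing real work
and may need loosening for low-coverage panels.

# Worked example

```{r example}
library(zwscan)
scan <- zw_run(seed = 1)
print(scan)
write_zw_report(scan, "zwscan_report")
```

`zw_run()` executes simulate → coverage → FST → k-mers → haplotype diff →
annotate → call on the synthetic defaults (12 F + 12 M at 20× per haploid
copy; k-mer stage at 15× per copy) and returns a `zw_scan` object whose
`print` method lists the band, the FST bound, the k-mer intervals and the
ranked region calls. All randomness derives from the single `seed`, and a
fixed seed reproduces the report files byte for byte.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; depth tables are 1-based
  (samtools-depth convention); BED output stays 0-based half-open.
* Windows with no depth rows have mean 0 (absent positions are zeros, not
  missing); the `missing` class is driven by the normalized floor instead.
* The final partial window is kept and flagged; dropping it would discard
  telomeric signal.
* Monomorphic sites return components (0, 0, 0) and are excluded from
  window sums; a windowed FST with no usable sites is missing, not 0.
* `sample.int`-based resampling and all simulators derive their streams
  from one user seed through fixed per-stage offsets, so stages are
  individually and jointly reproducible.
* TSD maximality: the longest qualifying duplication is reported; its upper
  bound (20 bp) exists only to bound the search. "Adjacent" for the
  retrogene direct repeat means offset 0 from the poly-A within a 2-bp
  slack.
* Problem sizes used by the test suite: the full study conditions
  (3 × 500 kb genome, 12 + 12 samples at 20×) for the end-to-end and
  coverage-expectation checks, and 30–80 kb genomes with 4–8 samples for
  per-module properties. These sizes are the package's own choice of a
  desk-scale study; they keep the complete suite to a few minutes.

# Known limitations

* The k-mer stage holds per-sample presence sets in memory; it is sized for
  desk-scale genomes (megabases), not vertebrate-scale data, where external
  counters would be the right tool.
* The haplotype comparison reports inversions and translocations only as
  divergent regions; it is an insertion caller, not a general
  structural-variant caller.
* Palindrome and anchor seeding use exact unique k-mers; highly repetitive
  arms (e.g. satellite-rich palindromes) would need a mismatch-tolerant
  seeder.
* The FST module implements the two-population Weir–Cockerham estimator
  only; Hudson- or Nei-style estimators are out of scope.
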