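---
title: "Designing and analyzing pooled CRISPRa/CRISPRi droplet screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and analyzing pooled CRISPRa/CRISPRi droplet screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprscreen)
```

# The problem

A pooled CRISPR activation/interference screen perturbs the expression of
thousands of genes at once: a library of single guide RNAs directs a dead
Cas9 fused to an activator or repressor to promoter regions; cells are
encapsulated in droplets with a fluorogenic substrate, sorted into high-
and low-signal fractions, and the guides recovered from each fraction are
sequenced. A gene matters for the phenotype when its guides are enriched
in the high fraction. This package implements the computational chain
around such a screen — guide design, off-target filtering, synthesis oligo
layout, read counting, and the enrichment statistics — plus simulators
that make every stage testable without external data.

This vignette explains the models, the parameters that matter, and the
numerical and design choices the implementation makes.

# Guide design

## Promoter windows and bins

Candidates for a feature are SpCas9 protospacers (20 nt followed by an NGG
PAM, either genomic strand) whose **cut site** falls between 400 bp
upstream and 100 bp downstream of the feature's TSS, measured in the
feature's transcriptional orientation (closed interval; negative offsets
are upstream). The cut site — between protospacer positions 17 and 18,
3 bp 5′ of the PAM — is the anchor because it is the standard design
reference point and is strand-symmetric; the window anchor for downstream
neighbor analyses defaults to the same point.

When a feature has fewer than six candidates, all are taken. Otherwise the
300 bp upstream of the TSS are divided into six 50-bp bins (half-open,
`[-300,-250) … [-50,0)`, so they partition the region), and the
highest-scoring candidate is taken from each bin; candidates outside the
binned region (offsets in `[-400,-300)` or `(0,+100]`) are ineligible in
bin mode. We read the selection procedure as binding: with six or more
candidates, only binned positions are used. Score ties break toward the
smaller `|offset|`, then the lexicographically smaller protospacer —
purely so repeated runs produce byte-identical libraries.

## Scoring

On-target activity prediction is a pluggable interface: any function
mapping a 20-mer to `[0, 1]` can be passed as `scorer`. The default,

```
score = clamp(1 − 2·|GC − 0.5| − 0.25·H, 0, 1)
```

(`GC` the G+C fraction, `H` = 1 if the protospacer contains a homopolymer
run of ≥ 5), is deliberately simple and deterministic: it encodes the two
coarsest empirical activity correlates (balanced GC, no long runs) and
keeps the toolkit self-contained. It is a stand-in interface default, not
a validated activity model; for production libraries inject a trained
scorer.

## Off-target filtering

Every PAM-adjacent 20-mer in the genome is indexed (both strands,
protospacer orientation). A guide is removed when any *other* site — or
any other library guide — lies within fewer than 3 Hamming mismatches over
the full 20-mer. Conflicting guide pairs are removed symmetrically, since
either member could act at the other's locus. The metric is ungapped and
unweighted: a plain mismatch count over the protospacer, PAM excluded.
Seed-region weighting and bulge off-targets are out of scope.

The index answers "is anything within 2 mismatches?" via a pigeonhole
partition: a 20-mer is split into segments of 7 + 7 + 6, and any site
within Hamming distance ≤ 2 must match at least one segment exactly, so
only sites sharing a segment need full distance computation. The exact
20-mer hash resolves duplicate sites (distance 0) directly. A quadratic
brute-force scan is retained and used as the oracle in the test suite.

## Synthesis-motif screening

`design_library()` also drops candidates whose protospacer contains the
cassette enzyme's recognition sequence on either strand (`GCTCTTC` /
`GAAGAGC` by default). Such a guide cannot be carried by the oligo
cassette — the digest that releases guides would cut inside it — so any
cassette-based library must exclude them at design time; `pack_oligos()`
independently rejects them as a safety net.

# Oligo cassettes and digest

Four guides are packed per 190-bp synthesis oligo:

```
left_flank · left_site · g1 · spacer · g2 · spacer · g3 · spacer · g4 · right_site · right_flank
 11 bp        11 bp      20    22 bp    20    22 bp   20    22 bp   20    11 bp       11 bp
```

The internal spacers carry the BspQI recognition sequence on both strands,
so one digest releases all four guides with the recognition sites staying
on the discarded spacer fragments. The digest simulation places a single
double-strand breakpoint per recognition site — one base 3′ of a
top-strand site, one base 5′ of a bottom-strand site — and returns
fragments that tile the oligo exactly. BspQI actually leaves 3-nt 5′
overhangs; modeling the two staggered nicks would complicate fragment
bookkeeping without changing which guides are released, which is the
testable claim, so overhang chemistry is documented here but not modeled.
Guide-bearing fragments are 26 bp (`AGG·guide·GTT`); their cores are
identified against a supplied library, or, absent one, by trimming the
three residual spacer bases from each end.

Layouts are configuration, not constants: other enzymes and slot counts
can be expressed, and the length law `|oligo| = 44 + 20n + 22(n−1)` holds
for any slot count `n` under the default flank/spacer lengths. A partial
final oligo is completed with a fixed filler 20-mer, flagged in the
manifest and never entering the guide library.

# Quantification

Reads carry an inline sample barcode (4–6 nt, validated prefix-free) at
the read start, then a constant flank, then the 20-nt guide. Demultiplexing
is exact prefix matching; counting extracts the 20 nt after the first
exact flank occurrence and looks them up exactly in the library. Exact
matching replaces alignment deliberately: library guides are pairwise ≥ 3
mismatches apart by construction, so a single sequencing error cannot
convert one guide into another — it lands in the `no_guide` counter
instead of a miscount. Per sample, assigned + `no_guide` (+ its share of
`no_barcode`) equals the input reads; this conservation is tested.

# Enrichment statistics

## Normalization

RLE (median-of-ratios) factors: for each sample, the median over
all-positive guides of the ratio of the guide's count to its across-sample
geometric mean, rescaled to geometric mean 1. Effective library sizes —
the GLM offsets — are the factors times the geometric mean of the column
sums, so they are proportional to the median-of-ratios size factors. (The
factors themselves, having geometric mean 1, are reporting-friendly; only
the relative effective sizes enter the model, so the overall scale is a
convention.)

## Dispersion

Counts are modeled NB with variance `μ + φμ²`. The common φ maximizes the
Cox–Reid adjusted profile likelihood of the two-group model: per guide and
group, the group mean is profiled out (vectorized Fisher scoring on the
log-mean with offsets), and the adjustment subtracts half the log Fisher
information, which for a one-factor design is block diagonal per group.
The maximization runs on a 21-point log-spaced grid over `[1e-4, 4]`
refined by golden-section search to a tolerance of 1e-4; the grid result
is tested against a dense 1000-point profile. Guides with an all-zero
group are excluded from estimation (their information term degenerates).
Optional tagwise dispersions maximize each guide's own adjusted profile
likelihood plus `prior_df` times the average profile; as `prior_df → ∞`
they collapse onto the common value. The default `prior_df = 10` follows
common practice for screens with few replicates.

## Testing and calls

Per guide, the likelihood-ratio statistic compares the full model
(intercept + fraction) to intercept-only, both with effective-size
offsets, against χ² with 1 df. The group fits are one-dimensional
profiled means, so the full fit is exact rather than IRLS-iterative; the
test suite checks it against a direct two-parameter likelihood
maximization and against an independent GLM implementation at fixed
dispersion (agreement ~1e-6 in p). Replicates across screens are pooled
into the two fractions; screen-specific batch terms are out of scope.

The reported `log2FC` refits the group means with a prior count of 0.125
(scaled by relative library size) so zero-count guides report finite fold
changes; the LRT itself uses raw counts. All-zero guides are not fitted:
`p = 1`, `log2FC = 0`.

FDR control is Benjamini–Hochberg (`stats::p.adjust`; the hand step-up is
the test oracle). A guide is **enriched** when `log2FC > 3` and
`FDR < 0.05`, both strict, as gates of that form are conventionally
printed. Gene summaries take, per gene, the guide with the highest fold
change among those passing a laxer gate (`log2FC > 3`, `FDR < 0.3`) — a
representative-guide rule that tolerates noisier per-guide FDRs when at
least one guide is individually convincing; genes with no passing guide
are omitted.

## Screen planning

Droplet loading is Poisson with mean λ (default 0.4): occupancy
probabilities are `(e^{−λ}, λe^{−λ}, 1−(1+λ)e^{−λ})`, and screening fold
coverage is `droplets × λ / library size` — the expected number of
screened cells per library guide. At λ = 0.4, 800 000 droplets over a
40 890-guide library give 7.8-fold coverage; 2 million give 19.6-fold.

# Neighbor analysis for non-coding RNAs

Hits on long non-coding RNAs (SUTs/CUTs in yeast) are interpreted through
the genes around them: `neighbor_features()` reports every feature whose
span intersects a closed 1-kb window centred on the query position
(defaulting to the guide's cut site, the caller may anchor elsewhere) and
classifies each by orientation: `antisense_overlapping` (opposite strand,
span contains the query), `divergent` (opposite strand, transcribing away
— a bidirectional-promoter candidate), `convergent` (opposite strand,
transcribing toward), `sense_overlapping`, `tandem_upstream` and
`tandem_downstream` (same strand, feature TSS down-/upstream of the query
in its transcriptional direction). The six classes are total over every
strand/position configuration. A natural "within window/2" condition on
divergent TSSs needs no explicit guard: for a window hit pointing apart,
the TSS sits at the window-proximal end of the span and is therefore
automatically within half a window of the query. The window is closed at
both ends; one base of slack is immaterial but must be fixed.

Coordinates are 1-based closed in memory (the R/Bioconductor convention);
BED files are read and written in their native 0-based half-open dialect,
converted only at the file boundary.

# The simulators, and what passing tests mean

`simulate_genome()` builds a uniform-random chromosome with features in
non-overlapping 700-bp slots (alternating strands, types cycling
ORF/SUT/CUT) and plants the requested number of protospacer+PAM sites in
each promoter's binned region, spread across bins. `simulate_screen_counts()`
draws NB counts with per-guide baseline abundances log-normally scattered
(sd 0.25 on the log scale) around `mean_depth`, and applies the spiked
effect symmetrically (`×2^{l/2}` in the high means, `×2^{−l/2}` in the
low) so overall depths stay comparable. `simulate_reads()` emits exactly
the table's counts as barcode·flank·guide·adapter reads, deterministically
shuffled. All generators are pure functions of (parameters, seed): they
save and restore the caller's RNG state.

The default simulated operating point — 4 + 4 replicates, mean depth 200,
φ = 0.15, 5% of guides spiked at log2FC = 4 — mirrors the replication,
dispersion and effect-size regime a droplet screen of this type reports.
At this point the LRT's type-I error at α = 0.05 is ≈ 0.05, its null
p-values pass a KS uniformity check, dispersion recovery lands within
±20% of truth, and sensitivity at the strict gate exceeds 0.98 with no
false positives — these are the quantities `scripts/acceptance.R`
recomputes. Problem sizes there (5000 guides for calibration, 2000 for
dispersion recovery, a 10-feature demo genome) were chosen as the smallest
that make the stochastic checks stable across seeds.

What passing does **not** show: the simulators draw independent NB counts
with a single dispersion and no guide–guide correlation, no growth
competition between clones, no sequencing errors, no sorting impurity, no
chromatin effects on guide activity, and uniform random genome background
(which is PAM-dense — a real genome's PAM-poor promoters will more often
fall below six guides). Calibration on simulated data bounds what the
statistics can do under their own assumptions; real screens add the above
nuisances on top.

# Degenerate inputs and numerical conventions

* Empty genomes scan to empty site lists; a chromosome absent from an
  annotation yields an empty (not erroneous) neighbor report.
* `min_mismatch_to_others()` returns `Inf` when the index holds only the
  guide itself; a second identical location returns 0.
* RLE normalization refuses tables with no all-positive guide and points
  at the low-count filter; a single sample gets factor 1.
* The low-count default (CPM > 1 in at least half the samples) is a
  configurable convention — screens report pool fractions surviving such a
  gate without standardizing it.
* LRT statistics are clamped at 0 (profiling can produce −1e-12); p-values
  live in (0, 1].
* Golden-section tolerance 1e-4 on φ is far below the ±0.02 reproducibility
  of the estimate across simulation seeds.

# Package shape

The toolkit surface follows the pipeline (design → off-target → pack →
count → test), with one model-style entry point, `screen_test()`,
returning a classed object with `print()`/`summary()` methods, because the
statistical readout is the one stage users re-run interactively with
varied thresholds. A thin shell front-end (`inst/cli/crisprscreen`)
exposes the same verbs for scripted use; the R functions are the tested
surface.

# Known limitations

* The default scorer is a coarse heuristic interface default, not a
  trained activity model.
* Off-target filtering is Hamming-only (no gaps, no NAG PAMs, no
  position weighting).
* Exact-match counting discards reads with any error in the guide; at
  typical error rates this costs a roughly uniform few percent of depth,
  which the fraction comparison cancels.
* Two-group designs only (high vs low); multi-factor batch modeling is
  out of scope.
* The digest model asserts guide release, not ligation-ready overhangs.
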