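---
title: "Quantifying PCR amplification bias in Hi-C libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PCR amplification bias in Hi-C libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hi-C counts ligation events between crosslinked chromatin fragments as a
proxy for three-dimensional contact frequency. Almost every Hi-C protocol
PCR-amplifies the ligation products before sequencing, and amplification has
two costs. First, it creates duplicates: multiple sequenced copies of one
ligation molecule, which must be collapsed and which waste sequencing depth.
Second, it skews the library composition — amplification efficiency depends
on fragment GC content and, more subtly, on the genomic separation of the
ligated ends, so that short-range contacts end up under-represented and
long-range contacts over-represented relative to an amplification-free
library. An amplification-free protocol sidesteps both costs, and duplicates
it does produce are *independent ligations of identical fragment pairs* and
are legitimate signal that should be kept.

`hicamp` implements the complete post-alignment battery needed to make this
comparison quantitative, plus a synthetic library generator with an explicit
PCR model, so every stage can be validated against planted ground truth.

## The synthetic library model

`sim_config()` + `simulate_genome()` + `simulate_true_ligations()` +
`amplify()` + `sequence_library()` generate a library in four stages, each
deterministic given the config seed (each stage derives its own RNG stream
from the seed, so stages are individually reproducible).

**Genome.** Restriction-fragment lengths are i.i.d. exponential with rate
`log(2)/194` so the *median* spacing matches the 194 bp genome-wide median of
a 4-cutter digest — the one fragment-geometry statistic we anchor to. TADs
tile each chromosome with lengths uniform in `[tad_min_bp, tad_max_bp]`
(default 200–400 kb). Loop anchors are snapped to centers of
`2 * loop_radius_bp` windows so a planted loop occupies exactly one pixel at
the matching resolution. Compartment labels alternate A/B in blocks of 10 ×
10 kb windows; per-window GC is Beta-distributed with mean 0.42 (a
fly-genome-like mean) and SD 0.08.

**Ligations.** Cis separations follow a power law `P(s) ∝ s^α` on
`[1 kb, L]` with `α = -1` by default (the fractal-globule regime). Structure
is imposed by *rejection sampling*: a candidate pair inside one TAD is
up-weighted `tad_enrichment`-fold (default 4), same-compartment-label pairs
`compartment_strength`-fold (default 2). Rejection sampling draws exactly
from the weighted density and never duplicates a molecule, which matters
because downstream deduplication is evaluated against these molecule ids.
The trans/cis split is decided first by a binomial draw (default trans
fraction 0.069, i.e. cis/trans ≈ 13.5, the value a good library shows), so
class proportions are not distorted by the weighting. Loops are planted
afterwards: for each loop the expected background count at its pixel is
estimated from a 20×-wider neighborhood (scaled by the area ratio — stable
at desk-scale coverage where the pixel itself holds ≪ 1 count), and
`Poisson((loop_enrichment - 1) × λ)` extra pairs are added at the pixel.
Because of these extras the returned set slightly exceeds
`n_true_ligations`.

**PCR.** Amplification is a per-cycle branching process. In every cycle each
existing copy of molecule *i* duplicates with probability

    p_i = clamp(p · (1 + b_gc (gc_i − 0.5)) · (1 + b_d (log10 s_i − μ)), 0, 1)

with `p` the base efficiency (default 0.7), `μ` the library-mean log10
separation, and trans pairs taking distance factor 1. With `p = 1` and no
bias every copy number is exactly `2^cycles` (a conservation law the tests
assert). The distance term is linear in `log10 s` and centered at `μ` —
the simplest monotone model that reproduces the observed crossing shape of
the amplified/unamplified decay ratio. Defaults `b_gc = 0.5`, `b_d = 0.1`
give, after 12 cycles, a ~2.5-fold differential between separations one
decade apart: enough to displace decay curves visibly without saturating
`p_i`.

**Sequencing.** `n_sequenced` records are drawn *with replacement* with
probability ∝ copy number (so even an unamplified library shows
birthday-collision duplicates at deep sampling, as a real one does), given
flow-cell coordinates (lane 1–8, tile 1–96, pixels uniform on [0, 30000] —
instrument geometry is arbitrary; it only needs to support the optical-
duplicate contract), and with probability `optical_dup_rate` (default 0.005,
matching the <1% observed in practice) a record is re-emitted on the same
tile with pixel offsets of scale `optical_pixel_sigma` (10 px).

What the generator does **not** emulate: mappability and alignment error,
fragment-size selection, chromatin accessibility bias, inter-chromosomal
compartment structure, and the sequence-level mechanism behind the distance
bias (self-hybridization of abundant ligates) — only its phenomenological
form. A green test therefore establishes that the *analysis* recovers the
*modelled* effects at desk scale, not that the model exhausts real data.

## Duplicate classification

Two records are duplicates iff they agree on chromosomes and strands and
both end coordinates differ by ≤ `wobble` bp (default 4 bp, the standard
setting; wobble is applied per end). Clusters are the transitive closure of
this relation (single linkage), which makes the result independent of input
order; the retained representative is the lexicographically smallest
`(pos1, pos2, read_id)`. A non-representative is an *optical* duplicate iff
it shares lane and tile with the representative within 100 px Euclidean
distance (the common HiSeq default), else a *PCR* duplicate. In SAFE mode
(`apply_dedup(safe_mode = TRUE)`) duplicates are retained as independent
ligations and only optical duplicates are dropped.

## Library complexity

`estimate_complexity()` inverts the equal-abundance (Lander–Waterman)
saturation `E[unique] = C(1 − e^{−total/C})` by bracketed bisection with a
geometrically expanded upper bracket (relative tolerance 1e−6). When
`unique == total` no finite solution exists and `Inf` is returned flagged.
Amplified libraries violate equal abundance; the resulting *downward* bias
of `Ĉ` is exactly the quality signal being measured and is deliberately not
corrected. Optical duplicates are excluded from both counts.

## Contact-map analyses

**KR balancing.** `kr_balance()` finds weights making all unmasked row sums
of `diag(w)·M·diag(w)` equal 1 within 1e−6, using the Knight–Ruiz
inner–outer Newton iteration (conjugate-gradient inner solves), with a
symmetric Sinkhorn fallback if it stagnates and a largest-component retry
for reducible support. All-zero rows are masked first.

**Decay curves.** Separations are histogrammed in log-spaced bins and each
bin is divided by the *genomic measure of locus pairs* at that separation
(`∫(L−s)ds` per segment — the diagonal-length normalization that makes the
`s^α` comparison meaningful), then normalized to sum 1.
`fit_decay_exponent()` is a pair-count-weighted least-squares slope in
log–log space; `decay_ratio()` is the per-bin quotient against a reference
on identical edges. Curves are computed on raw deduplicated pairs by
default; separation is taken directly from the fragment-end positions.

**SCC.** The stratum-adjusted correlation of two maps: a mean filter of
half-width `h` (default 1 bin), Pearson `r_k` per distance stratum, combined
with weights `N_k · sd_a,k · sd_b,k`. Zero-variance strata are skipped.

**GC representation.** Per-2-percentage-point GC-bin frequency ratio of two
libraries plus a Mann–Whitney U test on the per-pair GC values (exact null
distribution when both n ≤ 20 without ties; otherwise normal approximation
with tie and continuity corrections).

## TAD borders

The border-strength index at boundary `b` with block size `k = 8` sums
within-block contacts upstream (`A`) and downstream (`A′`), excluding
diagonal self-contacts, and cross-block contacts (`B`), reporting
`(A + A′)/B` on the balanced map. On a uniform map this is
`2·C(k,2)/k² = 0.875` exactly — the closed form the tests pin down. Border
*calling* takes local maxima filtered by a topographic-prominence floor
(default `0.1·(q90 − median)`, scale-free so flat tracks yield nothing) and
enforces ≥ 10 bins between accepted peaks (higher peak wins; ties to higher
prominence, then smaller index). TAD sets are the intervals between
successive borders; two TAD sets are compared by 90% *reciprocal* overlap
with greedy one-to-one matching. `aggregate_border_ratio()` stacks the
`2f × 2f` window around each border and applies the same `A/A′/B` geometry
to the stack; distance-dependent amplification bias inflates `B` (the
longest-range block) and therefore *lowers* the ratio — the directional
signature the acceptance tests assert.

## Compartments and APA

Compartments: observed/expected transform (each entry over its distance-
stratum mean), Pearson correlation matrix of the result, eigenvector of the
largest-magnitude eigenvalue. The global sign is arbitrary; it is oriented
by positive correlation with a GC track when available, else by the first
A-labelled ground-truth bin, else first-nonzero-positive. Computation is
per-chromosome; an error is raised when more than half the bins are
degenerate.

APA stacks the `(2w+1)²` raw-count window (defaults `w = 10`, corner
`c = 6`) centered on each loop pixel, with rows following the upstream
anchor so the lower-left corner is the *short-distance* corner.
`P2LL` = center over corner mean; `ZscoreLL` = center's Z-score against the
corner using the population SD (the corner is the full reference
population); a zero-variance corner yields a masked, not zero, Z-score.
Windows crossing the diagonal or the matrix edge are skipped. One caveat the
package surfaces deliberately: for loops close to the diagonal the corner
sits at a much shorter genomic distance, where the power-law background
inflates the reference and deflates P2LL; analyses here therefore raise
`min_separation` (e.g. 80–120 bins) when measuring absolute enrichment.

## Numerical and design choices

* Coordinates: `.pairs` positions are 1-based; bins and BED are 0-based
  half-open; bin index = `floor((pos−1)/resolution)`; chromosome order is
  the header's order of first appearance.
* Balancing tolerance 1e−6 on row sums; bisection tolerance 1e−6 relative;
  eigen-residual asserted < 1e−8 in tests.
* Desk-scale depths in scripts and tests (10⁵–6×10⁵ pairs on 2–20 Mb
  chromosomes) are chosen so each statistic has the coverage it needs while
  the whole suite runs in about a minute; the depth-hungry analyses
  (compartments, APA) use the deeper end and coarser bins (25 kb
  compartments instead of the 10 kb feasible at ~10⁸ reads).
* In the head-to-head border comparison, the aggregate ratio of both
  libraries is evaluated at the *same* (reference-called) border set, so the
  contrast measures map degradation rather than border-calling differences.

## A worked run

```{r}
library(hicamp)

cfg0  <- sim_config(n_true_ligations = 1.2e5, n_sequenced = 7e4,
                    pcr_cycles = 0,  seed = 1)
cfg12 <- sim_config(n_true_ligations = 1.2e5, n_sequenced = 7e4,
                    pcr_cycles = 12, seed = 1)

genome    <- simulate_genome(cfg0, list(list("chr1", 4e6)))
ligations <- simulate_true_ligations(genome, cfg0)
safe      <- sequence_library(amplify(ligations, cfg0),  cfg0)
amplified <- sequence_library(amplify(ligations, cfg12), cfg12)

report <- run_report(list(safe_pairs = safe, amp_pairs = amplified,
                          loops = loops_to_bedpe(genome),
                          resolution = 25000))
report$amplified$dup$pct_pcr_dup     # higher than the SAFE library
report$amplified$complexity$c_hat    # lower than the SAFE library
report$decay$crossing_bp             # ratio crosses 1 a few kb out
report$domains                       # lower aggregate (A+A')/B when amplified
```

The numbered scripts under `analysis/` run this narrative end to end and
write their tables under `results/`.

## Known limitations

Per-loop P2LL is Poisson-noisy at desk coverage (corner means near zero);
the aggregate statistic is the stable one. The border index needs TADs of at
least the block size (8 bins); at 25 kb this means ≥ 200 kb domains, so
fly-scale TADs should be analysed at 5–10 kb resolution instead. Complexity
estimation assumes sampling with replacement from the sequencer's cluster
pool; when `n_sequenced` approaches the true molecule count the SAFE
library's own collision duplicates depress `Ĉ` slightly below the true
molecule count, which mirrors real deep sequencing of a finite library.
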