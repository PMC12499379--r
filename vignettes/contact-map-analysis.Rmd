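---
title: "Multiscale contact-map analysis with chromascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale contact-map analysis with chromascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromascope)
```

# Scope and model

Chromosome-conformation (Hi-C) contact maps organize hierarchically: loops
at the tens-of-kilobase scale, topologically associating domains (TADs) at
hundreds of kilobases to a megabase, and A/B compartments at megabase
scale. `chromascope` implements the quantitative layer of that analysis —
normalization, insulation and boundary calling, compartment assignment and
an order parameter for compartmentalization, loop nesting statistics, and
an in silico perturbation screen over accessibility (ATAC-seq) and CTCF
binding tracks — together with a synthetic map generator that plants all
three structures so every claim the package makes can be tested against a
known truth.

Two matrix containers carry the analysis. A `contact_matrix` holds
symmetric non-negative counts or balanced intensities with a per-bin
validity mask; masked bins are `NA` throughout, never silent zeros. A
`log_fold_matrix` holds the same geometry in natural-log fold over a
per-distance expected vector (the distance-decay background), the
representation in which compartment structure is additive and loop bumps
are localized.

## Normalization

`ice_balance()` removes multiplicative per-bin coverage bias by iterative
row/column rescaling until the coefficient of variation of the valid row
sums falls below `tol` (default `1e-5`, at most 200 iterations — the
customary defaults for iterative correction). The accumulated bias vector
is kept so the factorization `raw = bias_i * bias_j * balanced` is
recoverable. `filter_low_coverage_bins()` masks bins with fewer than 10
nonzero row entries, the conventional low-coverage cut.
`expected_by_distance()` averages valid pairs per separation, and
`log_fold_oe()` divides by that background (configurable pseudocount,
default 0 — balanced intensities need none).

## Insulation: two scores on purpose

Two distinct insulation notions coexist because they answer different
questions:

* `diamond_insulation()` is the classic sliding-diamond score (log2 of
  the diamond mean over the track mean). Its minima locate boundaries;
  `tad_boundaries()` calls them through the delta-vector construction (3
  bins up/downstream by default), keeping minima where the delta crosses
  zero downward with strength — the delta range across the minimum — of
  at least `min_strength` (0.1 log2 units). The convention is a 25-kb map
  with a 1-Mb window. Boundary calling is best done on count-scale
  (distance-decayed) maps, where near-diagonal pairs dominate the diamond
  and boundary dips stay sharp; on a pure log-fold map, long-range
  compartment texture competes with the boundary signal.
* `insulation_profile()` measures boundary *strength* as the ratio
  `INSUL = (L + R + Const) / (M + Const)`, where `L` and `R` are the mean
  intensities of the two flanking squares, `M` the crossing block, and
  `Const` the average intensity of the map. A uniform map scores 1.5
  everywhere; a perfect two-block boundary scores 3. `Const` is taken as
  the mean over unmasked *nonzero* entries: in sparse maps zeros encode
  unobserved pairs, and including them would deflate the stabilizer —
  under that reading both closed forms above hold exactly, and on dense
  positive maps the definition coincides with the plain mean. The ratio
  is invariant under global rescaling of the map.

`differential_insulation()` compares profiles before and after a
perturbation: the peak is the extremum of the difference near the
perturbed locus, and the impact width counts the contiguous bins sharing
the peak's sign, peak inclusive, summing both arms (the per-arm counts
are also reported, since "maximum extent in both directions" admits
either reading). Identical profiles return a null-peak record rather
than an error.

## Compartments

`compartment_labels()` treats the map as a weighted graph adjacency,
eigendecomposes the symmetric normalized Laplacian, bipartitions with
k-means on the Fiedler vector (the standard spectral 2-cut), and then
fits a linear discriminant on the embedding of the `n_eig = 50`
smallest-eigenvalue eigenvectors with those cluster labels; the LD1 axis,
centered between the group means, is the signed per-bin score (A
positive, B negative). K-means directly in the 50-dimensional embedding
is unreliable for a 2-way cut — the separating direction is one axis
among many equally-scaled ones — which is why the partition comes from
the Fiedler vector and the embedding only shapes the score. When the
clusters are perfectly separated the within-group variance of the
separating eigenvector vanishes and the discriminant fit degenerates; the
centered Fiedler axis is then already the exact discriminant and is used
directly. Orientation is fixed by a caller-supplied reference (higher
mean accessibility or CpG density in A); without one the sign is
arbitrary and flagged.

`comp_score()` quantifies compartmentalization: quadrant means `AA`,
`AB`, `BA`, `BB` over off-diagonal unmasked pairs, `COMP = (AA + BB) /
(AB + BA)`, rescaled to `(COMP - 1)/(COMP + 1)` in `[-1, 1]`. Log-fold
input is exponentiated first, so the quadrant averages are mean fold
enrichments — averaging in log space would change the meaning of the
ratio (and is biased by the Jensen gap). The diagonal is excluded; the
`AB + BA = 0 < AA + BB` case takes the defined limit +1.

## Loops

A loop is a sub-loop of another when its anchors lie within the other's
(ties on one anchor allowed, identical coordinate pairs excluded — two
identical loops would otherwise each nest in the other, so duplicates
are removed first with a warning). `loop_hierarchy()` marks main-loops
(not nested in anything), assigns each remaining loop its smallest
enclosing parent, and reports per-main valency as the count of all loops
nested at any depth, read literally from the definition rather than as
direct children only; on non-laminar interval sets the two counts can
differ and the direct-nesting count is the one used.
`mean_size_per_valency` in `loop_stats()` is the ratio of means
(mean main size over mean valency, valency-0 mains included) — a
per-loop mean of size/valency would be undefined at valency 0.

`naive_loop_caller()` is deliberately simple plumbing for synthetic and
surrogate maps, standing in for the heavyweight learned callers used on
experimental data: strict local maxima of the log-fold map, scored
against a surrounding ring background by a one-sided Poisson tail test
at a nominal depth, with two guards — a minimum center enrichment
(`min_lf = 0.5`) so pixels adjacent to depleted boundaries are not
mistaken for loops, and optional anchor collapsing (coordinates within
one bin merge onto the best-scoring call) because the apex of a bump
sitting on a sloped background can shift by a pixel, which would break
exact anchor sharing in the hierarchy.

## Fragment annotation

`categorize_fragments()` tiles the span into 1-kb fragments and labels
each by overlap with fixed precedence promoter > enhancer > gene body >
other (the precedence is a package convention; overlaps are any-bp,
half-open arithmetic via `GenomicRanges`). Promoters are strand-aware
windows from 5 kb upstream to 500 bp downstream of the TSS. CGI
forest/prairie domains and CpG-content classes are consumed as input
annotation — their derivation belongs to upstream work —, and
`relative_enrichment()` reports per-class selected fractions.

## The perturbation engine and its surrogate predictor

Perturbation operators edit tracks or sequence: `silence_region()`
(zero a window), `activate_enhancers()` (pointwise max against a donor,
or a fold factor such as the 1.1-fold global enhancer activation),
`add_ctcf_peak()` (a Gaussian of apex 1000 spanning the motif extended
by 30 bp per side, max-combined with the original), `global_scale()`,
and `permute_sequence()` (16-bp segments shuffled under a seed, trailing
remainder fixed).

`surrogate_predict()` fills the predictor contract — window in, log-fold
matrix out, bit-deterministic — with a mechanistic composition rather
than a learned model:

* compartment field `kappa_comp * s_i * s_j`, `s` the z-score of the
  100-kb-smoothed binned ATAC signal bounded at `z_max = 1.2` (the bound
  keeps the field subordinate to loop bumps at anchor pixels; windows
  smaller than the smoothing scale carry no compartment field, which is
  the physically sensible limit);
* Gaussian loop bumps (`sigma_loop = 2` bins, amplitude `kappa_loop =
  1.5` gated by anchor accessibility) at pairs of anchors — CTCF peaks
  above `theta_c = 2` that also carry an ATAC peak above `theta_a = 4`
  at bin maximum — separated by at least 12 bins and at most 1 Mb with
  no strong boundary between them, loop extrusion being blocked at
  strong CTCF sites;
* an insulation penalty `kappa_ins = 0.3` per unit of crossed boundary
  weight (each CTCF peak contributes its strength above threshold,
  capped), saturating at `cap = 3` and decaying with distance over
  `d_ins = 2` Mb, so boundary effects stay extrusion-scale while
  long-range structure remains compartmental.

Bin-level ATAC statistics are split deliberately: the *mean* feeds the
compartment field, the *maximum* qualifies anchors. A 1-kb silencing
thus removes an anchor peak outright while barely moving the smoothed
compartment field — exactly the locality the screening workflow needs.
Because the surrogate only reads track values inside the requested
window, a perturbation outside the window has identically zero impact.

`impact_score()` is the mean absolute difference between predictions;
`screen_fragments()` runs the silencing screen per 1-kb fragment and
scale (each window is the scale-sized square centered on the fragment,
clipped at the span ends), and marks the HIS subset — the top decile by
impact, ties broken by impact then coordinate so membership is
deterministic.

## Synthetic ground truth

`make_truth()` draws a reproducible planted structure from `(config,
seed)`: alternating A/B blocks with jittered edges, jittered TAD
boundaries, and nested loop chains that share their lower anchor with
uppers stepping inward by `min_anchor_gap = 5` bins. The shared-anchor
chain is chosen so that the set of admissible anchor pairings in the
surrogate equals the planted loop set exactly, which is what makes exact
main-loop-count recovery a fair test; main spans are capped at 900 kb to
stay within the surrogate's extrusion reach. `render_logfold()`
composes checkerboard, TAD elevation and loop bumps on a zero baseline —
the distance decay lives in the expected vector, not the log-fold layer,
mirroring the representation the analyses consume. `sample_counts()`
wraps the rendered surface in `Poisson(depth * d^-gamma * exp(lf))`
noise (exponent 1 by default, the typical intra-chromosomal decay), or
returns the exact means with `noise = FALSE`. `make_tracks()` emits
1-kb-step ATAC and CTCF tracks consistent with the truth: an open-A
plateau (2.5 vs 0.5 in -log10 p units), single-step ATAC peaks of 6 at
anchors, CTCF peaks of 6 at boundaries and 2.5 at anchors — strong
boundaries, weak anchor insulation, in line with the graded boundary
weighting above.

What the generator does *not* emulate: experimental coverage bias beyond
the multiplicative kind, structural variation, trans contacts,
resolution-dependent blur, or realistic sequence (sequence fixtures are
uniform random). Tests passing on these maps certify the analytic
machinery — the estimators, the screening logic, the recovery of planted
structure under Poisson noise — not performance on tissue Hi-C.

## Numerical choices and degenerate inputs

All-zero maps raise degenerate-input errors in balancing, insulation and
compartment calling rather than returning sentinels. `comp_score` with
one label present, or with every quadrant empty, errors; the two
zero-denominator limits return the defined values of the rescaled order
parameter. Diamond scores at window edges are `NA`, never computed on
shrunken windows. Pooling a size not divisible by the factor averages
the trailing partial block over its actual members. HIS ties and k-means
seeding are fixed so every pipeline stage is reproducible bit-for-bit
under a seed.

## Problem sizes

The validation suite runs on maps of 100–200 bins (2.5–5 Mb at 25 kb),
screens of 50–100 one-kb fragments at 48–64-kb scales, and 10–20 seeds
per stochastic claim — sizes where the brute-force oracles (explicit
block means, all-pairs nesting scans, exhaustive rank statistics) remain
exact and fast, chosen as the package's own validation scale.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config()
truth <- make_truth(cfg, seed = 1)
tracks <- make_tracks(truth)
lf <- surrogate_predict(tracks, c(0, cfg$n_bins * cfg$resolution),
                        cfg$resolution)

# boundaries from the count-scale map
cm <- sample_counts(lf, depth = 100, noise = FALSE)
tad_boundaries(cm, window = 1e6)$positions

# compartments and order parameter
labels <- compartment_labels(lf)
comp_score(lf, labels)

# loop hierarchy from called loops
loop_hierarchy(naive_loop_caller(lf))
```

## Known limitations

The spectral 2-cut assumes two dominant compartment states;
sub-compartments are out of scope, as are trans contacts and cool/HDF5
containers. The naive loop caller is not a substitute for learned
callers on experimental maps. The surrogate predictor encodes plausible
mechanics, not a trained model; its role is to make the perturbation
workflows exercisable and falsifiable, and its parameters are plain
configuration for plugging in real predictions via the same contract.
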