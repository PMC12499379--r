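# chromascope

Multiscale analysis of chromosome-conformation (Hi-C) contact maps, and
in silico perturbation screening of the chromatin tracks that shape them.

Genome folding is hierarchical: chromatin loops (tens of kb) sit inside
topologically associating domains (TADs, ~0.1–1 Mb), which sit inside A/B
compartments (Mb scale). `chromascope` is for computational genomicists
who want the quantitative layer of that analysis as tested, scriptable
R functions:

* **Matrix handling** — sparse-triplet / dense text IO, iterative
  correction (ICE) balancing, low-coverage bin masking, 2-D average
  pooling, distance-decay expected, and log fold over background (O/E).
* **Insulation and TADs** — the sliding-diamond insulation track with
  delta-vector boundary calling (25-kb maps, 1-Mb window by
  convention), and the insulation ratio
  `INSUL = (L + R + Const) / (M + Const)` measuring boundary strength
  (1.5 on a uniform map, 3 at a perfect two-block boundary).
* **Compartments** — spectral clustering of the contact graph
  (normalized Laplacian, Fiedler 2-cut) with a linear-discriminant
  signed score over the top-50 eigenvector embedding, plus the
  compartmentalization order parameter
  `COMP = (AA + BB) / (AB + BA)` and its rescaling
  `(COMP − 1)/(COMP + 1) ∈ [−1, 1]` (+1: contacts only within
  compartments; −1: only across).
* **Loops** — anchor-interval nesting (a loop is a sub-loop of another
  when both its anchors lie within the other's span) grouping loops
  into main-loops and sub-loops, per-main valency (all nested loops,
  any depth), category calls (P–P / E–P / E–E) from anchor annotation,
  summary statistics (counts per Mb, mean main size per unit valency),
  and a naive ring-background enrichment caller for synthetic maps.
* **Perturbation screening** — silence / activate / scale track
  operators, Gaussian CTCF peak insertion, seeded 16-bp sequence
  permutation; a deterministic mechanistic surrogate predictor
  (tracks in, log-fold map out) standing in for a trained model behind
  the same contract; mean-absolute-difference impact scores; and a
  genome-fragment screen that marks the top-decile HIS subset per
  scale.
* **Synthetic ground truth** — a generator planting compartment
  checkerboards, TAD blocks and nested loop bumps with Poisson count
  noise, so every analysis above is testable against a known answer.
* **Evaluation metrics** — map Pearson correlation, distance-stratified
  correlation, and tie-aware AUROC.

## Worked example

Generate a planted 5-Mb chromosome (200 bins at 25 kb: 6 compartment
blocks, 4 TADs, 3 main-loops of valency 2), predict its map from the
consistent ATAC/CTCF tracks with the surrogate, and run the analyses:

```r
library(chromascope)

cfg    <- sim_config()
truth  <- make_truth(cfg, seed = 1)
tracks <- make_tracks(truth)
lf     <- surrogate_predict(tracks, c(0, cfg$n_bins * cfg$resolution),
                            cfg$resolution)

# TAD boundaries from the count-scale map
cm <- sample_counts(lf, depth = 100, noise = FALSE)
tad_boundaries(cm, window = 1e6)$positions
#> [1]  52  64 100 129 149     (planted: 52 100 149)

# compartments and the order parameter
labels <- compartment_labels(lf)
labels
#> <compartment_assignment> 200 bins: 92 A, 108 B, 0 masked (arbitrary sign)
comp_score(lf, labels)
#> <comp_score> AA=1.265 AB=0.5677 BA=0.5677 BB=1.109 COMP=2.091 rescaled=0.353

# loop hierarchy from called loops
loop_hierarchy(naive_loop_caller(lf))
#> <loop_hierarchy> 7 loops, 3 main-loops, valencies: 0,2,2
```

All three planted boundaries are recovered exactly (the two extra calls
sit at the planted anchor clusters, which genuinely insulate);
compartment labels match the planted truth at 99% up to sign, and
`COMP_rescaled = 0.353` says intra-compartment contacts run about twice
the inter-compartment level. The three planted main-loops are recovered;
one lost its two sub-loop calls to window clipping at the map edge.

A thin command-line interface wraps the same functions
(`inst/cli/chromascope`): `simulate`, `balance`, `pool`, `oe`,
`insulation`, `tads`, `compartments`, `comp-score`, `loops`,
`fragments`, `screen`. A small simulated dataset ships under
`inst/extdata/synthetic_example/`.

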