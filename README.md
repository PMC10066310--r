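# divprof

Similarity-scaled diversity profiles for T-cell receptor (TCR) repertoires.

## The problem

Immune monitoring compares "snapshots" of a TCR repertoire — a table of
CDR3β amino-acid sequences with clone counts — across treatments or
timepoints. Single diversity indices (richness, Shannon, Simpson,
Berger–Parker) weight large clones differently and can reorder the same
repertoires depending on which index is picked, and none of them see that
T cells responding to the same antigen tend to carry *similar* sequences.
`divprof` computes a two-parameter family of effective clone numbers that
covers both axes at once:

$$D(q,\lambda) \;=\; \Big(\sum_{i=1}^{S} p_i\,(Zp)_i^{\,q-1}\Big)^{1/(1-q)},
\qquad (Zp)_i = \sum_{j} e^{-\lambda d_{ij}}\,p_j ,$$

where `p_i` are clone frequencies and `d_ij` pairwise sequence distances
(normalised BLOSUM45 global-alignment score by default, mean-Atchley-factor
Euclidean distance as an alternative). The Hill order `q` scans clone-size
sensitivity (`q = 0` richness, `1` exp-Shannon, `2` inverse Simpson, `∞`
Berger–Parker); the kernel scale `λ` scans similarity sensitivity, from
`λ = 0` (all clones merged, `D = 1`) to the identity kernel (naive Hill
diversity). The surface `ln D(q, λ)` — the *diversity profile* — is then
reduced to scalar features (areas between λ-curves, mean small-λ spacing,
q-slopes) for ordination, clustering and classification of whole cohorts.
The small-λ spacing estimates the frequency-weighted mean pairwise distance
`Σ p_i p_j d_ij`; the naive slope at `q = 1` is `−Var_p(ln p)/2`, the
clone-size log-variance.

It is aimed at immunologists and bioinformaticians analysing bulk TCR-seq
clone tables (one TSV per sample: `sequence`, `count` or `frequency`).

## Worked example

Generate a small synthetic cohort (two classes differing in motif
tightness) and run one sample end to end:

```r
library(divprof)

dir <- tempfile(); dir.create(dir)
specs <- list(tight = mock_spec(S = 120, size_law = "powerlaw", exponent = 1,
                                n_motifs = 2, mutations_per_step = 1),
              loose = mock_spec(S = 120, size_law = "powerlaw", exponent = 1,
                                n_motifs = 2, mutations_per_step = 5))
man <- make_sequence_cohort(specs, n_per_class = 3, dir, seed = 42)

res <- run_sample(run_config(file.path(dir, man$path[1]),
                             file.path(dir, "out1"),
                             depth = 5000, metric = "blosum45", seed = 1))
res$repertoire
#> <tcr_repertoire> tight_01: 114 unique clones, subsampled to depth 5000 (seed 1)
#>   top clone frequency 0.1896

round(res$grid$log_values[c("0", "2", "inf"), c("0", "0.5", "16", "identity")], 3)
#>     0   0.5    16 identity
#> 0   0 0.363 4.163    4.736
#> 2   0 0.358 2.519    2.855
#> inf 0 0.285 1.465    1.663
```

Each cell is `ln D(q, λ)`. Reading it: the naive (`identity`) richness is
`exp(4.736) ≈ 114` clones, but the effective number drops to `exp(2.855) ≈ 17`
at `q = 2` (a few clones dominate) and the `λ = 16` column sits well below
the naive one (many clones are similar, so mild similarity clustering
already removes diversity). The `λ = 0` column is identically 0: one
effective clone.

```r
mean_small_lambda_spacing(res$grid)          # 0.0713  ~ mean pairwise distance / 10
area_between_lambda_curves(res$grid, 16, Inf) # 1.956   naive-vs-16 similarity drop
q_slope(res$grid, Inf, 0, 1)                 # -0.96    clonal expansion signal
```

`run_cohort()` then assembles per-sample feature rows into PCA scores,
a complete-linkage tree and partitioned leave-one-out SVM / random-forest
accuracies; `randomize_clone_sizes()` provides the clone-size
randomisation null. A thin command-line wrapper over the same functions is
installed at `inst/cli/divprof.R` (subcommands `sample`, `cohort`,
`synth`).

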