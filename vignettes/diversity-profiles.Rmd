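---
title: "Similarity-scaled diversity profiles for TCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-scaled diversity profiles for TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divprof)
```

## The model

A T-cell receptor repertoire, reduced to its CDR3β amino-acid sequences, is
summarised here as $S$ unique clones with frequencies $p_i$ summing to 1.
Single diversity indices (richness, Shannon, Simpson, Berger–Parker) weight
large clones differently and can *reorder* repertoires depending on which
index is chosen; all of them are special cases of the Hill number of order
$q$,

$$D(q) = \Big(\sum_{i=1}^{S} p_i^q\Big)^{1/(1-q)},$$

with the limits $D(1) = \exp(-\sum_i p_i \ln p_i)$ and
$D(\infty) = 1/\max_i p_i$. The order $q$ moves the focus from counting
every clone ($q = 0$) to seeing only the largest ($q \to \infty$).

Hill numbers are blind to sequence similarity, yet clones responding to the
same antigen tend to be similar in sequence. Following the
similarity-sensitive effective-number framework of Leinster and Cobbold, the
package scales a pairwise distance matrix $d_{ij}$ into a similarity kernel
$Z_{ij} = e^{-\lambda d_{ij}}$ and replaces each clone's own frequency by
its kernel-weighted effective abundance $(Zp)_i = \sum_j Z_{ij}\,p_j$:

$$D(q,\lambda) = \Big(\sum_{i=1}^{S} p_i\, (Zp)_i^{\,q-1}\Big)^{1/(1-q)}.$$

$\lambda$ is a second focus knob, for similarity instead of clone size.
At $\lambda = 0$ every clone is within reach of every other, $(Zp)_i = 1$
and $D = 1$: one effective clone. As $\lambda \to \infty$ the kernel
approaches the identity and $D(q,\lambda)$ approaches the naive Hill
number; the package represents that end of the axis by an explicit
*identity* column computed exactly from $D(q)$, never from $e^{-\lambda d}$
at a large finite $\lambda$. The surface $\ln D(q,\lambda)$ over a grid of
$(q, \lambda)$ is the *diversity profile* of the repertoire.

The $q = 1$ and $q = \infty$ cases of the similarity-scaled formula are not
fixed by the display above; the package adopts the continuous limits
$\exp(-\sum_i p_i \ln (Zp)_i)$ and $1/\max_i (Zp)_i$ and verifies
numerically (in the test suite) that the general formula approaches them
from both sides in $q$.

## Pipeline and parameters

A per-sample run (`run_sample()`) is: read the clone table, keep in-frame
sequences, subsample, compute the distance matrix in chunks, evaluate the
grid, extract features.

* **In-frame filter.** Input is amino-acid text, so "in frame" is
  operationalised as: non-empty and matching
  `^[ACDEFGHIKLMNPQRSTVWY]+$`. `*` (stop) and `X` (ambiguous) are dropped.
* **Subsampling** (`subsample_repertoire()`, default depth 50000 draws).
  Sampling is multinomial *with replacement* from the normalised abundance
  distribution — the only definition that works when the input column is
  already frequencies — after merging duplicate sequences. It equalises
  sequencing depth across samples and bounds the quadratic distance stage.
  The seed is a required argument and is recorded in the run manifest,
  because this is the pipeline's only stochastic stage.
* **Distances.** Two metrics. The default aligns a pair globally
  (Needleman–Wunsch) under BLOSUM45 with a *linear* gap cost of 10 per gap
  position — gap opening priced the same as extension, the minimal reading
  of a single "gap penalty" parameter, documented so scores are
  reproducible bit-exactly — and normalises
  $d = 1 - s_{ab} / \max(s_{aa}, s_{bb})$, floored at 0. The alternative
  embeds each peptide as the mean of its residues' five Atchley
  physicochemical factors (published values, not re-standardised) and takes
  Euclidean distance; it is faster, coarser, and not injective.
  Note the normalised alignment distance can exceed 2 for peptides of very
  different lengths with weak self-scores (gap costs dominate); within
  CDR3-like length ranges it stays in $[0, 2]$.
* **Chunking** (`compute_distance_chunks()`, default 100 rows). Each chunk
  holds full rows of the $S \times S$ matrix, so chunks are independent
  work units (each pair is computed twice across a run — the price of
  embarrassing parallelism); concatenated they give the full matrix with a
  zero diagonal. Chunk files carry a manifest with the sequence-list
  checksum, so a run can resume from completed chunks and a grid can never
  be computed against chunks from a different repertoire. The checksum
  deliberately covers sequences only, not frequencies: the clone-size
  randomisation control replaces frequencies while reusing the matrix.
* **Grid** (`parameter_grid()`). Defaults: $q \in \{0,1,2,3,4,5,6,\infty\}$
  and $\lambda \in \{0, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.75, 1, 1.5, 2, 4,
  8, 16, 32, 64\}$ plus the identity column — a 0.1-spaced ramp below 1 to
  resolve the small-$\lambda$ regime and a doubling sequence above 1 for
  the large-$\lambda$ regime.

### Numerical choices

Sums of the form $\sum_i p_i (Zp)_i^{q-1}$ underflow at $q = 6$ when
$(Zp)_i$ is tiny, so all accumulation runs in log space through a
log-sum-exp contract; the test suite pins the chunked, log-space grid
against a dense direct evaluation to $10^{-9}$ on $\ln D$. The
$\lambda = 0$ column is set to $\ln D = 0$ exactly, and the identity column
is evaluated from the naive formula. TSV artifacts serialize numbers with
17 significant digits so that reruns and chunk resumption are
byte-identical; grid values are bit-identical across worker counts, while
different chunk sizes can differ by a few ulps through BLAS summation
order (asserted at $10^{-12}$). Sentinels are serialized as the literal
tokens `inf` (for $q$) and `identity` (for $\lambda$).

## Profile features

`extract_features()` reduces a profile to 68 scalars:

* **Areas between adjacent λ curves** — trapezoidal integrals over the
  finite $q$ axis $\{0,\dots,6\}$ of
  $\ln D(q,\lambda_{k+1}) - \ln D(q,\lambda_k)$, non-negative by the
  monotonicity of $\ln D$ in $\lambda$. Only adjacent pairs are stored:
  any other pair (the identity-to-16 area, for instance) is recoverable
  exactly by additivity, so the adjacent set is a non-redundant basis.
  $q = \infty$ is excluded from the abscissa — a trapezoid needs a finite
  axis.
* **Mean small-λ spacing** — the average increment of $\ln D$ across
  $\lambda \in \{0, 0.1, 0.2, 0.3, 0.4, 0.5\}$ (0.25 and 0.75 are excluded
  so the set is evenly spaced; increments are deliberately *not* divided by
  $\Delta\lambda$). A perturbation expansion around $\lambda = 0$ gives
  $\ln D(q,\lambda) \approx \lambda \bar d$ with
  $\bar d = \sum_{ij} p_i p_j d_{ij}$, independent of $q$ at first order
  for finite $q$ (the $q=\infty$ limit instead tracks
  $\min_i \sum_j d_{ij} p_j$, and for heterogeneous distance matrices the
  radius of the expansion is set by the weighted second moment
  $\sum_{ij} p_i p_j d_{ij}^2$, not by $\bar d$). The spacing therefore
  reads out the frequency-weighted mean sequence distance of the
  repertoire.
* **q-slopes** — finite differences $\ln D(q_b) - \ln D(q_a)$ for
  $(0\!\to\!1), (1\!\to\!2), (0\!\to\!2)$ at every $\lambda$ including
  identity. Finite differences, not analytic derivatives, are the stored
  feature; the analytic naive slope at $q = 1$,
  $-\tfrac12 \mathrm{Var}_p(\ln p)$, is kept as a property test — its
  magnitude is the clone-size (log-)variance, which is what the slope is
  read as biologically.

## Cohort analysis

`assemble_cohort()` aligns per-sample feature rows with a label table;
`run_pca()` performs mean-centred PCA (features are already on the ln
scale, so columns are not variance-scaled by default — a `scale.` flag
exists); `hierarchical_cluster()` is complete-linkage on Euclidean feature
distances; `partitioned_cv_classify()` trains a linear-kernel SVM (kernel
unstated upstream; linear follows the cited precedent and adds no
hyperparameters) or a random forest on $K-1$ of $K$ stratified partitions
and predicts the held-out one, concatenating all predictions for the
overall accuracy. Partitions are dealt round-robin within each label
combination, so an 8-sample group splits 3/3/2 over three partitions.
`randomize_clone_sizes()` is the null control: frequencies are replaced by
normalised uniform pseudo-random draws while the sequence list — and hence
the distance chunks — stay fixed.

## What the synthetic generators emulate

* `make_uniform_mock(S, d0)` — $S$ equally frequent clones at constant
  pairwise distance $d_0$, with the dense matrix supplied directly. This
  makes closed forms exact (every Hill number equals $S$;
  $\bar d = d_0(1 - 1/S)$) and reproduces the textbook mock experiment:
  as $d_0$ grows the small-λ spacing rises linearly while the
  identity-to-16 area falls — the two features are inverse in this
  simplified setting.
* `make_mock_repertoire()` / `make_sequence_cohort()` — CDR3-like peptides
  (length 8–18, leading cysteine preserved under mutation) generated by
  seeding a few motifs and expanding each by a random walk of point
  substitutions; no indels, so distances are controlled primarily by
  substitution count. Clone sizes follow a uniform, power-law
  ($p_i \propto i^{-a}$, the rank law that approximates real clone-size
  distributions) or symmetric-Dirichlet law. Class structure is encoded by
  giving classes different size laws (separates in naive q-slopes) or
  different motif tightness (separates in the small-λ spacing but not, up
  to collision noise, in naive diversity). Every generator is a pure
  function of its seed.
* `make_clustered_mock()` / `make_structured_cohort()` — one tight cluster
  of similar clones carrying a chosen fraction of the total frequency
  inside a uniform background: an idealised polyclonal expansion. The
  structured cohort is a fixed balanced design of 20 such samples whose
  cluster mass rises monotonically while cluster tightness and background
  spread follow rank-orthogonal permutations of their ranges. The design is
  deliberately deterministic: the coupling of clone size to similarity —
  and the fact that replacing clone sizes with pseudo-random numbers
  destroys the spacing-vs-area correlation while independent distance axes
  do not re-create it — is then a property of the construction, not of a
  lucky draw. The post-randomisation correlation is judged on the pooled
  randomised replicates (5 seeds × 20 samples); a single 20-sample Spearman
  coefficient has a null standard deviation of ~0.23, too wide to call
  "near zero" honestly.

What these mocks do **not** emulate: V(D)J generation probabilities,
indels, sequencing error, shared public clones between samples, and the
heavy cross-sample richness variation of real data. Passing tests
demonstrate the estimator and its features behave as the mathematics says
on controlled structures; they are not evidence about any biological
cohort.

## Problem sizes and runtime

The test suite and the acceptance script run on repertoires of 20–250
unique clones and cohorts of 20–30 samples; a full per-sample run at those
sizes takes seconds, and the whole suite about a minute on one core. The
quadratic distance stage dominates real-scale runs (a 50000-sequence
sample is an all-against-all of $2.5\times10^9$ pairs); chunking exists
precisely so that stage can be spread over workers and resumed.

## Known limitations

* Linear gap costs; affine gaps and local alignment are out of scope.
* No approximate nearest-neighbour shortcut at large $\lambda$; every
  evaluation is exact and all-against-all.
* No rarefaction or bootstrap intervals on $D(q,\lambda)$.
* The Atchley metric identifies any two peptides with equal mean factor
  vectors ("A" vs "AA"); distances of 0 between distinct clones are legal
  throughout and simply merge those clones at every $\lambda$.
* Classification on small cohorts is a sanity check, not a validated
  classifier; no feature selection or hyperparameter search is performed.
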