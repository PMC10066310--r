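# Seeded generators for repertoires with controlled clone-size
# distributions and controlled pairwise-distance structure, so that every
# pipeline stage can be exercised without external data.

#' Uniform mock repertoire with constant pairwise distance
#'
#' `S` equally frequent clones at a constant pairwise distance `d0` (zero
#' diagonal). The distance structure is specified directly -- the dense
#' matrix bypasses the sequence metrics -- which makes closed forms exact:
#' every Hill number of the uniform repertoire equals `S`, and the
#' frequency-weighted mean distance is `d0 * (1 - 1/S)`.
#'
#' @param S Number of clones (>= 2).
#' @param d0 Constant off-diagonal distance (>= 0).
#' @param sample_id Sample identifier.
#' @return List with elements `repertoire` (a [tcr_repertoire()] with
#'   placeholder sequence tokens) and `dmat` (the dense `S x S` matrix),
#'   ready for [as_distance_chunks()].
#' @export
make_uniform_mock <- function(S, d0, sample_id = "mock") {
  stopifnot(S >= 2, d0 >= 0)
  rep <- tcr_repertoire(sprintf("MOCK%05d", seq_len(S)), rep(1 / S, S),
                        sample_id = sample_id)
  dmat <- matrix(d0, S, S)
  diag(dmat) <- 0
  list(repertoire = rep, dmat = dmat)
}

#' Clustered mock repertoire
#'
#' `S` clones of which the first `m` form a tight cluster (pairwise distance
#' `d_intra`) carrying total frequency `cluster_mass` split evenly; all other
#' pairs sit at `d_inter`, and the remaining mass is split evenly over the
#' background clones. Emulates a polyclonal expansion of similar sequences:
#' coupling `cluster_mass` to the cluster is what ties clone size to sequence
#' similarity, the structure that the clone-size randomisation control
#' destroys.
#'
#' @param S Total clones; `m` in the cluster (`1 <= m < S`).
#' @param m Cluster size.
#' @param cluster_mass Total frequency on the cluster, in (0, 1).
#' @param d_intra,d_inter Within-cluster / background pairwise distances
#'   (`0 <= d_intra <= d_inter`).
#' @param sample_id Sample identifier.
#' @return List with `repertoire` and dense `dmat`, as
#'   [make_uniform_mock()].
#' @export
make_clustered_mock <- function(S = 60, m = 15, cluster_mass = 0.5,
                                d_intra = 0.05, d_inter = 0.7,
                                sample_id = "clustered") {
  stopifnot(S >= 3, m >= 1, m < S, cluster_mass > 0, cluster_mass < 1,
            d_intra >= 0, d_inter >= d_intra)
  freqs <- c(rep(cluster_mass / m, m), rep((1 - cluster_mass) / (S - m),
                                           S - m))
  rep <- tcr_repertoire(sprintf("CLUS%05d", seq_len(S)), freqs,
                        sample_id = sample_id)
  dmat <- matrix(d_inter, S, S)
  dmat[seq_len(m), seq_len(m)] <- d_intra
  diag(dmat) <- 0
  list(repertoire = rep, dmat = dmat)
}

#' Deterministic structured cohort of clustered mocks
#'
#' A balanced cohort of [make_clustered_mock()] repertoires emulating a
#' gradient of polyclonal expansion: the cluster mass rises linearly across
#' samples (the structured coupling of clone size to sequence similarity),
#' while cluster tightness and background spread follow fixed rank-orthogonal
#' permutations of their ranges -- nuisance variation uncorrelated with the
#' expansion gradient and with each other. The design is deterministic: the
#' structured coupling, and its destruction by [randomize_clone_sizes()], do
#' not depend on a seed.
#'
#' @param n_samples Number of samples (default 20; the built-in orthogonal
#'   design supports exactly 20).
#' @param S,m Clones per repertoire and cluster size.
#' @param mass_range Range of the cluster-mass gradient.
#' @param tightness_range Range of within-cluster distances.
#' @param spread_range Range of background pairwise distances.
#' @return List of `n_samples` elements, each as [make_clustered_mock()].
#' @export
make_structured_cohort <- function(n_samples = 20, S = 200, m = 50,
                                   mass_range = c(0.05, 0.95),
                                   tightness_range = c(0.02, 0.06),
                                   spread_range = c(0.62, 0.78)) {
  # fixed permutations of 1..20 with pairwise rank correlations < 0.01
  # (vs the sample index and vs each other)
  perm_t <- c(9, 15, 8, 2, 6, 19, 14, 17, 10, 3,
              16, 7, 18, 1, 13, 11, 12, 4, 20, 5)
  perm_g <- c(11, 12, 6, 9, 18, 4, 16, 8, 3, 20,
              7, 14, 10, 1, 17, 19, 2, 13, 15, 5)
  if (n_samples != 20) {
    stop("the balanced design is defined for exactly 20 samples",
         call. = FALSE)
  }
  fmass <- seq(mass_range[1], mass_range[2], length.out = n_samples)
  tk <- tightness_range[1] +
    (perm_t - 1) / (n_samples - 1) * diff(tightness_range)
  gk <- spread_range[1] +
    (perm_g - 1) / (n_samples - 1) * diff(spread_range)
  lapply(seq_len(n_samples), function(k) {
    make_clustered_mock(S, m, fmass[k], tk[k], gk[k],
                        sample_id = sprintf("structured_%02d", k))
  })
}

#' Power-law clone frequencies
#'
#' `p_i` proportional to `i^(-exponent)`, normalised; the rank-frequency law
#' most often used to describe real clone-size distributions. The exponent
#' tunes clonal dominance: 0 is uniform, larger exponents concentrate mass
#' in the first ranks.
#'
#' @param S Number of clones.
#' @param exponent Non-negative decay exponent.
#' @return Frequency vector of length `S` (deterministic).
#' @examples
#' powerlaw_frequencies(3, 1)  # c(6, 3, 2) / 11
#' @export
powerlaw_frequencies <- function(S, exponent) {
  stopifnot(S >= 1, exponent >= 0)
  w <- seq_len(S)^(-exponent)
  w / sum(w)
}

#' Dirichlet clone frequencies
#'
#' Symmetric-Dirichlet draw; small concentrations give ragged, heavy-tailed
#' clone sizes, large concentrations approach uniform.
#'
#' @param S Number of clones.
#' @param conc Concentration parameter (> 0).
#' @param seed Integer seed.
#' @return Frequency vector of length `S`.
#' @export
dirichlet_frequencies <- function(S, conc, seed) {
  stopifnot(S >= 1, conc > 0)
  g <- withr::with_seed(seed, stats::rgamma(S, shape = conc))
  g <- pmax(g, .Machine$double.xmin)
  g / sum(g)
}

#' Random CDR3-like peptide
#' @noRd
random_cdr3 <- function(len_range = c(8, 18)) {
  len <- sample(seq(len_range[1], len_range[2]), 1)
  paste0("C", paste(sample(AA_ALPHABET, len - 1, replace = TRUE),
                    collapse = ""))
}

#' Apply point substitutions to a peptide, preserving the leading cysteine
#' @noRd
mutate_peptide <- function(seq, n_mut) {
  chars <- strsplit(seq, "")[[1]]
  if (n_mut <= 0 || length(chars) < 2) return(seq)
  pos <- sample(seq_along(chars)[-1], min(n_mut, length(chars) - 1))
  chars[pos] <- sample(AA_ALPHABET, length(pos), replace = TRUE)
  paste(chars, collapse = "")
}

#' Specification of a synthetic sequence repertoire
#'
#' @param S Number of clones.
#' @param size_law `"uniform"`, `"powerlaw"` or `"dirichlet"`.
#' @param exponent Power-law exponent (`size_law = "powerlaw"`).
#' @param conc Dirichlet concentration (`size_law = "dirichlet"`).
#' @param n_motifs Number of seed motifs the clones expand from.
#' @param mutations_per_step Point substitutions per expansion step; controls
#'   motif tightness (0 collapses each motif to a single clone).
#' @param len_range Motif length range (CDR3-like, starting `C`).
#' @return A `mock_spec` list.
#' @export
mock_spec <- function(S = 100, size_law = c("uniform", "powerlaw",
                                            "dirichlet"),
                      exponent = 1, conc = 1, n_motifs = 3,
                      mutations_per_step = 1, len_range = c(8, 18)) {
  size_law <- match.arg(size_law)
  stopifnot(S >= 1, exponent >= 0, conc > 0, n_motifs >= 1,
            mutations_per_step >= 0)
  structure(list(S = S, size_law = size_law, exponent = exponent,
                 conc = conc, n_motifs = n_motifs,
                 mutations_per_step = mutations_per_step,
                 len_range = len_range),
            class = "mock_spec")
}

generate_mock_sequences <- function(spec) {
  motifs <- replicate(spec$n_motifs, random_cdr3(spec$len_range))
  current <- motifs
  assign <- rep_len(seq_len(spec$n_motifs), spec$S)
  vapply(seq_len(spec$S), function(i) {
    m <- assign[i]
    current[m] <<- mutate_peptide(current[m], spec$mutations_per_step)
    current[m]
  }, character(1))
}

mock_frequencies <- function(spec, seed) {
  switch(spec$size_law,
         uniform = rep(1 / spec$S, spec$S),
         powerlaw = powerlaw_frequencies(spec$S, spec$exponent),
         dirichlet = dirichlet_frequencies(spec$S, spec$conc, seed))
}

#' Generate one synthetic sequence repertoire
#'
#' Seeds `n_motifs` random CDR3-like peptides and expands each by a random
#' walk of point substitutions (no indels, so distances are controlled
#' primarily by substitution count); clone sizes follow the spec's size law.
#' Sequences may collide (a raw clone table is returned; duplicates merge on
#' normalisation).
#'
#' @param spec A [mock_spec()].
#' @param sample_id Sample identifier.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A [clone_table()] with `frequency`-scale abundances.
#' @export
make_mock_repertoire <- function(spec, sample_id, seed) {
  stopifnot(inherits(spec, "mock_spec"))
  seqs <- withr::with_seed(seed, generate_mock_sequences(spec))
  clone_table(seqs, mock_frequencies(spec, seed), sample_id = sample_id)
}

#' Generate a labelled cohort of clone-table TSVs
#'
#' One clone table per sample; class differences are encoded by giving each
#' class its own [mock_spec()] (different size law and/or motif tightness).
#' A cohort manifest TSV (`cohort_manifest.tsv`: sample_id, class, path) is
#' written alongside.
#'
#' @param specs Named list of [mock_spec()]s, one per class.
#' @param n_per_class Samples per class (scalar or per-class vector).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; sample k of class c uses a sub-seed derived
#'   deterministically from it.
#' @return The manifest data frame, invisibly.
#' @export
make_sequence_cohort <- function(specs, n_per_class, dir, seed) {
  stopifnot(is.list(specs), length(specs) >= 1, !is.null(names(specs)))
  n_per_class <- rep_len(n_per_class, length(specs))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  counter <- 0L
  for (ci in seq_along(specs)) {
    for (k in seq_len(n_per_class[ci])) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", names(specs)[ci], k)
      ct <- make_mock_repertoire(specs[[ci]], sid, seed + counter)
      path <- file.path(dir, paste0(sid, ".tsv"))
      write_tsv_plain(data.frame(sequence = ct$sequence,
                                 frequency = ct$abundance), path)
      rows[[counter]] <- data.frame(sample_id = sid,
                                    class = names(specs)[ci],
                                    path = basename(path),
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write_tsv_plain(manifest, file.path(dir, "cohort_manifest.tsv"))
  invisible(manifest)
}
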