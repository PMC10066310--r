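# Pairwise CDR3beta distances under two metrics, computed and persisted in
# row-chunks that concatenate to the full S x S matrix.
#
# The chunk layout mirrors the parallel design of the pipeline: each chunk
# holds a contiguous block of rows, every row holding the distances of one
# sequence against ALL S sequences. Full rows are computed per chunk (each
# pair is computed twice across a run); symmetry is exploited only by tests.

check_peptide <- function(x, arg = "sequence") {
  if (length(x) == 0 || any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x))) {
    stop(arg, " must be non-empty and contain only canonical amino acids",
         call. = FALSE)
  }
  invisible(x)
}

#' Global alignment score between two peptides
#'
#' Optimal Needleman-Wunsch global alignment score under a substitution
#' matrix with a *linear* gap cost (each gap position costs `gap_penalty`;
#' opening costs nothing extra).
#'
#' @param a,b Peptide strings (canonical amino acids, non-empty).
#' @param matrix Substitution matrix; default [blosum45_matrix()].
#' @param gap_penalty Positive per-position gap cost (default 10).
#' @return Integer-valued optimal global alignment score.
#' @examples
#' global_alignment_score("CASSL", "CASSL")  # 30
#' @export
global_alignment_score <- function(a, b, matrix = blosum45_matrix(),
                                   gap_penalty = 10) {
  check_peptide(a, "a"); check_peptide(b, "b")
  as.numeric(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = matrix, type = "global",
    gapOpening = 0, gapExtension = gap_penalty, scoreOnly = TRUE))
}

# One pattern set against one subject, score-only; the S x S workhorse.
alignment_scores_vs <- function(patterns, subject, matrix, gap_penalty) {
  as.numeric(Biostrings::pairwiseAlignment(
    patterns, subject, substitutionMatrix = matrix, type = "global",
    gapOpening = 0, gapExtension = gap_penalty, scoreOnly = TRUE))
}

#' Alignment-based distance between two peptides
#'
#' `d(a, b) = 1 - score(a, b) / max(score(a, a), score(b, b))`, i.e. the
#' cross score normalised by the larger self score. Identical sequences have
#' distance 0. A negative value (cross score exceeding the larger self score,
#' not expected for global alignment under BLOSUM45) is floored at 0 with a
#' warning, since the similarity kernel `exp(-lambda d)` requires `d >= 0`.
#'
#' @inheritParams global_alignment_score
#' @return Non-negative distance (at most 2 in practice: the score of an
#'   alignment is bounded below by minus the larger self score).
#' @examples
#' blosum_distance("CASSL", "CASSV")  # 1 - 26/30
#' @export
blosum_distance <- function(a, b, matrix = blosum45_matrix(),
                            gap_penalty = 10) {
  saa <- global_alignment_score(a, a, matrix, gap_penalty)
  sbb <- global_alignment_score(b, b, matrix, gap_penalty)
  m <- max(saa, sbb)
  if (m <= 0) stop("degenerate scorer: max self-score <= 0", call. = FALSE)
  d <- 1 - global_alignment_score(a, b, matrix, gap_penalty) / m
  if (d < 0) {
    warning("negative distance floored at 0 for (", a, ", ", b, ")",
            call. = FALSE)
    d <- 0
  }
  d
}

#' Atchley-factor embedding of a peptide
#'
#' Arithmetic mean of the per-residue five-factor vectors. Note the map is
#' not injective ("A" and "AA" share an embedding); it trades positional
#' information for a fixed-length biochemical summary.
#'
#' @param a Peptide string.
#' @param table Factor table; default [atchley_factors()].
#' @return Numeric 5-vector named `f1`..`f5`.
#' @export
atchley_embed <- function(a, table = atchley_factors()) {
  check_peptide(a, "a")
  residues <- strsplit(a, "")[[1]]
  colMeans(table[residues, , drop = FALSE])
}

#' Euclidean distance between Atchley embeddings
#'
#' @param a,b Peptide strings.
#' @param table Factor table; default [atchley_factors()].
#' @return Non-negative distance; 0 for identical embeddings.
#' @export
atchley_distance <- function(a, b, table = atchley_factors()) {
  sqrt(sum((atchley_embed(a, table) - atchley_embed(b, table))^2))
}

new_distance_chunks <- function(chunks, metric, sample_id, n_sequences,
                                checksum) {
  structure(list(chunks = chunks, metric = metric, sample_id = sample_id,
                 n_sequences = n_sequences, checksum = checksum),
            class = "distance_chunks")
}

#' @export
print.distance_chunks <- function(x, ...) {
  cat("<distance_chunks> ", x$sample_id, ": ", length(x$chunks),
      " chunk(s) of a ", x$n_sequences, " x ", x$n_sequences,
      " matrix, metric '", x$metric, "'\n", sep = "")
  invisible(x)
}

chunk_row_starts <- function(S, chunk_size) {
  seq.int(0L, S - 1L, by = chunk_size)
}

#' Compute the pairwise distance matrix in row chunks
#'
#' Splits the `S` sequences into blocks of `chunk_size` consecutive rows and
#' computes, for each row, the distance of that sequence against all `S`
#' sequences. The concatenated blocks form the full distance matrix (zero
#' diagonal, symmetric); the result is independent of `chunk_size` and
#' `workers`.
#'
#' @param rep A [tcr_repertoire()].
#' @param metric `"blosum45"` (alignment-based) or `"atchley"` (embedding).
#' @param chunk_size Rows per chunk (default 100).
#' @param workers Number of parallel workers for chunk computation
#'   (forked via [parallel::mclapply()]; 1 = sequential).
#' @param gap_penalty Linear gap cost for the alignment metric.
#' @return A `distance_chunks` object: ordered list of chunks, each with
#'   0-based `row_start`, `row_count` and a `row_count x S` `values` matrix,
#'   plus the metric tag and the checksum of the sequence list.
#' @export
compute_distance_chunks <- function(rep, metric = c("blosum45", "atchley"),
                                    chunk_size = 100, workers = 1,
                                    gap_penalty = 10) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  metric <- match.arg(metric)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1) {
    stop("chunk_size must be >= 1", call. = FALSE)
  }
  seqs <- rep$sequences
  S <- length(seqs)
  check_peptide(seqs, "repertoire sequences")

  if (metric == "blosum45") {
    mat <- blosum45_matrix()
    self <- vapply(seqs, function(s) {
      sum(mat[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
    }, numeric(1))
    # self score of an identity alignment; gapped alternatives cannot beat it
    # for a matrix with positive diagonal, but guard anyway on first use
    row_fun <- function(i) {
      cross <- alignment_scores_vs(seqs, seqs[i], mat, gap_penalty)
      d <- 1 - cross / pmax(self, self[i])
      d[i] <- 0
      neg <- d < 0
      if (any(neg)) {
        warning("negative distance(s) floored at 0 in row ", i, call. = FALSE)
        d[neg] <- 0
      }
      d
    }
  } else {
    emb <- t(vapply(seqs, atchley_embed, numeric(5)))
    row_fun <- function(i) {
      d <- sqrt(rowSums(sweep(emb, 2, emb[i, ])^2))
      d[i] <- 0
      unname(d)
    }
  }

  starts <- chunk_row_starts(S, chunk_size)
  build_chunk <- function(row_start) {
    n <- min(chunk_size, S - row_start)
    vals <- t(vapply(seq_len(n) + row_start, row_fun, numeric(S)))
    list(row_start = row_start, row_count = n, values = vals)
  }
  chunks <- if (workers > 1) {
    parallel::mclapply(starts, build_chunk, mc.cores = workers)
  } else {
    lapply(starts, build_chunk)
  }
  new_distance_chunks(chunks, metric, rep$sample_id, S,
                      sequence_checksum(seqs))
}

#' Wrap a dense precomputed distance matrix as chunks
#'
#' Used for mock repertoires whose distance structure is specified directly
#' rather than derived from sequences.
#'
#' @param dmat Dense `S x S` distance matrix (zero diagonal, symmetric).
#' @param rep The matching [tcr_repertoire()].
#' @param chunk_size Rows per chunk.
#' @return A `distance_chunks` object with metric tag `"precomputed"`.
#' @export
as_distance_chunks <- function(dmat, rep, chunk_size = 100) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  S <- length(rep$sequences)
  dmat <- as.matrix(dmat)
  if (!all(dim(dmat) == c(S, S))) {
    stop("distance matrix dimensions do not match the repertoire",
         call. = FALSE)
  }
  if (any(dmat < 0) || any(abs(diag(dmat)) > 0)) {
    stop("distance matrix must be non-negative with zero diagonal",
         call. = FALSE)
  }
  starts <- chunk_row_starts(S, as.integer(chunk_size))
  chunks <- lapply(starts, function(row_start) {
    n <- min(chunk_size, S - row_start)
    list(row_start = row_start, row_count = n,
         values = dmat[seq_len(n) + row_start, , drop = FALSE])
  })
  new_distance_chunks(chunks, "precomputed", rep$sample_id, S,
                      sequence_checksum(rep$sequences))
}

#' Concatenate chunks into the dense distance matrix
#'
#' @param chunks A `distance_chunks` object.
#' @return The `S x S` numeric matrix.
#' @export
distance_matrix <- function(chunks) {
  stopifnot(inherits(chunks, "distance_chunks"))
  ord <- order(vapply(chunks$chunks, `[[`, integer(1), "row_start"))
  out <- do.call(rbind, lapply(chunks$chunks[ord], `[[`, "values"))
  dimnames(out) <- NULL
  out
}

#' Persist distance chunks and a manifest
#'
#' One headerless TSV per chunk, named `<sample>_chunk_<row_start>.tsv`,
#' row-major, plus a `<sample>_chunks_manifest.tsv` listing chunk paths, row
#' ranges, the metric tag and the repertoire sequence checksum.
#'
#' @param chunks A `distance_chunks` object.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_distance_chunks <- function(chunks, dir) {
  stopifnot(inherits(chunks, "distance_chunks"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(chunks$chunks, function(ch) {
    path <- file.path(dir, sprintf("%s_chunk_%d.tsv", chunks$sample_id,
                                   ch$row_start))
    write_tsv_plain(as.data.frame(ch$values), path, col.names = FALSE)
    data.frame(path = basename(path), row_start = ch$row_start,
               row_count = ch$row_count, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$metric <- chunks$metric
  manifest$n_sequences <- chunks$n_sequences
  manifest$checksum <- chunks$checksum
  manifest$sample_id <- chunks$sample_id
  mpath <- file.path(dir, sprintf("%s_chunks_manifest.tsv", chunks$sample_id))
  write_tsv_plain(manifest, mpath)
  invisible(mpath)
}

#' Load distance chunks from a manifest
#'
#' Validates each chunk file's shape against the manifest.
#'
#' @param manifest_path Path to a manifest written by
#'   [write_distance_chunks()].
#' @return A `distance_chunks` object.
#' @export
read_distance_chunks <- function(manifest_path) {
  man <- read_tsv_plain(manifest_path)
  dir <- dirname(manifest_path)
  S <- man$n_sequences[1]
  chunks <- lapply(seq_len(nrow(man)), function(k) {
    vals <- as.matrix(read_tsv_plain(file.path(dir, man$path[k]),
                                     header = FALSE))
    dimnames(vals) <- NULL
    if (nrow(vals) != man$row_count[k] || ncol(vals) != S) {
      stop("chunk file '", man$path[k], "' has shape ", nrow(vals), " x ",
           ncol(vals), ", expected ", man$row_count[k], " x ", S,
           call. = FALSE)
    }
    list(row_start = man$row_start[k], row_count = man$row_count[k],
         values = vals)
  })
  new_distance_chunks(chunks, man$metric[1], man$sample_id[1], S,
                      man$checksum[1])
}
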