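# Naive and similarity-scaled Hill diversities over the (q, lambda) grid.
#
# D(q) = (sum_i p_i^q)^(1/(1-q)) is the Hill number of order q; the
# similarity-scaled generalisation replaces each clone's own frequency with
# its kernel-weighted effective abundance (Zp)_i = sum_j exp(-lambda d_ij) p_j:
#
#   D(q, lambda) = (sum_i p_i (Zp)_i^(q-1))^(1/(1-q)).
#
# lambda = 0 makes every clone identical (D = 1); the identity sentinel
# (Z = I, i.e. lambda -> infinity) recovers the naive Hill number. The q = 1
# and q = infinity cases are the continuous limits exp(-sum p_i ln (Zp)_i)
# and 1 / max_i (Zp)_i. All sums with extreme exponents run in log space.

DEFAULT_Q <- c(0, 1, 2, 3, 4, 5, 6, Inf)
DEFAULT_LAMBDA <- c(0, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.75, 1,
                    1.5, 2, 4, 8, 16, 32, 64)

#' Evaluation grid for diversity profiles
#'
#' The default q list subsumes the common single-index summaries (q = 0
#' richness, q = 1 exponential Shannon, q = 2 inverse Simpson, q = Inf
#' reciprocal Berger-Parker) plus orders 3-6; the default lambda list covers
#' 0 (all clones identical) through a doubling sequence up to 64, with the
#' identity sentinel (naive diversity) appended last.
#'
#' @param q Ascending numeric vector of Hill orders; may end with `Inf`.
#' @param lambda Ascending numeric vector of finite, non-negative kernel
#'   scales.
#' @param include_identity Append the identity (naive) column? Default TRUE.
#' @return An object of class `parameter_grid` with elements `q`, `lambda`
#'   and `include_identity`. The identity column is represented internally as
#'   `lambda = Inf` and serialized as the token `"identity"`.
#' @export
parameter_grid <- function(q = DEFAULT_Q, lambda = DEFAULT_LAMBDA,
                           include_identity = TRUE) {
  q <- as.numeric(q); lambda <- as.numeric(lambda)
  if (length(q) == 0 || length(lambda) == 0) {
    stop("q and lambda must be non-empty", call. = FALSE)
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q values must be strictly ascending", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda < 0) ||
      is.unsorted(lambda, strictly = TRUE)) {
    stop("lambda values must be finite, non-negative and strictly ascending",
         call. = FALSE)
  }
  structure(list(q = q, lambda = lambda,
                 include_identity = isTRUE(include_identity)),
            class = "parameter_grid")
}

grid_lambdas <- function(grid) {
  c(grid$lambda, if (grid$include_identity) Inf)
}

check_frequencies <- function(freqs) {
  if (any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("frequencies must be positive and sum to 1", call. = FALSE)
  }
  invisible(freqs)
}

#' Naive (similarity-blind) Hill diversity
#'
#' @param freqs Positive frequency vector summing to 1 (within 1e-9).
#' @param q Single Hill order in `[0, Inf]`.
#' @return The effective number of clones, in `[1, S]`.
#' @examples
#' naive_diversity(c(0.5, 0.25, 0.25), 2)  # 1 / 0.375
#' @export
naive_diversity <- function(freqs, q) {
  check_frequencies(freqs)
  exp(ln_naive_diversity(freqs, q))
}

ln_naive_diversity <- function(freqs, q) {
  lp <- log(freqs)
  if (is.infinite(q)) {
    -max(lp)
  } else if (q == 1) {
    -sum(freqs * lp)
  } else {
    logsumexp(q * lp) / (1 - q)
  }
}

#' Kernel-weighted effective abundances for a chunk
#'
#' For each row i of the chunk, `(Zp)_i = sum_j exp(-lambda d_ij) p_j`: the
#' total frequency mass within reach of clone i under the similarity kernel.
#' Bounded between the clone's own frequency (no neighbours) and 1 (all
#' clones within reach).
#'
#' @param chunk One chunk (list with `row_start`, `row_count`, `values`).
#' @param freqs Frequency vector of length S.
#' @param lambda Non-negative finite kernel scale, or `Inf` for the identity
#'   sentinel (returns the rows' own frequencies).
#' @return Numeric vector of length `row_count`.
#' @export
kernel_weighted_abundance <- function(chunk, freqs, lambda) {
  if (is.na(lambda) || lambda < 0) {
    stop("lambda must be >= 0", call. = FALSE)
  }
  if (ncol(chunk$values) != length(freqs)) {
    stop("chunk width does not match frequency vector length", call. = FALSE)
  }
  rows <- chunk$row_start + seq_len(chunk$row_count)
  if (is.infinite(lambda)) {
    return(freqs[rows])
  }
  as.vector(exp(-lambda * chunk$values) %*% freqs)
}

#' Similarity-scaled Hill diversity from effective abundances
#'
#' @param freqs Positive frequency vector summing to 1.
#' @param zp Full kernel-weighted abundance vector `(Zp)_i`, element-wise in
#'   `[p_i, 1]`.
#' @param q Single Hill order in `[0, Inf]`.
#' @return The effective number of clones, in `[1, naive_diversity(freqs, q)]`.
#' @export
similarity_scaled_diversity <- function(freqs, zp, q) {
  check_frequencies(freqs)
  if (length(zp) != length(freqs) ||
      any(zp < freqs - 1e-9) || any(zp > 1 + 1e-9)) {
    stop("zp must be element-wise within [p_i, 1]", call. = FALSE)
  }
  exp(ln_similarity_scaled_diversity(freqs, zp, q))
}

ln_similarity_scaled_diversity <- function(freqs, zp, q) {
  lzp <- log(zp)
  if (is.infinite(q)) {
    -max(lzp)
  } else if (q == 1) {
    -sum(freqs * lzp)
  } else {
    logsumexp(log(freqs) + (q - 1) * lzp) / (1 - q)
  }
}

#' Evaluate ln D(q, lambda) over the full grid
#'
#' Streams over distance chunks once per finite lambda, accumulating the
#' effective-abundance vector, then evaluates every q. The identity column is
#' computed exactly from the naive formula (never from `exp(-lambda d)` at
#' large lambda), and the lambda = 0 column is exactly 0 on the log scale.
#'
#' @param rep A [tcr_repertoire()].
#' @param chunks A `distance_chunks` object or the path of a chunk manifest;
#'   its sequence checksum must match the repertoire.
#' @param grid A [parameter_grid()].
#' @return An object of class `diversity_grid`: the matrix `log_values` of
#'   ln D indexed `[q, lambda]` (identity column last), the grid, and the
#'   sample id.
#' @export
diversity_grid <- function(rep, chunks, grid = parameter_grid()) {
  stopifnot(inherits(rep, "tcr_repertoire"), inherits(grid, "parameter_grid"))
  if (is.character(chunks)) chunks <- read_distance_chunks(chunks)
  stopifnot(inherits(chunks, "distance_chunks"))
  if (chunks$checksum != sequence_checksum(rep$sequences)) {
    stop("distance chunks were not computed from this repertoire ",
         "(sequence checksum mismatch)", call. = FALSE)
  }
  freqs <- rep$frequencies
  check_frequencies(freqs)
  S <- length(freqs)
  lambdas <- grid_lambdas(grid)
  out <- matrix(NA_real_, nrow = length(grid$q), ncol = length(lambdas),
                dimnames = list(format_q(grid$q), format_lambda(lambdas)))
  for (j in seq_along(lambdas)) {
    lam <- lambdas[j]
    if (is.infinite(lam)) {
      out[, j] <- vapply(grid$q, function(q) ln_naive_diversity(freqs, q),
                         numeric(1))
    } else if (lam == 0) {
      out[, j] <- 0
    } else {
      zp <- numeric(S)
      for (ch in chunks$chunks) {
        zp[ch$row_start + seq_len(ch$row_count)] <-
          kernel_weighted_abundance(ch, freqs, lam)
      }
      out[, j] <- vapply(grid$q, function(q) {
        ln_similarity_scaled_diversity(freqs, zp, q)
      }, numeric(1))
    }
  }
  structure(list(sample_id = rep$sample_id, log_values = out, grid = grid),
            class = "diversity_grid")
}

#' @export
print.diversity_grid <- function(x, ...) {
  cat("<diversity_grid> ", x$sample_id, ": ", nrow(x$log_values), " q x ",
      ncol(x$log_values), " lambda values of ln D\n", sep = "")
  print(round(x$log_values, 4))
  invisible(x)
}

#' Write a diversity grid as a long-format table
#'
#' Columns `sample_id`, `q`, `lambda`, `ln_D`, `D`; the q = Inf and identity
#' sentinels are serialized as the literal tokens `inf` and `identity`.
#'
#' @param grid A `diversity_grid`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_diversity_table <- function(grid, path) {
  stopifnot(inherits(grid, "diversity_grid"))
  lv <- grid$log_values
  long <- expand.grid(q = rownames(lv), lambda = colnames(lv),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long <- data.frame(sample_id = grid$sample_id, long,
                     ln_D = as.vector(lv), D = exp(as.vector(lv)))
  write_tsv_plain(long, path)
}

#' Read a diversity grid back from its long-format table
#'
#' @param path Path written by [write_diversity_table()].
#' @return A `diversity_grid`.
#' @export
read_diversity_table <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("sample_id", "q", "lambda", "ln_D")
  if (!all(need %in% names(df))) {
    stop("diversity table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  qs <- sort(unique(parse_q(as.character(df$q))))
  lambdas <- sort(unique(parse_lambda(as.character(df$lambda))))
  include_identity <- any(is.infinite(lambdas))
  grid <- parameter_grid(qs, lambdas[is.finite(lambdas)], include_identity)
  lv <- matrix(NA_real_, length(qs), length(lambdas),
               dimnames = list(format_q(qs),
                               format_lambda(lambdas)))
  lv[cbind(format_q(parse_q(as.character(df$q))),
           format_lambda(parse_lambda(as.character(df$lambda))))] <- df$ln_D
  if (anyNA(lv)) stop("diversity table has missing grid cells", call. = FALSE)
  structure(list(sample_id = as.character(df$sample_id[1]),
                 log_values = lv, grid = grid),
            class = "diversity_grid")
}
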