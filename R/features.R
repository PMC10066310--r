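# Scalar profile features: areas between lambda curves, small-lambda
# spacing, and q-slopes. These reduce the two-parameter surface ln D(q,
# lambda) to a fixed-length vector suitable for ordination and
# classification.

grid_lambda_values <- function(grid) parse_lambda(colnames(grid$log_values))
grid_q_values <- function(grid) parse_q(rownames(grid$log_values))

lambda_column <- function(grid, lambda) {
  tok <- format_lambda(lambda)
  if (!tok %in% colnames(grid$log_values)) {
    stop("lambda ", tok, " is not on the grid", call. = FALSE)
  }
  grid$log_values[, tok]
}

#' Area between two lambda curves
#'
#' Composite trapezoidal integral, over the finite q axis, of
#' `ln D(q, lambda_high) - ln D(q, lambda_low)`. Since ln D is non-decreasing
#' in lambda, the area is non-negative whenever `lambda_high > lambda_low`.
#' A large area between the naive (identity) curve and a large-lambda curve
#' indicates many similar clones: a small amount of effective clustering
#' already produces a large drop from the naive diversity.
#'
#' @param grid A `diversity_grid`.
#' @param lambda_low,lambda_high Lambda values present on the grid (`Inf` for
#'   the identity curve).
#' @return The integral over q (the q = Inf row is excluded: the trapezoid
#'   rule needs a finite abscissa).
#' @export
area_between_lambda_curves <- function(grid, lambda_low, lambda_high) {
  stopifnot(inherits(grid, "diversity_grid"))
  qs <- grid_q_values(grid)
  fin <- is.finite(qs)
  ylo <- lambda_column(grid, lambda_low)[fin]
  yhi <- lambda_column(grid, lambda_high)[fin]
  unname(pracma::trapz(qs[fin], yhi - ylo))
}

#' Mean spacing of the small-lambda curves
#'
#' For each adjacent pair in the small-lambda set, the difference
#' `ln D(q, lambda_{k+1}) - ln D(q, lambda_k)` is averaged over all finite q;
#' the feature is the mean over pairs. To first order in lambda this spacing
#' equals `Delta-lambda` times the frequency-weighted mean pairwise distance
#' `dbar = sum_ij p_i p_j d_ij`, independent of q, so it reads out the
#' overall sequence dissimilarity of the repertoire. Differences are not
#' normalised by `Delta-lambda` (the default set is evenly spaced at 0.1).
#'
#' @param grid A `diversity_grid`.
#' @param small_lambdas At least two lambda values present on the grid;
#'   default `{0, 0.1, 0.2, 0.3, 0.4, 0.5}` (0.25 and 0.75 are deliberately
#'   excluded from the default even when present on the evaluation grid, to
#'   keep the spacing uniform).
#' @return Non-negative mean spacing.
#' @export
mean_small_lambda_spacing <- function(grid,
                                      small_lambdas = c(0, 0.1, 0.2,
                                                        0.3, 0.4, 0.5)) {
  stopifnot(inherits(grid, "diversity_grid"))
  if (length(small_lambdas) < 2) {
    stop("need at least two lambda values", call. = FALSE)
  }
  small_lambdas <- sort(small_lambdas)
  qs <- grid_q_values(grid)
  fin <- is.finite(qs)
  cols <- vapply(small_lambdas, function(l) lambda_column(grid, l)[fin],
                 numeric(sum(fin)))
  mean(colMeans(cols[, -1, drop = FALSE] -
                  cols[, -ncol(cols), drop = FALSE]))
}

#' Slope of the profile between two q values
#'
#' The finite difference `ln D(q_b, lambda) - ln D(q_a, lambda)`; negative
#' for non-uniform repertoires (ln D is non-increasing in q) and reported
#' as-is. Its magnitude at the naive curve reflects clonal expansion (the
#' balance of large to small clones).
#'
#' @param grid A `diversity_grid`.
#' @param lambda Lambda value on the grid (`Inf` for the identity curve).
#' @param q_a,q_b Finite q values on the grid, `q_a < q_b`.
#' @return The (signed) difference.
#' @export
q_slope <- function(grid, lambda, q_a, q_b) {
  stopifnot(inherits(grid, "diversity_grid"))
  if (is.infinite(q_a) || is.infinite(q_b)) {
    stop("q slopes are finite differences; q = inf is not allowed",
         call. = FALSE)
  }
  if (!(q_a < q_b)) stop("q_a must be < q_b", call. = FALSE)
  col <- lambda_column(grid, lambda)
  toks <- format_q(c(q_a, q_b))
  if (!all(toks %in% names(col))) {
    stop("q value(s) ", paste(setdiff(toks, names(col)), collapse = ", "),
         " not on the grid", call. = FALSE)
  }
  unname(col[toks[2]] - col[toks[1]])
}

#' Extract the full feature vector of a diversity grid
#'
#' Features: the area between every adjacent pair in the sorted lambda list
#' (identity last) -- arbitrary pairs follow by additivity of the integral;
#' the mean small-lambda spacing; and the three slopes (0 to 1, 1 to 2, 0 to
#' 2) at every lambda including identity. Column naming is stable:
#' `area_l<low>_l<high>`, `dln_small_lambda`, `slope_q<a>_<b>_l<lambda>`.
#'
#' @param grid A `diversity_grid` over a complete evaluation grid.
#' @param small_lambdas Passed to [mean_small_lambda_spacing()].
#' @return A named numeric vector with attribute `sample_id`.
#' @export
extract_features <- function(grid, small_lambdas = c(0, 0.1, 0.2,
                                                     0.3, 0.4, 0.5)) {
  stopifnot(inherits(grid, "diversity_grid"))
  lv <- grid$log_values
  if (anyNA(lv)) {
    bad <- which(is.na(lv), arr.ind = TRUE)
    stop("incomplete grid; missing cells: ",
         paste(sprintf("(q=%s, lambda=%s)", rownames(lv)[bad[, 1]],
                       colnames(lv)[bad[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  lambdas <- grid_lambda_values(grid)
  ltok <- colnames(lv)
  areas <- vapply(seq_len(length(lambdas) - 1), function(k) {
    area_between_lambda_curves(grid, lambdas[k], lambdas[k + 1])
  }, numeric(1))
  names(areas) <- sprintf("area_l%s_l%s", ltok[-length(ltok)], ltok[-1])
  pairs <- list(c(0, 1), c(1, 2), c(0, 2))
  slopes <- unlist(lapply(seq_along(lambdas), function(j) {
    vals <- vapply(pairs, function(pq) {
      q_slope(grid, lambdas[j], pq[1], pq[2])
    }, numeric(1))
    names(vals) <- sprintf("slope_q%g_%g_l%s",
                           vapply(pairs, `[`, numeric(1), 1),
                           vapply(pairs, `[`, numeric(1), 2), ltok[j])
    vals
  }))
  out <- c(areas, dln_small_lambda = mean_small_lambda_spacing(
    grid, small_lambdas), slopes)
  if (any(!is.finite(out))) stop("non-finite feature values", call. = FALSE)
  attr(out, "sample_id") <- grid$sample_id
  out
}

#' Bind per-sample feature vectors into a feature table
#'
#' @param features A list of vectors from [extract_features()].
#' @return A data frame: `sample_id` column plus one column per feature.
#' @export
feature_table <- function(features) {
  stopifnot(length(features) > 0)
  nm <- names(features[[1]])
  for (f in features) {
    if (!identical(names(f), nm)) {
      stop("feature vectors have mismatched columns", call. = FALSE)
    }
  }
  out <- as.data.frame(do.call(rbind, lapply(features, unclass)))
  data.frame(sample_id = vapply(features, attr, character(1), "sample_id"),
             out, check.names = FALSE)
}

#' Write / read a feature table
#'
#' @param ft Data frame from [feature_table()].
#' @param path TSV path.
#' @return The path (write) or the data frame (read).
#' @export
write_feature_table <- function(ft, path) write_tsv_plain(ft, path)

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) read_tsv_plain(path)

#' Plot profile curves of a diversity grid
#'
#' Convenience line plot of ln D versus finite q, one curve per lambda.
#'
#' @param x A `diversity_grid`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.diversity_grid <- function(x, ...) {
  qs <- grid_q_values(x)
  fin <- is.finite(qs)
  graphics::matplot(qs[fin], x$log_values[fin, , drop = FALSE], type = "l",
                    lty = 1, xlab = "q", ylab = "ln D(q, lambda)",
                    main = x$sample_id, ...)
  invisible(x)
}
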