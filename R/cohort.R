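# Multi-sample stratification: PCA, complete-linkage clustering,
# partitioned leave-one-out classification, and the clone-size
# randomisation null.

#' Assemble a cohort matrix from feature tables and labels
#'
#' @param features A feature table ([feature_table()] / TSV read back) with a
#'   `sample_id` column, or a list of [extract_features()] vectors. Raw grid
#'   cells (one column per (q, lambda) cell) work equally well.
#' @param labels Data frame with a `sample_id` column plus one or more
#'   categorical label columns (e.g. `treatment`, `timepoint`).
#' @return An object of class `tcr_cohort`: numeric matrix `X` (samples x
#'   features, rownames = sample ids) and the aligned `labels` data frame.
#' @export
assemble_cohort <- function(features, labels) {
  if (!is.data.frame(features)) features <- feature_table(features)
  if (!"sample_id" %in% names(features)) {
    stop("feature table must have a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(features$sample_id)) {
    stop("duplicate sample_id in feature table: ",
         paste(unique(features$sample_id[duplicated(features$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(features) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- as.matrix(features[, setdiff(names(features), "sample_id"),
                          drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) {
    stop("feature matrix must be numeric with no missing cells",
         call. = FALSE)
  }
  rownames(X) <- features$sample_id
  if (!"sample_id" %in% names(labels)) {
    stop("label table must have a sample_id column", call. = FALSE)
  }
  missing <- setdiff(features$sample_id, labels$sample_id)
  if (length(missing)) {
    stop("missing label(s) for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- labels[match(features$sample_id, labels$sample_id), ,
                   drop = FALSE]
  rownames(labels) <- NULL
  structure(list(X = X, labels = labels), class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat("<tcr_cohort> ", nrow(x$X), " samples x ", ncol(x$X), " features; ",
      "labels: ", paste(setdiff(names(x$labels), "sample_id"),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of a cohort
#'
#' Mean-centered PCA of the feature matrix. Features are already on the ln D
#' scale, so columns are not variance-scaled by default.
#'
#' @param cm A `tcr_cohort`.
#' @param n_components Number of components to return (default all).
#' @param scale. Scale columns to unit variance? Default FALSE.
#' @return List with `scores` (samples x components), `loadings`, and
#'   `explained` -- the variance fractions of *all* components (descending,
#'   summing to 1).
#' @export
run_pca <- function(cm, n_components = NULL, scale. = FALSE) {
  stopifnot(inherits(cm, "tcr_cohort"))
  sds <- apply(cm$X, 2, stats::sd)
  if (all(sds == 0)) {
    stop("degenerate input: all feature columns are constant", call. = FALSE)
  }
  X <- cm$X
  if (scale.) X <- X[, sds > 0, drop = FALSE]
  p <- stats::prcomp(X, center = TRUE, scale. = scale.)
  explained <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components %||% length(p$sdev), length(p$sdev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained = explained)
}

#' Complete-linkage hierarchical clustering of a cohort
#'
#' Agglomerates samples on Euclidean feature distances under the
#' complete-linkage (maximum) criterion, as produced by [stats::hclust()]
#' (deterministic; equal-distance merges are resolved by the lowest
#' observation index).
#'
#' @param cm A `tcr_cohort`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(cm) {
  stopifnot(inherits(cm, "tcr_cohort"))
  if (any(!is.finite(cm$X))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  stats::hclust(stats::dist(cm$X), method = "complete")
}

#' Stratified round-robin partition assignment
#'
#' Samples are grouped by the combination of the given label columns; within
#' each group (optionally shuffled by `seed`) partitions `1..k` are dealt out
#' round-robin, so every label combination is represented in each partition
#' where counts allow, and leftovers are spread as evenly as possible (8
#' samples over 3 partitions gives 3/3/2).
#'
#' @param labels Label data frame with `sample_id`.
#' @param by Label column name(s) to stratify on; default all non-id columns.
#' @param k Number of partitions (default 3).
#' @param seed Optional seed to shuffle within-group order before dealing.
#' @return Named integer vector: partition index per sample id.
#' @export
make_partitions <- function(labels, by = NULL, k = 3, seed = NULL) {
  by <- by %||% setdiff(names(labels), "sample_id")
  grp <- interaction(labels[by], drop = TRUE)
  assign <- integer(nrow(labels))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (!is.null(seed)) {
      idx <- withr::with_seed(seed, sample(idx))
    }
    assign[idx] <- (seq_along(idx) - 1L) %% k + 1L
  }
  stats::setNames(assign, labels$sample_id)
}

#' Partitioned leave-one-out classification
#'
#' Each partition is held out once: a classifier is trained on the remaining
#' partitions and predicts the held-out samples. All predictions are then
#' concatenated and the overall accuracy computed, alongside per-fold
#' accuracies.
#'
#' @param cm A `tcr_cohort`.
#' @param partitions Named integer vector from [make_partitions()] (or a
#'   `partition` column in the labels).
#' @param label Name of the label column to predict.
#' @param classifier `"svm"` (linear kernel, default regularisation) or
#'   `"random_forest"` (default tree count).
#' @param seed Seed fixing the stochastic classifier (default 1).
#' @return List with `predictions` (data frame: sample_id, partition, truth,
#'   predicted), `fold_accuracy`, and `accuracy` (overall, on the
#'   concatenated predictions).
#' @export
partitioned_cv_classify <- function(cm, partitions, label,
                                    classifier = c("svm", "random_forest"),
                                    seed = 1) {
  stopifnot(inherits(cm, "tcr_cohort"))
  classifier <- match.arg(classifier)
  ids <- rownames(cm$X)
  if (!all(ids %in% names(partitions))) {
    stop("partition scheme does not cover all samples", call. = FALSE)
  }
  part <- partitions[ids]
  y <- factor(cm$labels[[label]])
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  folds <- sort(unique(part))
  for (f in folds) {
    absent <- setdiff(levels(y), unique(as.character(y[part != f])))
    if (length(absent)) {
      stop("class(es) ", paste(absent, collapse = ", "),
           " absent from the training set of partition ", f, call. = FALSE)
    }
  }
  preds <- lapply(folds, function(f) {
    train <- part != f
    Xtr <- cm$X[train, , drop = FALSE]
    ytr <- droplevels(y[train])
    fit_pred <- withr::with_seed(seed, {
      if (classifier == "svm") {
        fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
        stats::predict(fit, cm$X[!train, , drop = FALSE])
      } else {
        fit <- randomForest::randomForest(Xtr, ytr)
        stats::predict(fit, cm$X[!train, , drop = FALSE])
      }
    })
    data.frame(sample_id = ids[!train], partition = f,
               truth = as.character(y[!train]),
               predicted = as.character(fit_pred),
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  fold_acc <- vapply(folds, function(f) {
    sub <- preds[preds$partition == f, ]
    mean(sub$predicted == sub$truth)
  }, numeric(1))
  list(predictions = preds,
       fold_accuracy = stats::setNames(fold_acc, paste0("partition_", folds)),
       accuracy = mean(preds$predicted == preds$truth))
}

#' Replace clone sizes with pseudo-random frequencies
#'
#' Null control for structure driven by the coupling of clone size and
#' sequence similarity: the sequence list (and hence any computed distance
#' chunks) is kept fixed while frequencies are replaced by normalised
#' pseudo-random positive draws.
#'
#' @param rep A [tcr_repertoire()].
#' @param seed Integer seed.
#' @return A `tcr_repertoire` with the same sequence support.
#' @export
randomize_clone_sizes <- function(rep, seed) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  u <- withr::with_seed(seed, stats::runif(length(rep$sequences)))
  tcr_repertoire(rep$sequences, u / sum(u),
                 sample_id = paste0(rep$sample_id, "_randomized"),
                 subsample_depth = rep$subsample_depth, seed = seed)
}
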