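# Clone-table input, filtering, subsampling and the normalised repertoire.

#' Construct a raw clone table
#'
#' A raw clone table is the unnormalised input stage: one row per clone with a
#' non-negative abundance (a read count or an already-normalised frequency).
#' Sequences may repeat; they are merged when the table is subsampled.
#'
#' @param sequence Character vector of CDR3beta amino-acid sequences.
#' @param abundance Numeric vector of non-negative abundances, same length.
#' @param sample_id Sample identifier.
#' @param metadata Optional named list carried along (e.g. treatment label).
#' @return An object of class `clone_table` (a data frame with columns
#'   `sequence` and `abundance` plus `sample_id`/`metadata` attributes).
#' @export
clone_table <- function(sequence, abundance, sample_id = "sample",
                        metadata = list()) {
  sequence <- as.character(sequence)
  abundance <- as.numeric(abundance)
  if (length(sequence) != length(abundance)) {
    stop("sequence and abundance lengths differ", call. = FALSE)
  }
  if (length(sequence) == 0) {
    stop("clone table is empty", call. = FALSE)
  }
  if (anyNA(abundance)) {
    stop("abundance contains non-numeric values at row(s) ",
         paste(which(is.na(abundance)), collapse = ", "), call. = FALSE)
  }
  bad <- which(abundance < 0)
  if (length(bad)) {
    stop("negative abundance at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!any(abundance > 0)) {
    stop("all abundances are zero", call. = FALSE)
  }
  out <- data.frame(sequence = sequence, abundance = abundance,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "metadata") <- metadata
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Read a clone table from TSV
#'
#' Expects a tab-delimited file with a header row. The abundance column may
#' hold integer counts or real frequencies; values are preserved verbatim.
#'
#' @param path Path to the TSV file.
#' @param seq_column,abundance_column Column names. `abundance_column` falls
#'   back from `"count"` to `"frequency"` when the default is absent.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [clone_table()].
#' @export
read_repertoire <- function(path, seq_column = "sequence",
                            abundance_column = "count",
                            sample_id = NULL) {
  df <- read_tsv_plain(path)
  if (nrow(df) == 0) stop("empty clone table: '", path, "'", call. = FALSE)
  if (!seq_column %in% names(df)) {
    stop("missing column '", seq_column, "' in '", path, "'", call. = FALSE)
  }
  if (!abundance_column %in% names(df)) {
    if (abundance_column == "count" && "frequency" %in% names(df)) {
      abundance_column <- "frequency"
    } else {
      stop("missing column '", abundance_column, "' in '", path, "'",
           call. = FALSE)
    }
  }
  ab <- df[[abundance_column]]
  if (!is.numeric(ab)) {
    suppressWarnings(ab <- as.numeric(ab))
    if (anyNA(ab)) {
      stop("non-numeric abundance in column '", abundance_column,
           "' at row(s) ", paste(which(is.na(ab)), collapse = ", "),
           call. = FALSE)
    }
  }
  clone_table(df[[seq_column]], ab,
              sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Keep in-frame CDR3 sequences
#'
#' Input sequences are amino-acid text (translated upstream), so "in frame" is
#' operationalised as: non-empty and composed solely of the 20 canonical
#' amino-acid letters. Sequences containing `*` (stop), `X` (ambiguous) or any
#' other symbol are dropped; row order is preserved.
#'
#' @param rep A [clone_table()].
#' @return The filtered `clone_table`.
#' @export
filter_in_frame <- function(rep) {
  stopifnot(inherits(rep, "clone_table"))
  keep <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", rep$sequence)
  if (!any(keep)) stop("no in-frame sequences", call. = FALSE)
  out <- rep[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(rep, "sample_id")
  attr(out, "metadata") <- attr(rep, "metadata")
  class(out) <- class(rep)
  out
}

#' Construct a normalised repertoire
#'
#' A repertoire is the normalised unit all downstream computation consumes:
#' `S` unique clone sequences with strictly positive frequencies summing to 1.
#'
#' @param sequences Character vector of distinct sequences.
#' @param frequencies Positive numeric vector summing to 1 (within 1e-9).
#' @param sample_id Sample identifier.
#' @param subsample_depth Number of cell-level draws the repertoire was built
#'   from (`NA` when constructed directly).
#' @param seed Seed used for subsampling (`NA` when constructed directly).
#' @return An object of class `tcr_repertoire`.
#' @export
tcr_repertoire <- function(sequences, frequencies, sample_id = "sample",
                           subsample_depth = NA_integer_, seed = NA_integer_) {
  sequences <- as.character(sequences)
  frequencies <- as.numeric(frequencies)
  if (length(sequences) != length(frequencies)) {
    stop("sequences and frequencies lengths differ", call. = FALSE)
  }
  if (anyDuplicated(sequences)) {
    stop("sequences must be pairwise distinct", call. = FALSE)
  }
  if (any(frequencies <= 0)) {
    stop("all frequencies must be > 0", call. = FALSE)
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(frequencies)), ")",
         call. = FALSE)
  }
  structure(
    list(sequences = sequences, frequencies = frequencies,
         sample_id = as.character(sample_id),
         subsample_depth = as.integer(subsample_depth),
         seed = as.integer(seed)),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat("<tcr_repertoire> ", x$sample_id, ": ", length(x$sequences),
      " unique clones", sep = "")
  if (!is.na(x$subsample_depth)) {
    cat(", subsampled to depth ", x$subsample_depth, " (seed ", x$seed, ")",
        sep = "")
  }
  cat("\n  top clone frequency ", format(max(x$frequencies), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Subsample a clone table to a fixed depth
#'
#' Draws `depth` cell-level samples with replacement (multinomially) from the
#' normalised abundance distribution, merging duplicate sequences first, then
#' collapses the draws back to unique clones and converts counts to
#' frequencies. Subsampling normalises sequencing depth across samples so
#' repertoires of different sizes are comparable, and bounds the cost of the
#' all-against-all distance stage.
#'
#' @param rep A [clone_table()] that has passed [filter_in_frame()].
#' @param depth Number of draws (default 50000).
#' @param seed Integer seed; mandatory for reproducibility of this stochastic
#'   stage, and recorded in the result.
#' @return A [tcr_repertoire()] with `S <= depth` unique clones.
#' @export
subsample_repertoire <- function(rep, depth = 50000, seed) {
  stopifnot(inherits(rep, "clone_table"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1) stop("depth must be >= 1", call. = FALSE)

  # merge rows with identical sequence: clones are defined by sequence identity
  ab <- tapply(rep$abundance, rep$sequence, sum)
  ab <- ab[ab > 0]
  seqs <- names(ab)
  prob <- as.numeric(ab) / sum(ab)

  if (length(seqs) == 1L) {
    return(tcr_repertoire(seqs, 1, attr(rep, "sample_id"), depth, seed))
  }
  total <- sum(rep$abundance)
  looks_like_counts <- all(abs(rep$abundance - round(rep$abundance)) < 1e-6)
  if (looks_like_counts && total < depth) {
    warning("total integer abundance (", round(total),
            ") is below the subsampling depth (", depth,
            "); multinomial sampling proceeds unchanged", call. = FALSE)
  }
  counts <- withr::with_seed(seed, as.vector(stats::rmultinom(1, depth, prob)))
  keep <- counts > 0
  tcr_repertoire(seqs[keep], counts[keep] / depth,
                 sample_id = attr(rep, "sample_id"),
                 subsample_depth = depth, seed = seed)
}

#' Normalise a clone table into a repertoire without sampling
#'
#' Merges duplicate sequences and renormalises abundances to frequencies.
#' Used when the table is already at the desired depth (e.g. re-reading a
#' written repertoire, or synthetic fixtures).
#'
#' @param rep A [clone_table()].
#' @return A [tcr_repertoire()].
#' @export
as_tcr_repertoire <- function(rep) {
  stopifnot(inherits(rep, "clone_table"))
  ab <- tapply(rep$abundance, rep$sequence, sum)
  ab <- ab[ab > 0]
  tcr_repertoire(names(ab), as.numeric(ab) / sum(ab),
                 sample_id = attr(rep, "sample_id"))
}

#' Write a repertoire to TSV
#'
#' Columns `sequence` and `frequency`; frequencies are serialized with 17
#' significant digits so the table round-trips through [read_repertoire()]
#' plus renormalisation bit-identically.
#'
#' @param rep A [tcr_repertoire()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  write_tsv_plain(
    data.frame(sequence = rep$sequences, frequency = rep$frequencies), path)
}
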