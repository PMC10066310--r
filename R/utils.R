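# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## The 20 canonical amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Checksum of a sequence list
#'
#' Identifies the sequence support of a repertoire; distance chunks carry it so
#' that a chunk set can be validated against the repertoire it was computed
#' from. Frequencies are deliberately excluded: replacing clone sizes while
#' keeping the distance matrix fixed (the randomisation control) must keep the
#' chunks valid.
#' @noRd
sequence_checksum <- function(sequences) {
  rlang::hash(as.character(sequences))
}

## Sentinel tokens used in serialized tables: q = Inf -> "inf",
## lambda = Inf (the identity kernel, i.e. naive diversity) -> "identity".
format_q <- function(q) ifelse(is.infinite(q), "inf", as.character(q))

format_lambda <- function(lambda) {
  ifelse(is.infinite(lambda), "identity", as.character(lambda))
}

parse_q <- function(tok) {
  out <- suppressWarnings(as.numeric(ifelse(tok == "inf", "Inf", tok)))
  if (anyNA(out)) {
    stop("unknown q token(s): ", paste(unique(tok[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

parse_lambda <- function(tok) {
  out <- suppressWarnings(as.numeric(ifelse(tok == "identity", "Inf", tok)))
  if (anyNA(out)) {
    stop("unknown lambda token(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

## Fixed-format TSV writer so reruns are byte-identical across platforms;
## %.17g round-trips doubles exactly, which chunk resumption relies on.
write_tsv_plain <- function(df, path, col.names = TRUE) {
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  utils::read.table(path, sep = "\t", header = header, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
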