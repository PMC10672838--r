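# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a character tag
#'
#' Every stochastic step in the package draws its own seed from the run seed
#' and a stage tag, so that stages are decoupled (adding classifiers does not
#' shift the random sets, etc.) while the whole run stays deterministic.
#'
#' @param seed master integer seed
#' @param ... character or integer tags identifying the consumer
#' @return an integer in [0, 2^31 - 1)
#' @keywords internal
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(tag)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1

#' Write a data frame as TSV (no quoting, no row names)
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "", ...)
}
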