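#' Derive a stage-specific random seed from a root seed
#'
#' All randomness in the pipeline flows from one root seed through named
#' substreams, so that toggling one stage never perturbs the random numbers
#' another stage sees.
#'
#' @param seed Integer root seed.
#' @param stream Character name of the substream (e.g. \code{"expression"}).
#' @return An integer seed in \code{[0, 2^31)}.
#' @keywords internal
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used to score recovery of planted modules. Invariant to label
#' permutations.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index, 1 for identical partitions, about 0 for
#'   independent ones.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Shared TSV conventions: tab-separated, no quoting, no row names.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
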