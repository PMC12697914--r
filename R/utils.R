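#' Normalize a free-text label for comparison
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds. This is the single normalization rule used
#' everywhere two free-text labels (symptoms, backend responses) must be
#' compared.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @export
#' @examples
#' normalize_label(c("  Feelings of   Guilt ", "guilt"))
normalize_label <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' L2-normalize the rows of a matrix
#'
#' Zero rows are left unchanged (their norm is 0; dividing would produce NaN).
#'
#' @param m numeric matrix.
#' @return matrix with unit-norm rows.
#' @keywords internal
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Enumerate all set partitions of n elements
#'
#' Partitions are generated as restricted-growth strings, i.e. each partition
#' is an integer label vector of length `n` in canonical form (labels first
#' appear in increasing order starting at 1). Used for exhaustive validation
#' of partition statistics; the number of partitions is the Bell number
#' (15 at n = 4, 203 at n = 6).
#'
#' @param n number of elements (small; intended n <= 8).
#' @return list of integer vectors, one per partition.
#' @export
#' @examples
#' length(enumerate_partitions(4)) # 15
enumerate_partitions <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n <= 10)
  res <- list()
  rec <- function(labels, m) {
    if (length(labels) == n) {
      res[[length(res) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (j in seq_len(m + 1L)) {
      rec(c(labels, j), max(m, j))
    }
  }
  rec(integer(0), 0L)
  res
}

# Prefix-stable stream of sub-seeds derived from one master seed: the first
# b entries are identical for any requested length >= b, so increasing the
# number of repetitions never reshuffles earlier ones.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

# stop() with a class so callers/tests can distinguish validation failures
qo_stop <- function(..., class = "qoverlap_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
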