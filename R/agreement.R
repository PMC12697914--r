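# Agreement between clustering solutions: Adjusted Rand Index, pairwise
# rater agreement, verbal strength bands, and the permuted-embedding null
# distribution with its empirical 95% CI.

#' Adjusted Rand Index between two label vectors
#'
#' Hubert-Arabie chance-corrected Rand index from the contingency table: with
#' cell counts \eqn{n_{ij}}, row sums \eqn{a_i}, column sums \eqn{b_j} and
#' \eqn{n} items,
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
#'   {\tfrac12\left(\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}\right) -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}.}
#' The attainable range is \eqn{[-0.5, 1]}: 1 for identical partitions,
#' values near 0 for chance-level agreement, negative values for agreement
#' below chance. Label names are irrelevant and the index is symmetric in its
#' arguments.
#'
#' When both partitions are trivial (both all-singletons or both one single
#' cluster) the formula is 0/0; the partitions are then necessarily
#' identical and 1.0 is returned (the convention of the major
#' clustering-metrics libraries, keeping `ari(x, x) = 1` universally).
#'
#' @param a,b label vectors of equal length (>= 2), positionally aligned.
#' @return the ARI, a number in \eqn{[-0.5, 1]}.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) qo_stop("label vectors differ in length")
  n <- length(a)
  if (n < 2) qo_stop("ARI needs at least 2 items")
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  s_n <- choose(n, 2)
  expected <- s_a * s_b / s_n
  maximum <- (s_a + s_b) / 2
  if (maximum == expected) {
    # both partitions trivial; identical <=> all pair counts agree
    return(if (s_ij == s_a && s_a == s_b) 1.0 else 0.0)
  }
  (s_ij - expected) / (maximum - expected)
}

#' Adjusted Rand Index between two clusterings
#'
#' Item-id aware wrapper around [ari()]: the two clusterings must cover the
#' identical item-id set; items are aligned by id, not by position.
#'
#' @param c1,c2 [clustering()] objects over the same items.
#' @return the ARI.
#' @seealso [strength_band()] for the verbal interpretation scale.
#' @export
adjusted_rand_index <- function(c1, c2) {
  stopifnot(inherits(c1, "clustering"), inherits(c2, "clustering"))
  ids1 <- names(c1$assignments)
  ids2 <- names(c2$assignments)
  d <- c(setdiff(ids1, ids2), setdiff(ids2, ids1))
  if (length(d)) {
    qo_stop("clusterings cover different item sets; symmetric difference: ",
            paste(sort(d), collapse = ", "))
  }
  ids <- sort(ids1)
  ari(unname(c1$assignments[ids]), unname(c2$assignments[ids]))
}

#' Pairwise rater agreement
#'
#' ARI for every pair of rater labelings plus the mean over distinct pairs
#' (diagonal excluded): the "mean ARI" reported per diagnostic domain for the
#' expert-to-expert comparison.
#'
#' @param labelings list of >= 2 [rater_labeling()] over a common item set.
#' @return list with `matrix` (symmetric, unit diagonal, rater ids as
#'   dimnames) and `mean` (over the distinct unordered pairs; 3 pairs for 3
#'   raters).
#' @export
pairwise_rater_ari <- function(labelings) {
  if (length(labelings) < 2 ||
      !all(vapply(labelings, inherits, logical(1), "rater_labeling"))) {
    qo_stop("pairwise_rater_ari requires >= 2 rater labelings")
  }
  r <- length(labelings)
  ids <- sort(names(labelings[[1]]$assignments))
  m <- matrix(1, r, r,
              dimnames = rep(list(vapply(labelings, `[[`, "", "rater_id")), 2))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      a <- labelings[[i]]$assignments
      b <- labelings[[j]]$assignments
      d <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
      if (length(d)) {
        qo_stop("raters cover different item sets: ",
                paste(sort(d), collapse = ", "))
      }
      m[i, j] <- m[j, i] <- ari(unname(a[ids]), unname(b[ids]))
    }
  }
  list(matrix = m, mean = mean(m[upper.tri(m)]))
}

#' Verbal strength band for an ARI or Jaccard value
#'
#' The correlation-coefficient convention: very weak (0.00-0.19), weak
#' (0.20-0.39), moderate (0.40-0.59), strong (0.60-0.79), very strong
#' (0.80-1.00); negative values are "below chance". Boundaries are half-open
#' on the unrounded value, so 0.195 is "very weak", not "weak".
#'
#' @param value numeric vector of agreement/overlap values.
#' @return character vector of band labels.
#' @export
strength_band <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0) "below chance"
    else if (v < 0.2) "very weak"
    else if (v < 0.4) "weak"
    else if (v < 0.6) "moderate"
    else if (v < 0.8) "strong"
    else "very strong"
  }, character(1))
}

#' Permuted-embedding null distribution of the k-means ARI
#'
#' The chance-level control for the embedding arm: for each of `B`
#' repetitions the embedding vectors are randomly reattached to items
#' ([permute_embeddings()]), the permuted matrix is re-clustered with k-means
#' under the same hyperparameters, and the ARI against the reference
#' clustering is recorded. The 95% CI is the empirical 2.5th/97.5th
#' percentile of the `B` values (type-7 quantiles). Repetition `b` uses a
#' deterministic function of `(seed, b)`, so increasing `B` never reshuffles
#' earlier repetitions.
#'
#' @param E an [embedding_matrix()].
#' @param k number of clusters (from [expert_k()]).
#' @param reference the reference [clustering()] (normally the expert
#'   consensus), covering E's items.
#' @param B repetitions (default 1000).
#' @param seed master seed.
#' @param n_init,max_iter k-means hyperparameters, as in [kmeans_cluster()].
#' @return object of class `null_distribution`: `values` (length B), `B`,
#'   `ci_low`, `ci_high`, `seed`.
#' @export
permutation_null_ari <- function(E, k, reference, B = 1000L, seed = 1L,
                                 n_init = 10L, max_iter = 300L) {
  stopifnot(inherits(E, "embedding_matrix"), inherits(reference, "clustering"))
  B <- as.integer(B)
  if (B < 1) qo_stop("B must be >= 1")
  d <- c(setdiff(rownames(E), names(reference$assignments)),
         setdiff(names(reference$assignments), rownames(E)))
  if (length(d)) {
    qo_stop("reference clustering does not cover the embedding's items: ",
            paste(sort(d), collapse = ", "))
  }
  seeds <- derive_seeds(seed, 2L * B)
  values <- numeric(B)
  for (b in seq_len(B)) {
    values[b] <- tryCatch({
      Eb <- permute_embeddings(E, seeds[2L * b - 1L])
      cl <- kmeans_cluster(Eb, k, seed = seeds[2L * b],
                           n_init = n_init, max_iter = max_iter)
      adjusted_rand_index(cl, reference)
    }, error = function(e) {
      qo_stop("permutation repetition ", b, " failed: ",
              conditionMessage(e))
    })
  }
  ci <- unname(stats::quantile(values, c(0.025, 0.975), type = 7))
  structure(list(values = values, B = B, ci_low = ci[1], ci_high = ci[2],
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> B = %d, mean = %.4f, 95%% CI [%.4f, %.4f]\n",
    x$B, mean(x$values), x$ci_low, x$ci_high))
  invisible(x)
}
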