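# Clusterings: an assignment of every analyzed item to exactly one
# cluster/symptom label, tagged with its provenance (expert, kmeans, llm,
# truth), and the k-means arm that produces one from an embedding matrix.

CLUSTERING_METHODS <- c("expert", "kmeans", "llm", "truth")

#' Construct a clustering
#'
#' @param assignments named character (or integer) vector: names are item ids,
#'   values are cluster/symptom labels. Every analyzed item has exactly one
#'   label.
#' @param method provenance: `"expert"`, `"kmeans"`, `"llm"` or `"truth"`.
#' @return object of class `clustering` with fields `assignments`, `method`
#'   and `k` (the number of distinct labels actually used).
#' @export
clustering <- function(assignments, method) {
  method <- match.arg(method, CLUSTERING_METHODS)
  ids <- names(assignments)
  if (is.null(ids) || any(!nzchar(ids))) {
    qo_stop("assignments must be a named vector (names = item ids)")
  }
  if (anyDuplicated(ids)) {
    qo_stop("duplicate item ids in assignments: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.character(assignments)
  if (any(is.na(vals))) {
    qo_stop("missing label for item(s): ",
            paste(ids[is.na(vals)], collapse = ", "))
  }
  names(vals) <- ids
  structure(list(assignments = vals, method = method,
                 k = length(unique(vals))),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  cat(sprintf("<clustering> method '%s': %d items in %d clusters\n",
              x$method, length(x$assignments), x$k))
  invisible(x)
}

#' Number of clusters used by an expert consensus
#'
#' The k handed to the k-means arm is tied to the expert-based analysis: it is
#' the number of distinct symptom labels the consensus actually used on the
#' analyzed item subset, NOT the catalog size. Stratifying by rating type can
#' reduce this number (some symptoms may have no items left in a stratum).
#'
#' @param consensus a [clustering()] with `method = "expert"`.
#' @return integer count of distinct labels used.
#' @export
expert_k <- function(consensus) {
  stopifnot(inherits(consensus, "clustering"))
  if (consensus$method != "expert") {
    qo_stop("expert_k expects a clustering with method 'expert', got '",
            consensus$method, "'")
  }
  consensus$k
}

# n x k matrix of squared Euclidean distances between rows of x and centers
sq_dist <- function(x, centers) {
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  d[d < 0] <- 0 # numeric noise
  d
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- sq_dist(x, x[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        # remaining mass degenerate: fall back to uniform over unused points
        pool <- setdiff(seq_len(n), idx[seq_len(j - 1)])
        idx[j] <- if (length(pool) == 1) pool else sample(pool, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, sq_dist(x, x[idx[j], , drop = FALSE])[, 1])
    }
  }
  x[idx, , drop = FALSE]
}

# Lloyd iterations with deterministic empty-cluster repair: an empty cluster
# is re-seeded with the point farthest from its current center.
lloyd <- function(x, centers, max_iter) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_prev <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d <- sq_dist(x, centers)
    assign <- max.col(-d, ties.method = "first")
    # repair empty clusters before the center update
    empty <- setdiff(seq_len(k), unique(assign))
    for (e in empty) {
      far <- which.max(d[cbind(seq_len(n), assign)])
      assign[far] <- e
      d[far, ] <- -Inf # a singleton; keep it out of later repairs this pass
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    centers <- rowsum(x, assign) / tabulate(assign, nbins = k)
  }
  d <- sq_dist(x, centers)
  wss <- sum(d[cbind(seq_len(n), assign)])
  list(cluster = assign, centers = centers, tot_withinss = wss)
}

#' k-means clustering of an embedding matrix
#'
#' Runs `n_init` independent k-means++-seeded Lloyd fits and keeps the one
#' with the smallest total within-cluster sum of squares. Deterministic given
#' `seed`. Labels are `0 .. k-1`.
#'
#' @param E an [embedding_matrix()] (or plain numeric matrix with item-id
#'   rownames).
#' @param k number of clusters, `1 <= k <= nrow(E)`; in the pipeline k comes
#'   from [expert_k()].
#' @param seed integer RNG seed.
#' @param n_init number of random restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return a [clustering()] with `method = "kmeans"`; attribute
#'   `tot_withinss` carries the winning within-cluster SS.
#' @export
kmeans_cluster <- function(E, k, seed = 1L, n_init = 10L, max_iter = 300L) {
  x <- unclass(E)
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1) qo_stop("k must be >= 1, got ", k)
  if (k > n) qo_stop("k = ", k, " exceeds the number of items (", n, ")")
  ids <- rownames(x)
  if (is.null(ids)) qo_stop("embedding matrix has no item-id rownames")
  if (k > 1 && all(sq_dist(x, x[1, , drop = FALSE]) == 0)) {
    qo_stop("degenerate input: all embedding rows identical but k = ", k)
  }
  best <- NULL
  seeds <- derive_seeds(seed, n_init)
  for (i in seq_len(n_init)) {
    fit <- withr::with_seed(seeds[i], {
      centers <- kmeanspp_centers(x, k)
      lloyd(x, centers, max_iter)
    })
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  labels <- as.character(best$cluster - 1L)
  names(labels) <- ids
  out <- clustering(labels, method = "kmeans")
  attr(out, "tot_withinss") <- best$tot_withinss
  out
}

#' Write / read a clustering as CSV
#'
#' Columns `item_id`, `label`, `method`, `run_id`; rows ordered by `item_id`
#' so re-export is deterministic.
#'
#' @param cl a [clustering()].
#' @param path output path.
#' @param run_id free-text run identifier stored alongside each row.
#' @export
write_clustering <- function(cl, path, run_id = "") {
  stopifnot(inherits(cl, "clustering"))
  ids <- sort(names(cl$assignments))
  df <- data.frame(item_id = ids, label = unname(cl$assignments[ids]),
                   method = cl$method, run_id = run_id,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_clustering
#' @param method expected method of the stored clustering; the file's own
#'   method column is used when `NULL`.
#' @export
read_clustering <- function(path, method = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("item_id", "label")
  if (!all(req %in% names(df))) {
    qo_stop("clustering file ", path, " must have columns item_id, label")
  }
  if (is.null(method)) {
    method <- if ("method" %in% names(df)) df$method[1] else "expert"
  }
  a <- as.character(df$label)
  names(a) <- as.character(df$item_id)
  clustering(a, method = method)
}
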