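# Embedding matrices and backends.
#
# An embedding matrix holds one fixed-length numeric vector per analyzed
# item, row-aligned to the item ids. Backends are pluggable: the shipped ones
# are "precomputed" (a TSV on disk) and "planted" (synthetic Gaussian
# components around known symptom clusters); a real sentence-transformer is a
# drop-in realization of the same contract but is deliberately not a
# dependency.

#' Construct an embedding matrix
#'
#' @param values numeric matrix, one row per item.
#' @param item_ids character vector of item ids, one per row, in order.
#' @return object of class `embedding_matrix`: the matrix with item ids as
#'   rownames. All entries must be finite and the dimension at least 2.
#' @export
embedding_matrix <- function(values, item_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(item_ids)) qo_stop("item_ids are required")
  if (length(item_ids) != nrow(values)) {
    qo_stop("item_ids length (", length(item_ids),
            ") does not match row count (", nrow(values), ")")
  }
  if (anyDuplicated(item_ids)) qo_stop("duplicate item ids in embedding")
  if (ncol(values) < 2) qo_stop("embedding dimension must be >= 2")
  if (!all(is.finite(values))) {
    bad <- unique(item_ids[!apply(is.finite(values), 1, all)])
    qo_stop("non-finite embedding values for item(s): ",
            paste(bad, collapse = ", "))
  }
  rownames(values) <- as.character(item_ids)
  structure(values, class = c("embedding_matrix", "matrix"))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> %d items x %d dims\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Define an embedding backend
#'
#' @param name backend name.
#' @param fn function `(items)` taking the analyzed-items data.frame (columns
#'   `item_id`, `text`, ...) and returning a numeric matrix with one row per
#'   input row.
#' @param deterministic must the backend return bit-identical vectors for
#'   identical inputs and configuration?
#' @return object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, fn, deterministic = TRUE) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn, deterministic = deterministic),
            class = "embedding_backend")
}

#' Embed the analyzed items of a bank
#'
#' Only non-excluded items are embedded, in bank order. Rows are
#' L2-normalized by default so that Euclidean k-means on them approximates
#' cosine similarity — the conventional metric for sentence embeddings.
#'
#' @param bank an [item_bank()].
#' @param backend an [embedding_backend()].
#' @param normalize L2-normalize rows (default `TRUE`).
#' @return an [embedding_matrix()], rows aligned to the analyzed items.
#' @export
embed_items <- function(bank, backend, normalize = TRUE) {
  stopifnot(inherits(bank, "item_bank"), inherits(backend, "embedding_backend"))
  items <- analyzed_items(bank)
  vals <- tryCatch(backend$fn(items), error = function(e) {
    qo_stop("embedding backend '", backend$name, "' failed: ",
            conditionMessage(e))
  })
  vals <- as.matrix(vals)
  if (nrow(vals) != nrow(items)) {
    qo_stop("backend '", backend$name, "' returned ", nrow(vals),
            " rows for ", nrow(items), " items")
  }
  if (!all(is.finite(vals))) {
    bad <- items$item_id[!apply(is.finite(vals), 1, all)]
    qo_stop("backend '", backend$name, "' produced non-finite values for: ",
            paste(bad, collapse = ", "))
  }
  if (normalize) vals <- l2_normalize_rows(vals)
  embedding_matrix(vals, items$item_id)
}

#' Load precomputed embeddings from a TSV
#'
#' File layout: header row `item_id v1 ... vD`, tab-separated, UTF-8. The file
#' may list rows in any order but must cover exactly the bank's non-excluded
#' item ids; the returned matrix is re-aligned to bank order.
#'
#' @param path TSV path.
#' @param bank an [item_bank()] giving the required ids and their order.
#' @return an [embedding_matrix()].
#' @export
load_embeddings <- function(path, bank) {
  stopifnot(inherits(bank, "item_bank"))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          encoding = "UTF-8", colClasses = NA)
  if (!"item_id" %in% names(df)) {
    qo_stop("embedding file ", path, " lacks an item_id column")
  }
  ids <- as.character(df$item_id)
  vals <- df[, setdiff(names(df), "item_id"), drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      qo_stop("non-numeric embedding value in ", path, " at row ", bad_row,
              ", column ", names(vals)[j])
    }
  }
  vals <- as.matrix(vals)
  want <- analyzed_items(bank)$item_id
  missing <- setdiff(want, ids)
  extra <- setdiff(ids, want)
  if (length(missing) || length(extra)) {
    qo_stop("embedding file does not match the bank's analyzed items.",
            if (length(missing)) paste0(" Missing: ",
                                        paste(missing, collapse = ", ")),
            if (length(extra)) paste0(" Extra: ",
                                      paste(extra, collapse = ", ")))
  }
  embedding_matrix(vals[match(want, ids), , drop = FALSE], want)
}

#' Write embeddings as TSV (inverse of [load_embeddings()])
#' @param E an [embedding_matrix()].
#' @param path output path.
#' @export
write_embeddings <- function(E, path) {
  stopifnot(inherits(E, "embedding_matrix"))
  df <- data.frame(item_id = rownames(E), unclass(E),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("item_id", paste0("v", seq_len(ncol(E))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Randomly permute which embedding vector belongs to which item
#'
#' This is the manipulation behind the permutation null: the multiset of
#' vectors is unchanged, but each vector is reattached to a uniformly random
#' item, destroying any relation between item content and position in the
#' embedding space. The item-id list itself is untouched.
#'
#' @param E an [embedding_matrix()].
#' @param seed integer seed; the permutation is reproducible given the seed.
#' @return an [embedding_matrix()] with the same ids and permuted rows.
#' @export
permute_embeddings <- function(E, seed) {
  stopifnot(inherits(E, "embedding_matrix"))
  ids <- rownames(E)
  perm <- withr::with_seed(as.integer(seed), sample.int(nrow(E)))
  embedding_matrix(unclass(E)[perm, , drop = FALSE], ids)
}
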