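# Synthetic planted-partition generator.
#
# Real questionnaire texts are copyrighted and cannot ship with the package,
# so every pipeline stage is exercised on generated data with the same
# statistical structure the analysis assumes: items grouped into latent
# symptom clusters, embeddings drawn from separated Gaussian components,
# three raters whose labels are the truth corrupted at a controllable error
# rate, and questionnaires that sample overlapping symptom subsets.
#
# Defaults mirror the adult-depression domain (7 questionnaires, ~180 items,
# 23 symptoms) and an embedding dimensionality of 768.

#' Synthetic-domain configuration
#'
#' @param n_questionnaires number of questionnaires (default 7).
#' @param items_per_questionnaire length-2 range of items per questionnaire
#'   (default `c(10, 40)`, drawn uniformly).
#' @param n_symptoms catalog size (default 23).
#' @param symptom_overlap rho in \[0, 1\]: per pool slot, the probability of
#'   drawing from the shared core symptoms rather than the peripheral
#'   (less-common) symptoms. Higher rho means more shared content (default
#'   0.6).
#' @param embedding_dim planted embedding dimension (default 768).
#' @param separation center distance between symptom components in units of
#'   the component sd (default 4).
#' @param rater_error epsilon in \[0, 1\]: per item, the probability a rater
#'   replaces the true label with a uniformly random different catalog label
#'   (default 0.1).
#' @param seed master seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_questionnaires = 7L,
                             items_per_questionnaire = c(10L, 40L),
                             n_symptoms = 23L,
                             symptom_overlap = 0.6,
                             embedding_dim = 768L,
                             separation = 4,
                             rater_error = 0.1,
                             seed = 1L) {
  stopifnot(n_questionnaires >= 1, length(items_per_questionnaire) == 2,
            all(items_per_questionnaire >= 1),
            items_per_questionnaire[1] <= items_per_questionnaire[2],
            symptom_overlap >= 0, symptom_overlap <= 1,
            embedding_dim >= 2, separation >= 0,
            rater_error >= 0, rater_error <= 1)
  if (n_symptoms < 2) qo_stop("n_symptoms must be >= 2")
  structure(list(n_questionnaires = as.integer(n_questionnaires),
                 items_per_questionnaire = as.integer(items_per_questionnaire),
                 n_symptoms = as.integer(n_symptoms),
                 symptom_overlap = symptom_overlap,
                 embedding_dim = as.integer(embedding_dim),
                 separation = separation,
                 rater_error = rater_error,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic diagnostic domain
#'
#' Each questionnaire draws a symptom pool: roughly a third of the catalog is
#' designated "core" (shared by all questionnaires) and each pool slot comes
#' from the core with probability `symptom_overlap`, otherwise from the
#' questionnaire's PRIVATE slice of the remaining symptoms — so the overlap
#' parameter alone controls how much content questionnaires share. Every pool
#' symptom receives at least one item (so profiles are determined by pools
#' whenever the item budget allows); remaining items sample the pool
#' uniformly. Item texts are templated variants of their symptom label. Each
#' questionnaire is SR, OR or dual-mode (SR+OR), and with small probability
#' carries one excluded assessment-quality item, exercising the exclusion
#' flag.
#'
#' @param config a [synthetic_config()].
#' @return list with `bank` (an [item_bank()]), `catalog` (a
#'   [symptom_catalog()]), and `truth` (a [clustering()] with
#'   `method = "truth"` covering exactly the non-excluded items).
#' @export
generate_synthetic_domain <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    ns <- config$n_symptoms
    symptoms <- sprintf("symptom %02d", seq_len(ns))
    n_core <- max(2L, ceiling(ns / 3))
    core <- symptoms[seq_len(n_core)]
    peripheral <- symptoms[-seq_len(n_core)]
    # non-core symptoms are PRIVATE to one questionnaire (round-robin
    # slices), so the overlap parameter alone controls shared content
    private <- lapply(seq_len(config$n_questionnaires), function(q) {
      if (length(peripheral) == 0) return(character(0))
      peripheral[seq_len(length(peripheral)) %% config$n_questionnaires ==
                   (q - 1L)]
    })

    rows <- list()
    truth <- character(0)
    for (q in seq_len(config$n_questionnaires)) {
      qid <- sprintf("Q%02d", q)
      n_items <- sample(seq(config$items_per_questionnaire[1],
                            config$items_per_questionnaire[2]), 1)
      pool_max <- min(ns, 12L, n_items)
      pool_min <- min(5L, pool_max)
      pool_size <- if (pool_min == pool_max) pool_min else
        sample(seq(pool_min, pool_max), 1)
      from_core <- stats::runif(pool_size) < config$symptom_overlap
      n_c <- min(sum(from_core), length(core))
      n_p <- min(pool_size - sum(from_core), length(private[[q]]))
      pool <- unique(c(
        if (n_c > 0) sample(core, n_c),
        if (n_p > 0) sample(private[[q]], n_p)))
      if (length(pool) == 0) pool <- sample(core, 1)
      # cover the pool, then fill uniformly
      labels <- c(pool, if (n_items > length(pool))
        sample(pool, n_items - length(pool), replace = TRUE))
      labels <- sample(labels) # shuffle item order
      rating <- sample(c("SR", "OR", "SR+OR"), 1, prob = c(0.7, 0.2, 0.1))
      variant <- stats::ave(seq_along(labels), labels, FUN = seq_along)
      df <- data.frame(
        item_id = paste0(qid, ":", seq_along(labels)),
        questionnaire_id = qid,
        text = paste0(labels, " phrased variant ", variant),
        rating_type = rating,
        excluded = FALSE,
        stringsAsFactors = FALSE
      )
      if (stats::runif(1) < 0.15) {
        df <- rbind(df, data.frame(
          item_id = paste0(qid, ":", nrow(df) + 1L),
          questionnaire_id = qid,
          text = "these answers represent my honest responses",
          rating_type = rating, excluded = TRUE,
          stringsAsFactors = FALSE))
      }
      rows[[q]] <- df
      truth[df$item_id[!df$excluded]] <- labels
    }
    items <- do.call(rbind, rows)
    bank <- item_bank(items, domain = "synthetic domain")
    list(bank = bank,
         catalog = symptom_catalog(symptoms, domain = "synthetic domain"),
         truth = clustering(truth, method = "truth"))
  })
}

#' Planted Gaussian embeddings around the true symptom clusters
#'
#' One unit-variance isotropic Gaussian component per true symptom; the
#' component centers sit on mutually orthogonal directions scaled so every
#' pair of centers is at distance `separation` (in units of the component
#' sd). Rows are L2-normalized, matching what [embed_items()] does to real
#' embeddings. With `separation = 0` all components coincide and the rows
#' are indistinguishable from a single Gaussian.
#'
#' @param truth a [clustering()] (`method = "truth"`).
#' @param dim embedding dimension; must be >= the number of distinct true
#'   symptoms (orthogonal center placement needs one axis per component).
#' @param separation center distance in units of the component sd (>= 0).
#' @param seed integer seed.
#' @return an [embedding_matrix()] row-aligned to the truth's item ids.
#' @export
generate_planted_embeddings <- function(truth, dim = 768L, separation = 4,
                                        seed = 1L) {
  stopifnot(inherits(truth, "clustering"))
  dim <- as.integer(dim)
  if (dim < 2) qo_stop("embedding dim must be >= 2")
  labels <- unique(unname(truth$assignments))
  k <- length(labels)
  if (k > dim) {
    qo_stop("cannot place ", k, " orthogonal cluster centers in ", dim,
            " dimensions; use dim >= ", k)
  }
  ids <- names(truth$assignments)
  withr::with_seed(as.integer(seed), {
    basis <- qr.Q(qr(matrix(stats::rnorm(dim * k), dim, k)))
    centers <- t(basis) * separation / sqrt(2) # pairwise distance = separation
    li <- match(unname(truth$assignments), labels)
    x <- centers[li, , drop = FALSE] +
      matrix(stats::rnorm(length(ids) * dim), length(ids), dim)
    embedding_matrix(l2_normalize_rows(x), ids)
  })
}

#' Planted embedding backend
#'
#' An [embedding_backend()] that serves rows of a pre-generated planted
#' matrix by item id — the synthetic stand-in for a sentence-transformer.
#'
#' @inheritParams generate_planted_embeddings
#' @return an [embedding_backend()] named `"planted"`.
#' @export
planted_backend <- function(truth, dim = 768L, separation = 4, seed = 1L) {
  E <- generate_planted_embeddings(truth, dim = dim, separation = separation,
                                   seed = seed)
  embedding_backend("planted", function(items) {
    miss <- setdiff(items$item_id, rownames(E))
    if (length(miss)) {
      stop("planted backend has no vectors for: ",
           paste(miss, collapse = ", "))
    }
    unclass(E)[items$item_id, , drop = FALSE]
  }, deterministic = TRUE)
}

#' Noisy raters around the true labels
#'
#' Each rater independently keeps an item's true label with probability
#' `1 - error_rate`, otherwise substitutes a uniformly random DIFFERENT
#' catalog label (symmetric corruption, no confusion structure between
#' similar symptoms). Supply `confusion` to override the substitution draw.
#'
#' @param truth a [clustering()].
#' @param catalog a [symptom_catalog()] containing every truth label.
#' @param n_raters number of raters (default 3).
#' @param error_rate epsilon in \[0, 1\].
#' @param seed integer seed.
#' @param confusion optional function `(true_label, catalog)` returning a
#'   replacement label; defaults to uniform over the other catalog labels.
#' @return list of [rater_labeling()] objects.
#' @export
generate_noisy_raters <- function(truth, catalog, n_raters = 3L,
                                  error_rate = 0.1, seed = 1L,
                                  confusion = NULL) {
  stopifnot(inherits(truth, "clustering"), inherits(catalog, "symptom_catalog"),
            error_rate >= 0, error_rate <= 1)
  ids <- names(truth$assignments)
  if (is.null(confusion)) {
    confusion <- function(true_label, catalog) {
      others <- setdiff(catalog$symptoms, true_label)
      if (length(others) == 0) true_label else
        if (length(others) == 1) others else sample(others, 1)
    }
  }
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_raters), function(r) {
      flip <- stats::runif(length(ids)) < error_rate
      lab <- unname(truth$assignments)
      for (i in which(flip)) lab[i] <- confusion(lab[i], catalog)
      rater_labeling(sprintf("rater%02d", r),
                     stats::setNames(lab, ids), catalog)
    })
  })
}

#' Lookup assignment backend (synthetic stand-in for a prompted LLM)
#'
#' Answers each item with its true label, corrupted exactly as in
#' [generate_noisy_raters()]; with `malformed_rate > 0` a fraction of items
#' instead get an off-catalog response on every attempt, exercising the
#' validation/failure layer. Deterministic: the corruption pattern is fixed
#' at construction from `seed`.
#'
#' @param truth a [clustering()].
#' @param catalog a [symptom_catalog()]; defaults to the labels used in
#'   `truth`.
#' @param error_rate label-substitution probability.
#' @param malformed_rate probability an item's response is off-catalog
#'   garbage.
#' @param seed integer seed.
#' @return an [assignment_backend()] named `"lookup"`.
#' @export
make_lookup_backend <- function(truth, catalog = NULL, error_rate = 0,
                                malformed_rate = 0, seed = 1L) {
  stopifnot(inherits(truth, "clustering"),
            error_rate >= 0, error_rate <= 1,
            malformed_rate >= 0, malformed_rate <= 1)
  if (is.null(catalog)) {
    catalog <- symptom_catalog(unique(unname(truth$assignments)))
  }
  ids <- names(truth$assignments)
  responses <- withr::with_seed(as.integer(seed), {
    out <- unname(truth$assignments)
    flip <- stats::runif(length(ids)) < error_rate
    for (i in which(flip)) {
      others <- setdiff(catalog$symptoms, out[i])
      out[i] <- if (length(others) == 0) out[i] else
        if (length(others) == 1) others else sample(others, 1)
    }
    malformed <- stats::runif(length(ids)) < malformed_rate
    out[malformed] <- paste0("@@malformed response ", which(malformed), "@@")
    stats::setNames(out, ids)
  })
  assignment_backend("lookup", function(item_id, prompt, attempt) {
    if (!item_id %in% names(responses)) {
      stop("lookup backend has no entry for item ", item_id)
    }
    responses[[item_id]]
  }, deterministic = TRUE)
}
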