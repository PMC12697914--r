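# Content overlap between questionnaires (Fried-style): per-questionnaire
# symptom profiles (the SET of symptoms a questionnaire's items cover),
# pairwise Jaccard indices, per-questionnaire and domain means, and the
# occurrence structure (which symptom appears in which questionnaire,
# universal vs idiosyncratic symptoms).

#' Symptom profile of one questionnaire
#'
#' The set of distinct symptom labels assigned to the questionnaire's
#' non-excluded items under a given clustering.
#'
#' @param cl a [clustering()] covering the questionnaire's analyzed items.
#' @param bank an [item_bank()].
#' @param questionnaire_id questionnaire key.
#' @return character vector of distinct symptom labels (first-seen order).
#' @export
symptom_profile <- function(cl, bank, questionnaire_id) {
  stopifnot(inherits(cl, "clustering"), inherits(bank, "item_bank"))
  if (!questionnaire_id %in% bank$questionnaires$questionnaire_id) {
    qo_stop("unknown questionnaire: ", questionnaire_id)
  }
  items <- analyzed_items(bank)
  ids <- items$item_id[items$questionnaire_id == questionnaire_id]
  miss <- setdiff(ids, names(cl$assignments))
  if (length(miss)) {
    qo_stop("clustering does not cover item(s) of ", questionnaire_id, ": ",
            paste(miss, collapse = ", "))
  }
  unique(unname(cl$assignments[ids]))
}

#' Jaccard index of two symptom sets
#'
#' \eqn{J(A, B) = |A \cap B| / |A \cup B|}, in \eqn{[0, 1]}: 0 for disjoint
#' sets (no overlap), 1 for identical sets (complete overlap). Inputs are
#' deduplicated; an empty input is an error (a questionnaire with no symptoms
#' signals an upstream pipeline bug).
#'
#' @param a,b character vectors treated as sets.
#' @return the Jaccard index.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    qo_stop("jaccard_index: empty symptom set")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Pairwise content-overlap report for one domain
#'
#' For every pair of questionnaires the Jaccard index of their symptom
#' profiles, plus per-questionnaire means (off-diagonal row means), the
#' domain mean (over the C(Q,2) unordered pairs), and the occurrence
#' structure from [occurrence_matrix()].
#'
#' @param cl a [clustering()] (by default the prompted-assignment arm, per
#'   the headline analysis; any arm works).
#' @param bank an [item_bank()] with >= 2 questionnaires.
#' @return object of class `overlap_report`: `questionnaire_ids`, `jaccard`
#'   (symmetric matrix, unit diagonal), `per_questionnaire_mean`,
#'   `domain_mean`, `occurrence`, `universal_symptoms`,
#'   `idiosyncratic_symptoms` (named character: symptom -> its single
#'   questionnaire).
#' @export
overlap_matrix <- function(cl, bank) {
  stopifnot(inherits(cl, "clustering"), inherits(bank, "item_bank"))
  qids <- bank$questionnaires$questionnaire_id
  if (length(qids) < 2) {
    qo_stop("overlap needs >= 2 questionnaires, bank has ", length(qids))
  }
  profiles <- lapply(qids, symptom_profile, cl = cl, bank = bank)
  names(profiles) <- qids
  q <- length(qids)
  jac <- matrix(1, q, q, dimnames = list(qids, qids))
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      jac[i, j] <- jac[j, i] <- jaccard_index(profiles[[i]], profiles[[j]])
    }
  }
  per_q <- stats::setNames(vapply(seq_len(q), function(i) {
    mean(jac[i, -i])
  }, numeric(1)), qids)
  occ <- occurrence_matrix(cl, bank)
  structure(list(
    questionnaire_ids = qids,
    jaccard = jac,
    per_questionnaire_mean = per_q,
    domain_mean = mean(jac[upper.tri(jac)]),
    occurrence = occ$occurrence,
    universal_symptoms = occ$universal,
    idiosyncratic_symptoms = occ$idiosyncratic,
    profiles = profiles
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %d questionnaires, domain mean Jaccard %.3f (%s)\n",
    length(x$questionnaire_ids), x$domain_mean,
    strength_band(x$domain_mean)))
  cat(sprintf("  universal symptoms: %d, idiosyncratic: %d\n",
              length(x$universal_symptoms), length(x$idiosyncratic_symptoms)))
  invisible(x)
}

#' Symptom-by-questionnaire occurrence structure
#'
#' The symptom universe is the set of labels the clustering actually uses
#' (not the full catalog: symptoms no arm found stay out of the table).
#'
#' @param cl a [clustering()].
#' @param bank an [item_bank()].
#' @return list with `occurrence` (logical symptom x questionnaire matrix),
#'   `universal` (symptoms present in every questionnaire) and
#'   `idiosyncratic` (named character: symptoms present in exactly one
#'   questionnaire, mapped to it).
#' @export
occurrence_matrix <- function(cl, bank) {
  stopifnot(inherits(cl, "clustering"), inherits(bank, "item_bank"))
  qids <- bank$questionnaires$questionnaire_id
  profiles <- lapply(qids, symptom_profile, cl = cl, bank = bank)
  symptoms <- unique(unlist(profiles))
  occ <- matrix(FALSE, length(symptoms), length(qids),
                dimnames = list(symptoms, qids))
  for (j in seq_along(qids)) occ[profiles[[j]], j] <- TRUE
  counts <- rowSums(occ)
  idio <- which(counts == 1)
  idiosyncratic <- if (length(idio)) {
    stats::setNames(
      qids[vapply(idio, function(i) which(occ[i, ]), integer(1))],
      symptoms[idio])
  } else {
    stats::setNames(character(0), character(0))
  }
  list(occurrence = occ,
       universal = symptoms[counts == length(qids)],
       idiosyncratic = idiosyncratic)
}
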