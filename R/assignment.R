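# The expert arm (three independent raters plus majority consensus and
# discussion-based adjudication) and the prompted-assignment arm (an
# LLM-style backend answering with a symptom label, validated against the
# catalog by the pipeline, never trusted).

#' Construct a rater labeling
#'
#' @param rater_id rater identifier.
#' @param assignments named character vector: item id -> symptom label.
#' @param catalog a [symptom_catalog()]; every label must be a member (after
#'   normalization).
#' @return object of class `rater_labeling`.
#' @export
rater_labeling <- function(rater_id, assignments, catalog) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  ids <- names(assignments)
  if (is.null(ids)) qo_stop("assignments must be named by item id")
  vals <- as.character(assignments)
  m <- match(normalize_label(vals), normalize_label(catalog$symptoms))
  if (anyNA(m)) {
    qo_stop("rater '", rater_id, "' used off-catalog label(s): ",
            paste(unique(vals[is.na(m)]), collapse = ", "))
  }
  vals <- catalog$symptoms[m] # canonical spelling
  names(vals) <- ids
  structure(list(rater_id = as.character(rater_id), assignments = vals),
            class = "rater_labeling")
}

#' Read rater labelings from CSV
#'
#' Columns: `rater_id`, `item_id`, `symptom`. One [rater_labeling()] is built
#' per distinct rater id.
#'
#' @param path CSV path.
#' @param catalog a [symptom_catalog()].
#' @return named list of [rater_labeling()] objects.
#' @export
read_rater_labelings <- function(path, catalog) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("rater_id", "item_id", "symptom")
  if (!all(req %in% names(df))) {
    qo_stop("rater file ", path, " must have columns ",
            paste(req, collapse = ", "))
  }
  out <- lapply(split(df, df$rater_id), function(d) {
    a <- as.character(d$symptom)
    names(a) <- as.character(d$item_id)
    rater_labeling(d$rater_id[1], a, catalog)
  })
  out[order(names(out))]
}

#' Write rater labelings to CSV (inverse of [read_rater_labelings()])
#' @param labelings list of [rater_labeling()].
#' @param path output path.
#' @export
write_rater_labelings <- function(labelings, path) {
  rows <- do.call(rbind, lapply(labelings, function(l) {
    data.frame(rater_id = l$rater_id, item_id = names(l$assignments),
               symptom = unname(l$assignments), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Render the assignment prompt for one item
#'
#' Deterministic substitution of `{item_text}` and `{symptom_list}` into a
#' template; the symptom list is rendered one label per line in catalog
#' order.
#'
#' @param item one-row data.frame (or list) with a `text` field.
#' @param catalog a [symptom_catalog()].
#' @param template prompt template containing both placeholders.
#' @return the rendered prompt text.
#' @export
render_prompt <- function(item, catalog,
                          template = default_prompt_template()) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  for (ph in c("{item_text}", "{symptom_list}")) {
    if (!grepl(ph, template, fixed = TRUE)) {
      qo_stop("prompt template lacks required placeholder ", ph)
    }
  }
  out <- gsub("{item_text}", item$text, template, fixed = TRUE)
  gsub("{symptom_list}", paste(catalog$symptoms, collapse = "\n"), out,
       fixed = TRUE)
}

#' Default assignment prompt template
#' @return template text with `{item_text}` and `{symptom_list}`
#'   placeholders.
#' @export
default_prompt_template <- function() {
  paste0("You are given one questionnaire item and a list of symptoms. ",
         "Reply with exactly one symptom from the list that best matches ",
         "the item.\nItem: {item_text}\nSymptoms:\n{symptom_list}")
}

#' Define an assignment backend
#'
#' @param name backend name (a concrete API backend should record the pinned
#'   model identifier here).
#' @param fn function `(item_id, prompt, attempt)` returning a single
#'   response string. The pipeline, not the backend, enforces catalog
#'   membership.
#' @param deterministic logical.
#' @return object of class `assignment_backend`.
#' @export
assignment_backend <- function(name, fn, deterministic = TRUE) {
  stopifnot(is.function(fn))
  structure(list(name = name, fn = fn, deterministic = deterministic),
            class = "assignment_backend")
}

# Response validation: exact normalized match first, then unique
# case-insensitive substring. Never fuzzy distance - a silently wrong
# assignment is worse than a failure.
match_response <- function(response, catalog) {
  nrm <- normalize_label(response)
  cat_nrm <- normalize_label(catalog$symptoms)
  hit <- which(cat_nrm == nrm)
  if (length(hit) == 1) return(catalog$symptoms[hit])
  # strip trailing punctuation, retry exact
  hit <- which(cat_nrm == sub("[[:punct:]]+$", "", nrm))
  if (length(hit) == 1) return(catalog$symptoms[hit])
  sub_hit <- which(vapply(cat_nrm, grepl, logical(1), x = nrm, fixed = TRUE))
  if (length(sub_hit) == 1) return(catalog$symptoms[sub_hit])
  NA_character_
}

#' Assign items to symptoms through a prompted backend
#'
#' Each analyzed item is rendered into a prompt and sent to the backend; the
#' raw response is validated against the catalog (exact normalized match,
#' then unique case-insensitive substring). Invalid responses are retried up
#' to `max_retries` further attempts and then reported as failures — a
#' non-empty failure set is a reported condition, not an exception.
#'
#' @param bank an [item_bank()].
#' @param catalog a [symptom_catalog()].
#' @param backend an [assignment_backend()].
#' @param max_retries additional attempts per item after the first (default
#'   2).
#' @param template prompt template, see [render_prompt()].
#' @param transcript_path optional JSONL path; one record per call
#'   (`item_id`, `prompt`, `response`, `label` or `failure`) for audit.
#' @return list with `clustering` (a [clustering()] with `method = "llm"`
#'   over the validated items) and `failures` (character vector of item ids).
#' @export
assign_items <- function(bank, catalog, backend, max_retries = 2L,
                         template = default_prompt_template(),
                         transcript_path = NULL) {
  stopifnot(inherits(bank, "item_bank"), inherits(catalog, "symptom_catalog"),
            inherits(backend, "assignment_backend"))
  items <- analyzed_items(bank)
  labels <- character(0)
  failures <- character(0)
  transcript <- if (is.null(transcript_path)) NULL else file(transcript_path,
                                                             open = "wt")
  on.exit(if (!is.null(transcript)) close(transcript), add = TRUE)
  for (i in seq_len(nrow(items))) {
    item <- items[i, ]
    prompt <- render_prompt(item, catalog, template)
    label <- NA_character_
    response <- NA_character_
    for (attempt in seq_len(max_retries + 1L)) {
      response <- tryCatch(
        as.character(backend$fn(item$item_id, prompt, attempt))[1],
        error = function(e) NA_character_)
      if (!is.na(response)) label <- match_response(response, catalog)
      if (!is.na(label)) break
    }
    if (is.na(label)) {
      failures <- c(failures, item$item_id)
    } else {
      labels[item$item_id] <- label
    }
    if (!is.null(transcript)) {
      rec <- list(item_id = item$item_id, prompt = prompt,
                  response = response)
      if (is.na(label)) rec$failure <- "no catalog match" else
        rec$label <- label
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 transcript)
    }
  }
  if (length(labels) == 0) {
    qo_stop("assignment backend '", backend$name,
            "' produced no valid label for any item")
  }
  list(clustering = clustering(labels, method = "llm"), failures = failures)
}

#' Majority consensus over exactly three rater labelings
#'
#' Per item, the label chosen by at least two of the three raters wins; items
#' on which all three raters disagree are returned as `unresolved` for
#' discussion-based adjudication ([apply_adjudication()]). The result is
#' symmetric in rater order.
#'
#' @param labelings list of exactly 3 [rater_labeling()] covering the same
#'   item set.
#' @param catalog a [symptom_catalog()].
#' @return object of class `consensus_result`: `clustering` (method
#'   `"expert"`, resolved items only) and `unresolved` (item ids).
#' @export
consensus_labeling <- function(labelings, catalog) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  if (length(labelings) != 3 ||
      !all(vapply(labelings, inherits, logical(1), "rater_labeling"))) {
    qo_stop("consensus_labeling requires exactly 3 rater labelings")
  }
  id_sets <- lapply(labelings, function(l) sort(names(l$assignments)))
  for (j in 2:3) {
    d <- c(setdiff(id_sets[[1]], id_sets[[j]]),
           setdiff(id_sets[[j]], id_sets[[1]]))
    if (length(d)) {
      qo_stop("raters '", labelings[[1]]$rater_id, "' and '",
              labelings[[j]]$rater_id, "' cover different items: ",
              paste(d, collapse = ", "))
    }
  }
  ids <- id_sets[[1]]
  lab <- vapply(labelings, function(l) l$assignments[ids], character(length(ids)))
  if (length(ids) == 1) lab <- matrix(lab, nrow = 1)
  consensus <- character(0)
  unresolved <- character(0)
  for (i in seq_along(ids)) {
    tab <- table(lab[i, ])
    if (max(tab) >= 2) {
      consensus[ids[i]] <- names(tab)[which.max(tab)]
    } else {
      unresolved <- c(unresolved, ids[i])
    }
  }
  cl <- if (length(consensus)) clustering(consensus, method = "expert") else NULL
  structure(list(clustering = cl, unresolved = unresolved),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  n_res <- if (is.null(x$clustering)) 0 else length(x$clustering$assignments)
  cat(sprintf("<consensus_result> %d resolved, %d unresolved\n",
              n_res, length(x$unresolved)))
  invisible(x)
}

#' Apply discussion-based adjudication to unresolved items
#'
#' @param result a `consensus_result` from [consensus_labeling()].
#' @param adjudication named character vector item id -> symptom; must cover
#'   every unresolved item with catalog labels.
#' @param catalog a [symptom_catalog()].
#' @return complete expert [clustering()].
#' @export
apply_adjudication <- function(result, adjudication, catalog) {
  stopifnot(inherits(result, "consensus_result"),
            inherits(catalog, "symptom_catalog"))
  adjudication <- if (length(adjudication)) {
    stats::setNames(as.character(adjudication), names(adjudication))
  } else character(0)
  uncovered <- setdiff(result$unresolved, names(adjudication))
  if (length(uncovered)) {
    qo_stop("unresolved item(s) without adjudication: ",
            paste(uncovered, collapse = ", "))
  }
  use <- adjudication[result$unresolved]
  if (length(use)) {
    m <- match(normalize_label(use), normalize_label(catalog$symptoms))
    if (anyNA(m)) {
      qo_stop("adjudication uses off-catalog label(s): ",
              paste(unique(use[is.na(m)]), collapse = ", "))
    }
    use <- stats::setNames(catalog$symptoms[m], names(use))
  }
  base <- if (is.null(result$clustering)) character(0) else
    result$clustering$assignments
  clustering(c(base, use), method = "expert")
}

#' Read an adjudication table (CSV columns `item_id`, `symptom`)
#' @param path CSV path.
#' @return named character vector item id -> symptom.
#' @export
read_adjudication <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("item_id", "symptom") %in% names(df))) {
    qo_stop("adjudication file ", path,
            " must have columns item_id, symptom")
  }
  stats::setNames(as.character(df$symptom), as.character(df$item_id))
}
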