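# Item banks and symptom catalogs: the tables every downstream stage consumes.
#
# An item bank holds the pooled items of all questionnaires of one diagnostic
# domain (e.g. adult depression) together with questionnaire metadata; a
# symptom catalog holds the ordered list of core-symptom labels for that
# domain.

RATING_TYPES <- c("SR", "OR", "SR+OR")

#' Construct a symptom catalog
#'
#' @param symptoms character vector of symptom labels, order preserved.
#' @param domain domain label (e.g. `"adult depression"`).
#' @return object of class `symptom_catalog` with fields `domain`, `symptoms`.
#' @details Labels must be unique after normalization
#'   ([normalize_label()]): `"Guilt"` and `"guilt "` collide.
#' @export
symptom_catalog <- function(symptoms, domain = "unspecified") {
  symptoms <- as.character(symptoms)
  symptoms <- symptoms[!is.na(symptoms) & nzchar(trimws(symptoms))]
  if (length(symptoms) == 0) {
    qo_stop("symptom catalog is empty")
  }
  nrm <- normalize_label(symptoms)
  if (anyDuplicated(nrm)) {
    dup <- unique(symptoms[duplicated(nrm) | duplicated(nrm, fromLast = TRUE)])
    qo_stop("duplicate symptom labels after normalization: ",
            paste(dup, collapse = ", "))
  }
  structure(list(domain = domain, symptoms = symptoms),
            class = "symptom_catalog")
}

#' @export
print.symptom_catalog <- function(x, ...) {
  cat(sprintf("<symptom_catalog> domain '%s', %d symptoms\n",
              x$domain, length(x$symptoms)))
  invisible(x)
}

#' Construct an item bank
#'
#' @param items data.frame with columns `item_id`, `questionnaire_id`, `text`,
#'   `rating_type` (one of `"SR"`, `"OR"`, `"SR+OR"`), `excluded` (logical).
#'   Row order is the item order.
#' @param questionnaires data.frame with columns `questionnaire_id`, `name`,
#'   `rating_type`; derived from `items` when `NULL`.
#' @param domain domain label.
#' @return object of class `item_bank`.
#' @details Invariants enforced: unique `item_id`; non-empty text on every
#'   non-excluded item; every item's questionnaire present in the metadata;
#'   at least one non-excluded item.
#' @export
item_bank <- function(items, questionnaires = NULL, domain = "unspecified") {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  req <- c("item_id", "questionnaire_id", "text", "rating_type", "excluded")
  miss <- setdiff(req, names(items))
  if (length(miss)) {
    qo_stop("item table is missing column(s): ", paste(miss, collapse = ", "))
  }
  items$item_id <- as.character(items$item_id)
  items$questionnaire_id <- as.character(items$questionnaire_id)
  items$text <- as.character(items$text)
  items$rating_type <- toupper(gsub("\\s", "", items$rating_type))
  items$rating_type <- sub("^SR,OR$|^OR,SR$|^OR\\+SR$", "SR+OR",
                           items$rating_type)
  items$excluded <- as.logical(items$excluded)
  if (nrow(items) == 0) qo_stop("item table is empty")
  if (anyDuplicated(items$item_id)) {
    dup <- unique(items$item_id[duplicated(items$item_id)])
    qo_stop("duplicate item_id: ", paste(dup, collapse = ", "))
  }
  bad_rt <- !items$rating_type %in% RATING_TYPES
  if (any(bad_rt)) {
    qo_stop("invalid rating_type in row(s) ",
            paste(which(bad_rt), collapse = ", "),
            " (expected SR, OR or SR+OR)")
  }
  bad_text <- !items$excluded & !nzchar(trimws(items$text))
  if (any(bad_text)) {
    qo_stop("empty text on non-excluded item(s): ",
            paste(items$item_id[bad_text], collapse = ", "))
  }
  if (!any(!items$excluded)) qo_stop("item bank has no non-excluded items")

  if (is.null(questionnaires)) {
    qids <- unique(items$questionnaire_id)
    questionnaires <- data.frame(
      questionnaire_id = qids,
      name = qids,
      rating_type = vapply(qids, function(q) {
        rts <- unique(items$rating_type[items$questionnaire_id == q])
        if (length(rts) == 1) rts else "SR+OR"
      }, character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    questionnaires <- as.data.frame(questionnaires, stringsAsFactors = FALSE)
    questionnaires$questionnaire_id <-
      as.character(questionnaires$questionnaire_id)
  }
  rownames(items) <- NULL
  rownames(questionnaires) <- NULL
  orphan <- setdiff(items$questionnaire_id, questionnaires$questionnaire_id)
  if (length(orphan)) {
    qo_stop("items reference unknown questionnaire(s): ",
            paste(orphan, collapse = ", "))
  }
  structure(list(domain = domain, items = items,
                 questionnaires = questionnaires),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf(
    "<item_bank> domain '%s': %d items (%d excluded), %d questionnaires\n",
    x$domain, nrow(x$items), sum(x$items$excluded),
    nrow(x$questionnaires)))
  invisible(x)
}

#' Non-excluded items of a bank
#' @param bank an [item_bank()].
#' @return data.frame of analyzed (non-excluded) items, bank order preserved.
#' @export
analyzed_items <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  bank$items[!bank$items$excluded, , drop = FALSE]
}

read_table_any <- function(path, format) {
  sep <- switch(format, csv = ",", tsv = "\t",
                qo_stop("unsupported table format: ", format))
  if (!file.exists(path)) qo_stop("file not found: ", path)
  if (file.size(path) == 0) qo_stop("empty file: ", path)
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    encoding = "UTF-8", check.names = TRUE)
}

#' Read an item bank from disk
#'
#' Expected columns: `domain`, `questionnaire_id`, `questionnaire_name`,
#' `item_id`, `text`, `rating_type` (`SR` | `OR` | `SR+OR`, `"SR, OR"` also
#' accepted), `excluded` (0/1). `item_id` may be absent or blank; ids are then
#' generated as `"<questionnaire_id>:<ordinal>"` with 1-based ordinals in row
#' order. UTF-8, header row required. JSON input is an array of objects with
#' the same keys.
#'
#' @param path file path.
#' @param format `"csv"`, `"tsv"` or `"json"`; guessed from the extension by
#'   default.
#' @return an [item_bank()]; row order preserved as item order.
#' @export
read_item_bank <- function(path, format = guess_format(path)) {
  if (format == "json") {
    df <- as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    df <- read_table_any(path, format)
  }
  req <- c("domain", "questionnaire_id", "text", "rating_type", "excluded")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    qo_stop("item bank file ", path, " is missing column(s): ",
            paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) qo_stop("item bank file ", path, " has no rows")
  if (is.null(df$item_id)) df$item_id <- NA_character_
  df$item_id <- as.character(df$item_id)
  blank <- is.na(df$item_id) | !nzchar(trimws(df$item_id))
  if (any(blank)) {
    ord <- stats::ave(seq_len(nrow(df)), df$questionnaire_id,
                      FUN = seq_along)
    df$item_id[blank] <- paste0(df$questionnaire_id[blank], ":", ord[blank])
  }
  if (anyDuplicated(df$item_id)) {
    rows <- which(duplicated(df$item_id))
    qo_stop("duplicate item_id in ", path, " at row(s) ",
            paste(rows, collapse = ", "), ": ",
            paste(unique(df$item_id[rows]), collapse = ", "))
  }
  if (is.null(df$questionnaire_name)) df$questionnaire_name <- df$questionnaire_id
  items <- df[, c("item_id", "questionnaire_id", "text", "rating_type",
                  "excluded")]
  items$excluded <- items$excluded %in% c(1, "1", TRUE, "TRUE", "true")
  qmeta <- unique(df[, c("questionnaire_id", "questionnaire_name")])
  questionnaires <- data.frame(
    questionnaire_id = as.character(qmeta$questionnaire_id),
    name = as.character(qmeta$questionnaire_name),
    rating_type = NA_character_,
    stringsAsFactors = FALSE
  )
  bank <- item_bank(items, questionnaires = NULL,
                    domain = as.character(df$domain[1]))
  # keep the file's questionnaire names, rating types derived from items
  m <- match(bank$questionnaires$questionnaire_id,
             questionnaires$questionnaire_id)
  bank$questionnaires$name <- questionnaires$name[m]
  bank
}

#' Write an item bank to CSV/TSV/JSON
#'
#' Inverse of [read_item_bank()]: `read(write(bank))` round-trips
#' field-by-field.
#'
#' @param bank an [item_bank()].
#' @param path output path.
#' @param format `"csv"`, `"tsv"` or `"json"`.
#' @export
write_item_bank <- function(bank, path, format = guess_format(path)) {
  stopifnot(inherits(bank, "item_bank"))
  m <- match(bank$items$questionnaire_id,
             bank$questionnaires$questionnaire_id)
  df <- data.frame(
    domain = bank$domain,
    questionnaire_id = bank$items$questionnaire_id,
    questionnaire_name = bank$questionnaires$name[m],
    item_id = bank$items$item_id,
    text = bank$items$text,
    rating_type = bank$items$rating_type,
    excluded = as.integer(bank$items$excluded),
    stringsAsFactors = FALSE
  )
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv", "json")) ext else "csv"
}

#' Read a symptom catalog
#'
#' Accepts a one-column CSV (header `symptom`, or any single-column header) or
#' a JSON array of strings.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @param domain domain label to attach.
#' @return a [symptom_catalog()] with unique, order-preserved labels.
#' @export
read_symptom_catalog <- function(path, format = guess_format(path),
                                 domain = "unspecified") {
  if (format == "json") {
    labels <- unlist(jsonlite::fromJSON(path, simplifyVector = TRUE))
  } else {
    if (!file.exists(path)) qo_stop("file not found: ", path)
    if (file.size(path) == 0) qo_stop("empty symptom catalog file: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (ncol(df) != 1) {
      qo_stop("symptom catalog must have exactly one column, found ",
              ncol(df))
    }
    labels <- df[[1]]
  }
  symptom_catalog(labels, domain = domain)
}

#' Write a symptom catalog to a one-column CSV
#' @param catalog a [symptom_catalog()].
#' @param path output path.
#' @export
write_symptom_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "symptom_catalog"))
  utils::write.csv(data.frame(symptom = catalog$symptoms), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter an item bank by rating type and exclusion flag
#'
#' Items tagged with both rating types (`"SR+OR"`) are retained in BOTH the
#' SR and the OR stratum: duplication is the only rule that cannot silently
#' drop items of dual-mode questionnaires. Questionnaires left with zero items
#' are removed from the metadata.
#'
#' @param bank an [item_bank()].
#' @param rating_type `"SR"`, `"OR"`, or `NULL` for no stratification.
#' @param drop_excluded drop items flagged as excluded (default `TRUE`).
#' @return a filtered [item_bank()].
#' @export
filter_items <- function(bank, rating_type = NULL, drop_excluded = TRUE) {
  stopifnot(inherits(bank, "item_bank"))
  items <- bank$items
  if (drop_excluded) items <- items[!items$excluded, , drop = FALSE]
  if (!is.null(rating_type)) {
    rating_type <- match.arg(rating_type, c("SR", "OR"))
    keep <- items$rating_type %in% c(rating_type, "SR+OR")
    items <- items[keep, , drop = FALSE]
  }
  if (nrow(items) == 0) {
    qo_stop("filter removed every item (rating_type = ",
            if (is.null(rating_type)) "none" else rating_type,
            ", drop_excluded = ", drop_excluded, ")",
            class = "qoverlap_empty_result")
  }
  qs <- bank$questionnaires[
    bank$questionnaires$questionnaire_id %in% items$questionnaire_id, ,
    drop = FALSE]
  item_bank(items, questionnaires = qs, domain = bank$domain)
}
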