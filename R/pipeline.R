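# End-to-end orchestration: run the three arms (expert consensus, embedding
# k-means, prompted assignment) per rating-type stratum, compare them with
# the ARI and its permutation null, compute the content-overlap report, and
# export the report surfaces (agreement table, overlap summary, occurrence
# table, sunburst JSON, manifest).

#' Build a run configuration
#'
#' @param bank path to the item-bank file, or an [item_bank()].
#' @param catalog path to the symptom catalog, or a [symptom_catalog()].
#' @param raters path to the rater-labeling CSV, or a list of
#'   [rater_labeling()].
#' @param adjudication optional path to an adjudication CSV, or a named
#'   vector.
#' @param embeddings path to a precomputed embedding TSV (backend
#'   `"precomputed"`); ignored for backend `"planted"`.
#' @param truth path to a truth clustering CSV, or a [clustering()];
#'   required by the `"planted"` embedding backend and the `"lookup"`
#'   assignment backend.
#' @param assignments path to a stored llm clustering CSV (assignment
#'   backend `"file"`).
#' @param strata subset of `c("all", "SR", "OR")`.
#' @param embedding_backend `"precomputed"` or `"planted"`.
#' @param assignment_backend `"lookup"` or `"file"`.
#' @param B permutation repetitions (default 1000).
#' @param seed master seed.
#' @param n_init,max_iter k-means hyperparameters.
#' @param normalize L2-normalize embeddings (default TRUE).
#' @param planted_dim,planted_separation planted-backend parameters.
#' @param lookup_error_rate,lookup_malformed_rate lookup-backend parameters.
#' @param overlap_arm arm whose clustering feeds the overlap report:
#'   `"llm"` (the headline analysis), `"kmeans"` or `"expert"`.
#' @param prompt_template see [render_prompt()].
#' @return object of class `run_config`.
#' @export
run_config <- function(bank, catalog, raters,
                       adjudication = NULL,
                       embeddings = NULL,
                       truth = NULL,
                       assignments = NULL,
                       strata = "all",
                       embedding_backend = c("precomputed", "planted"),
                       assignment_backend = c("lookup", "file"),
                       B = 1000L, seed = 1L,
                       n_init = 10L, max_iter = 300L,
                       normalize = TRUE,
                       planted_dim = 768L, planted_separation = 4,
                       lookup_error_rate = 0, lookup_malformed_rate = 0,
                       overlap_arm = c("llm", "kmeans", "expert"),
                       prompt_template = default_prompt_template()) {
  strata <- match.arg(strata, c("all", "SR", "OR"), several.ok = TRUE)
  structure(list(
    bank = bank, catalog = catalog, raters = raters,
    adjudication = adjudication, embeddings = embeddings, truth = truth,
    assignments = assignments, strata = strata,
    embedding_backend = match.arg(embedding_backend),
    assignment_backend = match.arg(assignment_backend),
    B = as.integer(B), seed = as.integer(seed),
    n_init = as.integer(n_init), max_iter = as.integer(max_iter),
    normalize = isTRUE(normalize),
    planted_dim = as.integer(planted_dim),
    planted_separation = planted_separation,
    lookup_error_rate = lookup_error_rate,
    lookup_malformed_rate = lookup_malformed_rate,
    overlap_arm = match.arg(overlap_arm),
    prompt_template = prompt_template
  ), class = "run_config")
}

#' Read a run configuration from a JSON document
#'
#' Keys mirror the arguments of [run_config()]; path values are resolved
#' relative to the JSON file's directory.
#'
#' @param path JSON config path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p) || !is.character(p)) return(p)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (key in c("bank", "catalog", "raters", "adjudication", "embeddings",
                "truth", "assignments")) {
    cfg[[key]] <- rel(cfg[[key]])
  }
  args <- cfg[intersect(names(cfg), names(formals(run_config)))]
  do.call(run_config, args)
}

resolve_inputs <- function(config) {
  bank <- if (inherits(config$bank, "item_bank")) config$bank else
    read_item_bank(config$bank)
  catalog <- if (inherits(config$catalog, "symptom_catalog")) config$catalog
    else read_symptom_catalog(config$catalog, domain = bank$domain)
  raters <- if (is.character(config$raters))
    read_rater_labelings(config$raters, catalog) else config$raters
  adjudication <- if (is.null(config$adjudication)) character(0)
    else if (is.character(config$adjudication) &&
             length(config$adjudication) == 1 &&
             file.exists(config$adjudication))
      read_adjudication(config$adjudication)
    else config$adjudication
  truth <- if (is.null(config$truth)) NULL
    else if (inherits(config$truth, "clustering")) config$truth
    else read_clustering(config$truth, method = "truth")
  list(bank = bank, catalog = catalog, raters = raters,
       adjudication = adjudication, truth = truth)
}

subset_labeling <- function(labeling, ids) {
  keep <- intersect(names(labeling$assignments), ids)
  structure(list(rater_id = labeling$rater_id,
                 assignments = labeling$assignments[keep]),
            class = "rater_labeling")
}

subset_clustering <- function(cl, ids) {
  clustering(cl$assignments[intersect(names(cl$assignments), ids)],
             method = cl$method)
}

run_stratum <- function(stratum, inputs, config, seeds) {
  bank <- filter_items(inputs$bank,
                       rating_type = if (stratum == "all") NULL else stratum,
                       drop_excluded = TRUE)
  ids <- analyzed_items(bank)$item_id
  catalog <- inputs$catalog

  # --- expert arm ---------------------------------------------------------
  raters <- lapply(inputs$raters, subset_labeling, ids = ids)
  covered <- Reduce(intersect, lapply(raters, function(l)
    names(l$assignments)))
  missing <- setdiff(ids, covered)
  if (length(missing)) {
    qo_stop("stratum ", stratum, ": rater labelings do not cover item(s): ",
            paste(missing, collapse = ", "))
  }
  cons <- consensus_labeling(raters, catalog)
  expert <- apply_adjudication(cons, inputs$adjudication, catalog)
  k <- expert_k(expert)
  rr <- pairwise_rater_ari(raters)

  # --- embedding / k-means arm --------------------------------------------
  backend <- switch(config$embedding_backend,
    precomputed = {
      if (is.null(config$embeddings)) {
        qo_stop("embedding backend 'precomputed' needs an embeddings path")
      }
      NULL
    },
    planted = {
      if (is.null(inputs$truth)) {
        qo_stop("embedding backend 'planted' needs a truth clustering")
      }
      planted_backend(subset_clustering(inputs$truth, ids),
                      dim = config$planted_dim,
                      separation = config$planted_separation,
                      seed = seeds["planted"])
    })
  E <- if (config$embedding_backend == "precomputed") {
    Efull <- load_embeddings(config$embeddings, inputs$bank)
    m <- embedding_matrix(unclass(Efull)[ids, , drop = FALSE], ids)
    if (config$normalize) embedding_matrix(
      l2_normalize_rows(unclass(m)), ids) else m
  } else {
    embed_items(bank, backend, normalize = config$normalize)
  }
  km <- kmeans_cluster(E, k, seed = seeds["kmeans"],
                       n_init = config$n_init, max_iter = config$max_iter)
  km_ari <- adjusted_rand_index(km, expert)
  null <- permutation_null_ari(E, k, expert, B = config$B,
                               seed = seeds["null"],
                               n_init = config$n_init,
                               max_iter = config$max_iter)

  # --- prompted arm -------------------------------------------------------
  if (config$assignment_backend == "file") {
    if (is.null(config$assignments)) {
      qo_stop("assignment backend 'file' needs an assignments path")
    }
    llm_full <- read_clustering(config$assignments, method = "llm")
    llm <- subset_clustering(llm_full, ids)
    failures <- setdiff(ids, names(llm$assignments))
  } else {
    if (is.null(inputs$truth)) {
      qo_stop("assignment backend 'lookup' needs a truth clustering")
    }
    ab <- make_lookup_backend(subset_clustering(inputs$truth, ids),
                              catalog = catalog,
                              error_rate = config$lookup_error_rate,
                              malformed_rate = config$lookup_malformed_rate,
                              seed = seeds["lookup"])
    res <- assign_items(bank, catalog, ab,
                        template = config$prompt_template)
    llm <- res$clustering
    failures <- res$failures
  }
  llm_ari <- adjusted_rand_index(subset_clustering(expert,
                                                   names(llm$assignments)),
                                 llm)

  # --- overlap ------------------------------------------------------------
  overlap_cl <- switch(config$overlap_arm,
                       llm = llm, kmeans = km, expert = expert)
  overlap_bank <- bank
  if (length(failures)) {
    keep <- analyzed_items(bank)$item_id %in% names(overlap_cl$assignments)
    overlap_bank <- item_bank(analyzed_items(bank)[keep, , drop = FALSE],
                              domain = bank$domain)
  }
  overlap <- if (nrow(overlap_bank$questionnaires) >= 2) {
    overlap_matrix(overlap_cl, overlap_bank)
  } else NULL

  list(stratum = stratum, bank = bank, k = k,
       expert = expert, unresolved = cons$unresolved,
       expert_expert_mean = rr$mean, rater_matrix = rr$matrix,
       kmeans = km, kmeans_ari = km_ari, null = null,
       llm = llm, llm_ari = llm_ari, failures = failures,
       overlap = overlap)
}

#' Run the full three-arm pipeline
#'
#' Per requested stratum: expert consensus (adjudicating unresolved items or
#' aborting with their ids), k from the consensus, the k-means arm with its
#' permutation null, the prompted arm, expert-to-expert mean agreement, and
#' the content-overlap report on the configured arm.
#'
#' @param config a [run_config()].
#' @return a report bundle (class `run_bundle`): one result per stratum plus
#'   the domain and run metadata; pass to [export_reports()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- resolve_inputs(config)
  seed_vec <- derive_seeds(config$seed, 4 * length(config$strata))
  results <- list()
  for (i in seq_along(config$strata)) {
    s <- config$strata[i]
    seeds <- stats::setNames(seed_vec[(4 * i - 3):(4 * i)],
                             c("planted", "kmeans", "null", "lookup"))
    results[[s]] <- run_stratum(s, inputs, config, seeds)
  }
  structure(list(domain = inputs$bank$domain, strata = results,
                 config = config),
            class = "run_bundle")
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> domain '%s', strata: %s\n", x$domain,
              paste(names(x$strata), collapse = ", ")))
  for (s in x$strata) {
    cat(sprintf(
      "  [%s] k = %d | expert-expert %.3f | kmeans-expert %.3f (null CI [%.3f, %.3f]) | llm-expert %.3f\n",
      s$stratum, s$k, s$expert_expert_mean, s$kmeans_ari,
      s$null$ci_low, s$null$ci_high, s$llm_ari))
  }
  invisible(x)
}

fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h out of bitwXor's int range
    h <- (h - h %% 256) + bitwXor(h %% 256, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

#' Export the report bundle to a deterministic file set
#'
#' Writes `agreement.csv` (one row per stratum and comparison, mirroring the
#' agreement table layout), `overlap_pairs.csv` (long-form pairwise Jaccard),
#' `overlap_summary.csv` (per questionnaire: items, symptoms, mean Jaccard),
#' `occurrence.csv` (symptom x questionnaire 0/1), `sunburst.json` (nested
#' questionnaire -> symptom -> items) and `manifest.json` (seeds, config
#' hash, backend identifiers). Partial outputs are removed on error.
#'
#' @param bundle a `run_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_reports <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) qo_stop("cannot create output directory ", out_dir)
  files <- file.path(out_dir, c("agreement.csv", "overlap_pairs.csv",
                                "overlap_summary.csv", "occurrence.csv",
                                "sunburst.json", "manifest.json"))
  names(files) <- basename(files)
  ok <- FALSE
  on.exit(if (!ok) unlink(files), add = TRUE)

  agreement <- do.call(rbind, lapply(bundle$strata, function(s) {
    data.frame(
      domain = bundle$domain,
      stratum = s$stratum,
      comparison = c("expert-expert", "kmeans-expert", "llm-expert"),
      ari = c(s$expert_expert_mean, s$kmeans_ari, s$llm_ari),
      ci_low = c(NA, s$null$ci_low, NA),
      ci_high = c(NA, s$null$ci_high, NA),
      band = strength_band(c(s$expert_expert_mean, s$kmeans_ari, s$llm_ari)),
      stringsAsFactors = FALSE)
  }))
  utils::write.csv(agreement, files["agreement.csv"], row.names = FALSE,
                   fileEncoding = "UTF-8")

  pairs_rows <- list()
  summary_rows <- list()
  occ_rows <- list()
  sunburst <- list(name = bundle$domain, children = list())
  for (s in bundle$strata) {
    if (is.null(s$overlap)) next
    ov <- s$overlap
    qids <- ov$questionnaire_ids
    for (i in seq_along(qids)) {
      for (j in seq_along(qids)) {
        if (i < j) {
          pairs_rows[[length(pairs_rows) + 1]] <- data.frame(
            stratum = s$stratum, questionnaire_a = qids[i],
            questionnaire_b = qids[j], jaccard = ov$jaccard[i, j],
            stringsAsFactors = FALSE)
        }
      }
    }
    items <- analyzed_items(s$bank)
    for (q in qids) {
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        stratum = s$stratum, questionnaire = q,
        n_items = sum(items$questionnaire_id == q),
        n_symptoms = length(ov$profiles[[q]]),
        mean_jaccard = unname(ov$per_questionnaire_mean[q]),
        stringsAsFactors = FALSE)
    }
    occ <- ov$occurrence
    occ_rows[[s$stratum]] <- data.frame(
      stratum = s$stratum, symptom = rownames(occ),
      as.data.frame(occ * 1L), check.names = FALSE,
      stringsAsFactors = FALSE)
    if (s$stratum == bundle$strata[[1]]$stratum) {
      cl <- switch(bundle$config$overlap_arm, llm = s$llm,
                   kmeans = s$kmeans, expert = s$expert)
      sunburst$children <- lapply(qids, function(q) {
        qi <- items$item_id[items$questionnaire_id == q &
                              items$item_id %in% names(cl$assignments)]
        by_sym <- split(qi, unname(cl$assignments[qi]))
        list(name = q, children = lapply(names(by_sym), function(sym) {
          list(name = sym,
               children = lapply(by_sym[[sym]], function(id)
                 list(name = id)))
        }))
      })
    }
  }
  utils::write.csv(do.call(rbind, pairs_rows), files["overlap_pairs.csv"],
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(do.call(rbind, summary_rows), files["overlap_summary.csv"],
                   row.names = FALSE, fileEncoding = "UTF-8")
  occ_all <- do.call(rbind, lapply(occ_rows, function(d) {
    long <- utils::stack(d[, setdiff(names(d), c("stratum", "symptom"))])
    data.frame(stratum = d$stratum, symptom = d$symptom,
               questionnaire = as.character(long$ind),
               present = long$values, stringsAsFactors = FALSE)
  }))
  utils::write.csv(occ_all, files["occurrence.csv"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(sunburst, files["sunburst.json"], auto_unbox = TRUE)

  cfg <- bundle$config
  cfg_txt <- jsonlite::toJSON(
    cfg[vapply(cfg, function(v) is.atomic(v) || is.null(v), logical(1))],
    auto_unbox = TRUE, null = "null")
  manifest <- list(
    domain = bundle$domain,
    seed = cfg$seed,
    strata = cfg$strata,
    B = cfg$B,
    embedding_backend = cfg$embedding_backend,
    assignment_backend = cfg$assignment_backend,
    overlap_arm = cfg$overlap_arm,
    config_hash = fnv1a(as.character(cfg_txt)),
    files = unname(vapply(files, basename, character(1)))
  )
  jsonlite::write_json(manifest, files["manifest.json"], auto_unbox = TRUE,
                       pretty = TRUE)
  ok <- TRUE
  invisible(files)
}
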