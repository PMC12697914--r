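# expert consensus and prompted-assignment arms

test_that("render_prompt substitutes deterministically and validates", {
  catalog <- symptom_catalog(c("sadness", "guilt", "sleep problems"))
  item <- list(text = "I feel sad")
  p <- render_prompt(item, catalog)
  expect_equal(lengths(regmatches(p, gregexpr("I feel sad", p, fixed = TRUE))),
               1L)
  for (s in catalog$symptoms) expect_match(p, s, fixed = TRUE)
  # symptom list one per line, catalog order
  expect_match(p, "sadness\nguilt\nsleep problems", fixed = TRUE)
  expect_identical(render_prompt(item, catalog), p)
  expect_error(render_prompt(item, catalog, template = "Item: {item_text}"),
               "symptom_list")
})

test_that("assign_items validates responses and reports failures", {
  catalog <- symptom_catalog(c("sadness", "guilt"))
  bank <- item_bank(data.frame(
    item_id = c("q:1", "q:2", "q:3"), questionnaire_id = "q",
    text = c("i feel sad", "i feel guilty", "unanswerable"),
    rating_type = "SR", excluded = FALSE), domain = "d")

  answers <- c("q:1" = "Sadness.", # normalized + punctuation-stripped match
               "q:2" = "the best match is guilt", # unique substring
               "q:3" = "none of these") # off-catalog on every retry
  backend <- assignment_backend("test", function(id, prompt, attempt)
    answers[[id]])
  tpath <- withr::local_tempfile(fileext = ".jsonl")
  res <- assign_items(bank, catalog, backend, transcript_path = tpath)
  expect_equal(res$failures, "q:3")
  expect_equal(unname(res$clustering$assignments[c("q:1", "q:2")]),
               c("sadness", "guilt"))
  expect_equal(res$clustering$method, "llm")
  # idempotent with a deterministic backend
  res2 <- assign_items(bank, catalog, backend)
  expect_identical(res2$clustering$assignments, res$clustering$assignments)
  # transcript: one JSON record per item, failures annotated
  recs <- lapply(readLines(tpath), jsonlite::fromJSON)
  expect_length(recs, 3)
  expect_equal(recs[[3]]$failure, "no catalog match")
  expect_match(recs[[1]]$prompt, "i feel sad")
})

test_that("ambiguous substrings are failures, not guesses", {
  catalog <- symptom_catalog(c("decreased appetite", "increased appetite"))
  bank <- item_bank(data.frame(
    item_id = c("q:1", "q:2"), questionnaire_id = "q",
    text = c("appetite changed", "eats less"),
    rating_type = "SR", excluded = FALSE), domain = "d")
  backend <- assignment_backend("vague", function(id, prompt, attempt) {
    if (id == "q:1") "decreased appetite or increased appetite"
    else "decreased appetite"
  })
  res <- assign_items(bank, catalog, backend, max_retries = 0)
  expect_equal(res$failures, "q:1")
  expect_equal(unname(res$clustering$assignments["q:2"]),
               "decreased appetite")
})

test_that("consensus is majority-of-three and symmetric in rater order", {
  catalog <- symptom_catalog(c("s1", "s2", "s3"))
  ids <- c("a", "b", "c")
  r1 <- rater_of("r1", stats::setNames(c("s1", "s1", "s1"), ids), catalog)
  r2 <- rater_of("r2", stats::setNames(c("s1", "s2", "s2"), ids), catalog)
  r3 <- rater_of("r3", stats::setNames(c("s2", "s3", "s2"), ids), catalog)
  res <- consensus_labeling(list(r1, r2, r3), catalog)
  # a: (s1,s1,s2) -> s1; c: (s1,s2,s2) -> s2; b: all three disagree
  expect_equal(unname(res$clustering$assignments[c("a", "c")]),
               c("s1", "s2"))
  expect_equal(res$unresolved, "b")
  for (ord in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    alt <- consensus_labeling(list(r1, r2, r3)[ord], catalog)
    expect_identical(alt$clustering$assignments[c("a", "c")],
                     res$clustering$assignments[c("a", "c")])
    expect_identical(alt$unresolved, res$unresolved)
  }
  # unanimous raters: no unresolved items, pairwise ARI exactly 1
  res1 <- consensus_labeling(list(r1, r1, r1), catalog)
  expect_length(res1$unresolved, 0)
  expect_identical(res1$clustering$assignments, r1$assignments)
  expect_equal(pairwise_rater_ari(list(r1, r1, r1))$mean, 1.0)
})

test_that("consensus rejects differing item coverage, naming the difference", {
  catalog <- symptom_catalog(c("s1", "s2"))
  r1 <- rater_of("r1", c(a = "s1", b = "s2"), catalog)
  r2 <- rater_of("r2", c(a = "s1", b = "s2"), catalog)
  r3 <- rater_of("r3", c(a = "s1", z = "s2"), catalog)
  expect_error(consensus_labeling(list(r1, r2, r3), catalog), "b.*z|z.*b")
  expect_error(consensus_labeling(list(r1, r2), catalog), "exactly 3")
})

test_that("adjudication completes the consensus", {
  catalog <- symptom_catalog(c("s1", "s2", "s3"))
  ids <- c("a", "b")
  r1 <- rater_of("r1", stats::setNames(c("s1", "s1"), ids), catalog)
  r2 <- rater_of("r2", stats::setNames(c("s1", "s2"), ids), catalog)
  r3 <- rater_of("r3", stats::setNames(c("s1", "s3"), ids), catalog)
  res <- consensus_labeling(list(r1, r2, r3), catalog)
  expect_equal(res$unresolved, "b")
  done <- apply_adjudication(res, c(b = "s3"), catalog)
  expect_equal(done$method, "expert")
  expect_equal(unname(done$assignments[c("a", "b")]), c("s1", "s3"))
  # empty unresolved + empty adjudication: unchanged
  res0 <- consensus_labeling(list(r1, r1, r1), catalog)
  same <- apply_adjudication(res0, character(0), catalog)
  expect_identical(same$assignments, res0$clustering$assignments)
  # uncovered unresolved item, off-catalog label
  expect_error(apply_adjudication(res, character(0), catalog), "b")
  expect_error(apply_adjudication(res, c(b = "fatigue"), catalog),
               "off-catalog")
})

test_that("rater labelings round-trip through CSV with catalog validation", {
  catalog <- symptom_catalog(c("s1", "s2"))
  r1 <- rater_of("r1", c(a = "s1", b = "s2"), catalog)
  r2 <- rater_of("r2", c(a = "s2", b = "s2"), catalog)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rater_labelings(list(r1, r2), path)
  back <- read_rater_labelings(path, catalog)
  expect_equal(names(back), c("r1", "r2"))
  expect_identical(back$r1$assignments[c("a", "b")],
                   r1$assignments[c("a", "b")])
  expect_error(rater_labeling("rx", c(a = "unknown"), catalog),
               "off-catalog")
})
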