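# planted-partition generator: banks, embeddings, raters, lookup backend

test_that("generated domains mirror the configured world and are seeded", {
  cfg <- synthetic_config(seed = 11) # defaults: 7 questionnaires, 23 symptoms
  dom <- generate_synthetic_domain(cfg)
  expect_equal(nrow(dom$bank$questionnaires), 7)
  expect_length(dom$catalog$symptoms, 23)
  expect_s3_class(dom$bank, "item_bank") # constructor re-checks invariants
  expect_equal(dom$truth$method, "truth")
  # truth covers exactly the non-excluded items
  expect_setequal(names(dom$truth$assignments),
                  analyzed_items(dom$bank)$item_id)
  # all truth labels are catalog members
  expect_true(all(dom$truth$assignments %in% dom$catalog$symptoms))
  # item counts honor the configured range
  per_q <- table(analyzed_items(dom$bank)$questionnaire_id)
  expect_true(all(per_q >= 10 & per_q <= 40))
  # byte-identical regeneration under the same seed
  dom2 <- generate_synthetic_domain(cfg)
  expect_identical(dom2$bank$items, dom$bank$items)
  expect_identical(dom2$truth$assignments, dom$truth$assignments)
  expect_false(identical(
    generate_synthetic_domain(synthetic_config(seed = 12))$bank$items,
    dom$bank$items))
  expect_error(synthetic_config(n_symptoms = 1), "n_symptoms")
})

test_that("planted embeddings are reproducible and need dim >= k", {
  truth <- balanced_truth(5, 20)
  E1 <- generate_planted_embeddings(truth, dim = 16, separation = 10,
                                    seed = 2)
  expect_identical(
    unclass(generate_planted_embeddings(truth, dim = 16, separation = 10,
                                        seed = 2)),
    unclass(E1))
  expect_equal(dim(E1), c(100L, 16L))
  expect_equal(unname(sqrt(rowSums(unclass(E1)^2))), rep(1, 100),
               tolerance = 1e-12)
  expect_error(generate_planted_embeddings(truth, dim = 4, seed = 1),
               "dim >= 5")
  # separation 10: k-means recovers the planted truth
  km <- kmeans_cluster(E1, 5, seed = 2)
  expect_gte(adjusted_rand_index(km, truth), 0.99)
})

test_that("noisy raters degrade smoothly with the error rate", {
  truth <- balanced_truth(5, 30) # 150 items
  catalog <- symptom_catalog(sprintf("s%02d", 1:5))
  r0 <- generate_noisy_raters(truth, catalog, error_rate = 0, seed = 1)
  expect_length(r0, 3)
  for (r in r0) {
    expect_identical(unname(r$assignments[names(truth$assignments)]),
                     unname(truth$assignments))
  }
  expect_equal(pairwise_rater_ari(r0)$mean, 1.0)
  # epsilon = 1 with a large catalog: agreement collapses to chance
  big_truth <- cl_of(withr::with_seed(9, sample(sprintf("s%02d", 1:25), 300,
                                                replace = TRUE)),
                     ids = sprintf("i%03d", 1:300))
  big_cat <- symptom_catalog(sprintf("s%02d", 1:25))
  means <- vapply(1:5, function(s)
    pairwise_rater_ari(generate_noisy_raters(big_truth, big_cat,
                                             error_rate = 1,
                                             seed = s))$mean,
    numeric(1))
  expect_lt(abs(mean(means)), 0.05)
  # monotone: 0.2 strictly noisier than 0.4 over replicates
  m_at <- function(eps) mean(vapply(1:10, function(s)
    pairwise_rater_ari(generate_noisy_raters(truth, catalog,
                                             error_rate = eps,
                                             seed = 100 + s))$mean,
    numeric(1)))
  expect_gt(m_at(0.2), m_at(0.4))
})

test_that("lookup backend reproduces, corrupts, and fails as configured", {
  truth <- balanced_truth(4, 10)
  catalog <- symptom_catalog(sprintf("s%02d", 1:4))
  bank <- item_bank(data.frame(
    item_id = names(truth$assignments),
    questionnaire_id = rep(c("QA", "QB"), each = 20),
    text = paste("item", seq_along(truth$assignments)),
    rating_type = "SR", excluded = FALSE), domain = "d")

  exact <- make_lookup_backend(truth, catalog, error_rate = 0, seed = 1)
  res <- assign_items(bank, catalog, exact)
  expect_length(res$failures, 0)
  expect_equal(adjusted_rand_index(res$clustering, truth), 1)
  expect_identical(res$clustering$assignments[names(truth$assignments)],
                   truth$assignments)

  # malformed responses surface as failures at roughly the stated rate
  big <- balanced_truth(5, 60) # 300 items for a tight binomial check
  big_bank <- item_bank(data.frame(
    item_id = names(big$assignments), questionnaire_id = "Q",
    text = paste("item", 1:300), rating_type = "SR", excluded = FALSE),
    domain = "d")
  big_cat <- symptom_catalog(sprintf("s%02d", 1:5))
  mal <- make_lookup_backend(big, big_cat, malformed_rate = 0.1, seed = 3)
  res_m <- assign_items(big_bank, big_cat, mal, max_retries = 0)
  frac <- length(res_m$failures) / 300
  expect_true(abs(frac - 0.1) < 3 * sqrt(0.1 * 0.9 / 300)) # +-3 binomial sd
  # deterministic: identical corruption pattern across runs
  res_m2 <- assign_items(big_bank, big_cat,
                         make_lookup_backend(big, big_cat,
                                             malformed_rate = 0.1, seed = 3),
                         max_retries = 0)
  expect_identical(res_m2$failures, res_m$failures)
  expect_identical(res_m2$clustering$assignments,
                   res_m$clustering$assignments)
})
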