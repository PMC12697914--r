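# Shared fixtures and independent oracles. Everything is built in code; no
# binary fixtures.

# Independent pair-counting ARI oracle: classifies every unordered item pair
# as together/apart in each partition and applies the 2x2 closed form
# ARI = 2(n11*n00 - n10*n01) / ((n11+n10)(n10+n00) + (n11+n01)(n01+n00)).
# Deliberately shares no code with qoverlap::ari (which goes through the
# contingency table).
oracle_ari <- function(a, b) {
  s1 <- outer(a, a, "==")
  s2 <- outer(b, b, "==")
  up <- upper.tri(s1)
  n11 <- sum(s1[up] & s2[up])
  n10 <- sum(s1[up] & !s2[up])
  n01 <- sum(!s1[up] & s2[up])
  n00 <- sum(!s1[up] & !s2[up])
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1) # both partitions trivial => identical
  2 * (n11 * n00 - n10 * n01) / den
}

# small deterministic item bank: 2 questionnaires, mixed rating types,
# one excluded quality item
toy_bank <- function() {
  item_bank(data.frame(
    item_id = c("QA:1", "QA:2", "QA:3", "QB:1", "QB:2", "QB:3", "QB:4"),
    questionnaire_id = c("QA", "QA", "QA", "QB", "QB", "QB", "QB"),
    text = c("i feel sad", "i sleep badly", "i feel guilty",
             "sadness observed", "guilt observed", "honest answers check",
             "slowness observed"),
    rating_type = c("SR", "SR", "SR+OR", "OR", "OR", "OR", "OR"),
    excluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ), domain = "toy domain")
}

toy_catalog <- function() {
  symptom_catalog(c("sadness", "sleep problems", "guilt",
                    "psychomotor slowing"),
                  domain = "toy domain")
}

# labeled clustering helper
cl_of <- function(labels, ids = sprintf("i%02d", seq_along(labels)),
                  method = "truth") {
  clustering(stats::setNames(as.character(labels), ids), method)
}

# balanced planted truth: k clusters of size m
balanced_truth <- function(k, m) {
  cl_of(rep(sprintf("s%02d", seq_len(k)), each = m),
        ids = sprintf("i%03d", seq_len(k * m)))
}

# rater labeling built from a plain named vector
rater_of <- function(id, labels, catalog) {
  rater_labeling(id, labels, catalog)
}
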