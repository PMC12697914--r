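---
title: "Quantifying content overlap of mental-health questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying content overlap of mental-health questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qoverlap)
```

## The problem

Mental disorders are routinely assessed with questionnaires, and many
instruments exist for the same construct (seven or more scales for adult
depression alone). Instruments that nominally measure the same thing can
cover rather different symptom sets, which undermines the interchangeability
of scores across studies. The classical way to quantify this *content
overlap* is to have human raters assign every questionnaire item to a
symptom category and then compare the per-questionnaire symptom sets — a
procedure that is slow and observer-dependent.

`qoverlap` implements an observer-independent version of that procedure with
three interchangeable "arms" that each partition the pooled items of one
diagnostic domain by symptom:

1. **Expert arm** — three independent raters label every item with a symptom
   from a fixed catalog; the per-item majority (2 of 3) is the consensus,
   and items on which all three disagree are adjudicated explicitly.
2. **Embedding arm** — each item text is mapped to a fixed-length sentence
   embedding and the embeddings are partitioned with k-means, with the
   number of clusters $k$ tied to the expert consensus.
3. **Prompted arm** — a language-model-style backend is asked, item by item,
   to pick the single best-matching symptom from the catalog; responses are
   validated against the catalog and never trusted blindly.

Agreement between arms is measured with the Adjusted Rand Index (ARI), the
embedding arm is calibrated against a permutation null, and content overlap
between questionnaires is measured with the Jaccard index over symptom sets.

## The statistics

### Adjusted Rand Index

For two partitions of the same $n$ items with contingency counts $n_{ij}$,
row sums $a_i$ and column sums $b_j$,

$$
\mathrm{ARI} \;=\;
\frac{\sum_{ij}\binom{n_{ij}}{2} \;-\;
      \sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}\Big/\binom{n}{2}}
     {\tfrac12\!\left[\sum_i \binom{a_i}{2} + \sum_j \binom{b_j}{2}\right]
      \;-\; \sum_i \binom{a_i}{2}\sum_j \binom{b_j}{2}\Big/\binom{n}{2}} .
$$

The attainable range is $[-0.5, 1]$: 1 for identical partitions, values near
0 for chance-level agreement, negative values for agreement below chance.
The test suite verifies the implementation against an independent
pair-counting oracle exhaustively over *all* pairs of partitions of sets of
up to six elements (203 partitions at $n = 6$), and verifies by enumeration
that the minimum over partition pairs of a 4-element set is exactly $-0.5$.

*Degenerate denominator.* When both partitions are trivial (both
all-singletons, or both a single cluster) the formula is $0/0$. Both cases
force the partitions to be identical, and `ari()` returns 1 — the dominant
library convention, which keeps `ari(x, x) = 1` universally.

*Verbal bands.* In the absence of established ARI guidelines the
correlation-coefficient scale is used: very weak $[0, 0.2)$, weak
$[0.2, 0.4)$, moderate $[0.4, 0.6)$, strong $[0.6, 0.8)$, very strong
$[0.8, 1]$; negative values are "below chance". Boundaries are half-open on
the **unrounded** value, so 0.195 is "very weak", not "weak".

### Permutation null

A k-means solution always produces *some* partition, so its ARI against the
expert consensus needs a chance reference. The null reattaches the embedding
vectors to uniformly random items (`permute_embeddings()`), re-clusters, and
recomputes the ARI; the default is $B = 1000$ repetitions and the 95% CI is
the empirical 2.5th/97.5th percentile (type-7 quantiles, no interpolation
correction). Repetition $b$ derives its seed from a prefix-stable stream, so
enlarging $B$ never reshuffles earlier repetitions. An observed ARI above
`ci_high` indicates agreement beyond chance.

### Jaccard content overlap

A questionnaire's *symptom profile* is the **set** of distinct symptoms its
(non-excluded) items were assigned to; the overlap of two questionnaires is
$J(A,B) = |A \cap B| / |A \cup B|$. Overlap is deliberately computed over
symptom sets, not item counts: published analyses of this kind report
"$x/y$ symptoms found in questionnaire Q", and the set reading is the only
one consistent with that framing. Per-questionnaire means exclude the
diagonal; the domain mean averages the $\binom{Q}{2}$ unordered pairs. The
occurrence table distinguishes *universal* symptoms (present in every
questionnaire) from *idiosyncratic* ones (present in exactly one).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| embedding dimension | 768 | the conventional sentence-transformer width |
| row normalization | on | Euclidean k-means on unit rows $\approx$ cosine similarity, the conventional metric for sentence embeddings; configurable because the choice is not forced |
| k-means `n_init` / `max_iter` | 10 / 300 | standard defaults; k-means++ seeding, best of `n_init` by within-cluster SS |
| `k` | from `expert_k()` | the number of symptom labels the consensus *actually used* on the analyzed items — not the catalog size; stratifying by rating type can shrink it |
| permutation repetitions `B` | 1000 | convention for a stable 95% CI |
| majority rule | 2 of 3 | the only reading of "highest agreement" for three raters; only full three-way disagreement goes to adjudication |
| response matching | exact, then unique substring | never fuzzy-distance: a silently wrong assignment is worse than a reported failure |

Empty clusters during Lloyd iterations are repaired by re-seeding the empty
cluster with the point farthest from its current center — deterministic, and
recorded here because it affects bit-reproducibility. `stats::kmeans` cannot
express this rule (it stops on empty clusters), which is why the Lloyd loop
is implemented in the package; `stats::kmeans` is retained as an independent
cross-check in the test suite.

## The synthetic world

Real questionnaire texts are copyrighted, so the package ships a
planted-partition generator instead of data. Its defaults mirror a realistic
domain — 7 questionnaires of 10–40 items, a 23-symptom catalog (the
adult-depression scale of the published tables: 7 questionnaires, ~180
items, 23 symptoms), embedding dimension 768:

* **Symptom pools.** Roughly a third of the catalog is a shared *core*;
  the rest is split into per-questionnaire *private* slices. Each pool slot
  draws from the core with probability $\rho$ (`symptom_overlap`, default
  0.6 — a mid-range value giving moderate overlap, matching the range
  reported for real domains), otherwise from the questionnaire's private
  slice. $\rho$ therefore controls shared content directly and the
  domain-mean Jaccard rises monotonically with it. Private slices also give
  the generated domains idiosyncratic symptoms, as real domains have.
* **Embeddings.** One unit-variance isotropic Gaussian per true symptom,
  centers on mutually orthogonal directions at pairwise distance
  `separation` (in units of the component sd, default 4 — recoverable but
  not trivially so; 10 is the "well-separated" regime used in recovery
  tests). Rows are L2-normalized like real embeddings.
* **Raters.** Each rater keeps the true label with probability
  $1-\varepsilon$ (`rater_error`, default 0.1 — three raters at 10% error
  give consensus agreement in the "very strong" band, the level reported
  for well-behaved domains) and otherwise substitutes a uniformly random
  different catalog label. The corruption is symmetric — no confusion
  structure between similar symptoms — which is the simplest model
  consistent with the agreement levels being emulated; a confusion hook
  exists for sensitivity checks.
* **Prompted backend.** A lookup table answering with the (optionally
  corrupted) true label; a configurable fraction of malformed responses
  exercises the validation layer.

What a green test does *not* establish: real sentence embeddings are not
isotropic Gaussians, real rater errors are correlated with symptom
similarity, and real prompted models fail in structured ways. The synthetic
world validates the *pipeline arithmetic* — recovery when signal exists,
chance-level calibration when it does not — not the semantic quality of any
particular embedding or language model.

## Numerical and design choices

* **Sub-seeding.** All derived seeds come from a fixed-seed `sample.int`
  stream whose first $b$ entries are independent of the requested length —
  permutation $b$ of the null is identical whether $B$ is 200 or 1000.
* **Dual-mode questionnaires.** Items tagged `SR+OR` (self- *and*
  observer-rated) are included in **both** strata when stratifying by
  rating type. Duplication is the only rule that cannot silently drop
  items; whether the original analyses did this is not recoverable from the
  published tables, so the rule is a documented convention, not an
  inference.
* **`k` from labels used.** Tying $k$ to the labels the consensus actually
  used (not the catalog size) reproduces the observed phenomenon that
  stratification reduces the number of identified symptoms.
* **Degenerate inputs.** All-identical embedding rows with $k>1$ raise an
  error (a fallback would silently produce arbitrary partitions); empty
  filter results raise a typed error; a backend whose every response fails
  validation for an item puts the item in `failures` rather than guessing.
* **Overlap arm.** The content-overlap report is computed on the prompted
  arm's clustering by default — the headline configuration of the analysis
  being reproduced — with a switch for any arm (useful sensitivity check).
* **Recovery-test worlds.** The end-to-end recovery checks run in worlds
  with balanced planted clusters of ≳15 items. With singleton symptom
  clusters (which the default generator world does produce, like real
  domains), *no* within-cluster-SS k-means reliably isolates the
  singletons, and recovery saturates around ARI 0.87 — an inherent property
  of the objective, not an implementation artifact; the cross-check with
  `stats::kmeans` at `nstart = 50` lands in the same place.

## Known limitations

* The real transformer and chat-model backends are deliberately out of the
  test path; the backend contracts (`embedding_backend()`,
  `assignment_backend()`) are the extension point.
* ARI variance is not computed analytically; uncertainty statements rest on
  the permutation null.
* Weighted Jaccard variants for compound symptoms are not implemented.
* The consensus rule is specific to three raters; other panel sizes only
  support pairwise agreement.
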