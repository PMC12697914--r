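# item bank and symptom catalog ingestion, validation, stratification

test_that("read_item_bank parses the documented CSV layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "domain,questionnaire_id,questionnaire_name,item_id,text,rating_type,excluded",
    "adult depression,BDI,Beck Depression Inventory,BDI:1,i feel sad,SR,0",
    "adult depression,BDI,Beck Depression Inventory,BDI:2,i sleep badly,SR,0",
    "adult depression,IDS,Inventory of Depressive Symptoms,IDS:1,\"sadness, observed\",\"SR, OR\",0"
  ), path)
  bank <- read_item_bank(path)
  expect_s3_class(bank, "item_bank")
  expect_equal(nrow(bank$items), 3)
  expect_equal(nrow(bank$questionnaires), 2)
  expect_equal(bank$items$item_id, c("BDI:1", "BDI:2", "IDS:1"))
  # dual rating type "SR, OR" collapses to the SR+OR tag
  expect_equal(bank$items$rating_type[3], "SR+OR")
  expect_equal(bank$questionnaires$name[1], "Beck Depression Inventory")
})

test_that("read_item_bank generates item ids when absent and rejects bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "domain,questionnaire_id,text,rating_type,excluded",
    "d,QA,first item,SR,0",
    "d,QA,second item,SR,0",
    "d,QB,other item,OR,0"
  ), path)
  bank <- read_item_bank(path)
  expect_equal(bank$items$item_id, c("QA:1", "QA:2", "QB:1"))

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "domain,questionnaire_id,item_id,text,rating_type,excluded",
    "d,QA,x1,first,SR,0",
    "d,QA,x1,second,SR,0"
  ), dup)
  expect_error(read_item_bank(dup), "duplicate item_id.*x1")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("domain,questionnaire_id,text,excluded",
               "d,QA,first,0"), miss)
  expect_error(read_item_bank(miss), "rating_type")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_item_bank(empty), "empty")
})

test_that("item banks round-trip through csv, tsv and json", {
  bank <- toy_bank()
  for (ext in c(".csv", ".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_item_bank(bank, path)
    back <- read_item_bank(path)
    expect_equal(back$items, bank$items, info = ext)
    expect_equal(back$questionnaires$questionnaire_id,
                 bank$questionnaires$questionnaire_id, info = ext)
    expect_equal(back$domain, bank$domain, info = ext)
  }
})

test_that("read_symptom_catalog validates labels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("symptom", sprintf("symptom %02d", 1:23)), path)
  cat23 <- read_symptom_catalog(path, domain = "adult depression")
  expect_length(cat23$symptoms, 23)
  expect_equal(cat23$domain, "adult depression")

  # normalization collision: "Guilt" vs "guilt "
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("symptom", "Guilt", "guilt "), bad)
  expect_error(read_symptom_catalog(bad), "duplicate symptom")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_symptom_catalog(empty), "empty")

  jf <- withr::local_tempfile(fileext = ".json")
  writeLines('["sadness", "guilt"]', jf)
  expect_equal(read_symptom_catalog(jf)$symptoms, c("sadness", "guilt"))
})

test_that("filter_items stratifies by rating type with dual-mode duplication", {
  bank <- toy_bank() # 2 SR, 1 SR+OR, 3 OR (one excluded)
  sr <- filter_items(bank, "SR")
  or <- filter_items(bank, "OR")
  expect_equal(nrow(sr$items), 3) # 2 SR + 1 dual
  expect_equal(nrow(or$items), 4) # 3 OR kept + 1 dual (excluded dropped)
  # dual-mode item appears in BOTH strata
  expect_true("QA:3" %in% sr$items$item_id)
  expect_true("QA:3" %in% or$items$item_id)
  # union covers all non-excluded items; intersection is exactly the duals
  expect_setequal(union(sr$items$item_id, or$items$item_id),
                  analyzed_items(bank)$item_id)
  expect_equal(intersect(sr$items$item_id, or$items$item_id), "QA:3")
  # questionnaires with zero remaining items leave the metadata
  sr_only <- filter_items(item_bank(bank$items[bank$items$rating_type == "SR", ],
                                    domain = "d"), "SR")
  expect_false("QB" %in% sr_only$questionnaires$questionnaire_id)
})

test_that("filters that remove every item raise an empty-result error", {
  bank <- item_bank(data.frame(
    item_id = c("a", "b"), questionnaire_id = "Q", text = c("x", "y"),
    rating_type = "SR", excluded = FALSE), domain = "d")
  expect_error(filter_items(bank, "OR"), class = "qoverlap_empty_result")
})

test_that("item bank invariants are enforced", {
  base <- data.frame(item_id = c("a", "b"), questionnaire_id = "Q",
                     text = c("x", "y"), rating_type = "SR",
                     excluded = FALSE, stringsAsFactors = FALSE)
  expect_error(item_bank(transform(base, item_id = "a")), "duplicate")
  expect_error(item_bank(transform(base, text = "")), "empty text")
  expect_error(item_bank(transform(base, excluded = TRUE)),
               "no non-excluded")
  expect_error(item_bank(transform(base, rating_type = "XX")),
               "rating_type")
  expect_error(item_bank(base[, -3]), "missing column")
})
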