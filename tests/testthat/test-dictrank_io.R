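test_that("toy table parses to one record per concern category", {
  path <- write_toy_dictrank(toy_dictrank_rows())
  rec <- parse_dictrank_table(path)
  expect_equal(nrow(rec), 4L)
  expect_setequal(rec$concern, c("most", "less", "no", "ambiguous"))
  expect_equal(rec$generic_name[rec$concern == "most"], "sildenafil")
  expect_equal(rec$keywords[[1L]], c("QT prolongation", "hypotension"))
})

test_that("concern label dialects all normalise to the same category", {
  variants <- c("Most concern", "most-concern", "MOST CONCERN",
                "Most DICT Concern")
  expect_true(all(normalize_concern(variants) == "most"))
  expect_equal(normalize_concern(c("Less Concern", "Ambiguous", "No concern")),
               c("less", "ambiguous", "no"))
})

test_that("rows with unmappable concern are reported, not silently dropped", {
  rows <- toy_dictrank_rows()
  rows$`DICT Concern Category`[2L] <- "unclassifiable"
  path <- write_toy_dictrank(rows)
  expect_warning(rec <- parse_dictrank_table(path), "unrecognised concern")
  expect_equal(nrow(rec), 3L)
  expect_equal(nrow(attr(rec, "unmapped_concern")), 1L)
})

test_that("missing mandatory columns and empty files fail loudly", {
  rows <- toy_dictrank_rows()[, -2L]
  expect_error(parse_dictrank_table(write_toy_dictrank(rows)),
               "concern column")
  empty <- tempfile(fileext = ".csv")
  writeLines("Compound Name,DICT Concern Category", empty)
  expect_error(parse_dictrank_table(empty), "no rows")
})

test_that("drug-name normalisation strips salt suffixes and is idempotent", {
  expect_equal(normalize_drug_name("Sildenafil citrate"), "sildenafil")
  expect_equal(normalize_drug_name("morphine"), "morphine")
  expect_equal(normalize_drug_name("Metoprolol Tartrate"), "metoprolol")
  expect_error(normalize_drug_name("   "), "non-empty")

  # brute-force oracle: repeatedly drop the last token while it is a salt
  brute_strip <- function(nm, suffixes) {
    tok <- strsplit(tolower(trimws(nm)), "\\s+")[[1L]]
    repeat {
      if (length(tok) <= 1L || !tok[length(tok)] %in% suffixes) break
      tok <- tok[-length(tok)]
    }
    paste(tok, collapse = " ")
  }
  sfx <- default_config()$suffix_tokens
  fixtures <- c("Quinidine sulfate dihydrate", "Fludeoxyglucose 18F",
                "Warfarin Sodium", "esomeprazole magnesium trihydrate",
                "amlodipine besylate", "citrate", "plain drug")
  for (nm in fixtures) {
    once <- normalize_drug_name(nm, sfx)
    expect_equal(once, brute_strip(nm, sfx), info = nm)
    expect_equal(normalize_drug_name(once, sfx), once, info = nm)
  }
})

test_that("consolidation keeps the more severe labels and logs conflicts", {
  rec <- tibble::tibble(
    raw_name = c("Sildenafil", "Sildenafil citrate"),
    generic_name = c("sildenafil", "sildenafil"),
    concern = c("less", "most"),
    severity = c("mild", "severe"),
    toxicity_type = c("arrhythmia", "arrhythmia"),
    keywords = list("hypotension", c("QT prolongation"))
  )
  out <- consolidate_records(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$concern, "most")
  expect_equal(out$severity, "severe")
  expect_setequal(out$keywords[[1L]], c("hypotension", "QT prolongation"))
  conflicts <- attr(out, "conflicts")
  expect_setequal(conflicts$field, c("concern", "severity"))
})

test_that("consolidation is the identity without duplicates and is
           order-invariant in its concern counts", {
  path <- write_toy_dictrank(toy_dictrank_rows())
  rec <- parse_dictrank_table(path)
  out <- consolidate_records(rec)
  expect_equal(nrow(out), nrow(rec))
  expect_setequal(out$generic_name, rec$generic_name)

  d <- generate_synthetic(small_synthetic_config(seed = 11))
  p1 <- write_toy_dictrank(d$dictrank)
  p2 <- write_toy_dictrank(d$dictrank[rev(seq_len(nrow(d$dictrank))), ])
  c1 <- consolidate_records(parse_dictrank_table(p1))
  c2 <- consolidate_records(parse_dictrank_table(p2))
  expect_lte(nrow(c1), nrow(d$dictrank))
  expect_equal(table(c1$concern), table(c2$concern))
})

test_that("annotation join keeps every drug and reports strays", {
  drugs <- tibble::tibble(
    raw_name = c("a", "b", "c"), generic_name = c("a", "b", "c"),
    concern = "most", severity = "none", toxicity_type = "none",
    keywords = list(character(0), character(0), character(0))
  )
  ann <- tibble::tibble(
    generic_name = c("a", "b", "zz"), target_name = "t",
    target_class = "hERG", mode = "antagonist_or_inhibitor",
    affinity = "1 nM", ppb = 0.5, cmax = "1 nM", molecular_weight = 300
  )
  expect_warning(j <- merge_annotations(drugs, ann), "matched no drug")
  expect_equal(nrow(j), 3L)
  expect_equal(sum(j$annotation_status == "unannotated"), 1L)
  expect_equal(attr(j, "unmatched_annotations")$generic_name, "zz")

  dup <- ann[c(1, 1, 2), ]
  expect_error(merge_annotations(drugs, dup), "duplicate annotation keys")
})
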