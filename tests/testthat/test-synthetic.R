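test_that("identical seed and config give identical datasets", {
  a <- generate_synthetic(small_synthetic_config(seed = 42))
  b <- generate_synthetic(small_synthetic_config(seed = 42))
  expect_identical(a, b)
  c <- generate_synthetic(small_synthetic_config(seed = 43))
  expect_false(identical(a$dictrank, c$dictrank))
})

test_that("full availability and no duplicates give a complete dataset", {
  cfg <- synthetic_config(
    n_per_concern = c(most = 20L, less = 20L, ambiguous = 5L, no = 10L),
    availability = c(ppb = 1, affinity = 1, cmax = 1),
    duplicates_per_concern = NULL, duplicate_rate = 0, seed = 9
  )
  d <- generate_synthetic(cfg)
  expect_equal(nrow(d$dictrank), 55L)
  expect_false(any(is.na(d$annotations$affinity)))
  expect_false(any(is.na(d$annotations$ppb)))
  expect_false(any(is.na(d$annotations$cmax)))
  # consolidation is the identity
  rec <- parse_dictrank_table(write_toy_dictrank(d$dictrank))
  expect_equal(nrow(consolidate_records(rec)), nrow(rec))
})

test_that("concern marginals are exact and mapped fractions are calibrated", {
  n_each <- 2500L
  cfg <- synthetic_config(
    n_per_concern = c(most = n_each, less = n_each, ambiguous = n_each,
                      no = n_each),
    duplicates_per_concern = NULL, duplicate_rate = 0, seed = 2024
  )
  d <- generate_synthetic(cfg)
  marg <- table(d$truth$concern)
  expect_true(all(marg == n_each))
  for (cc in names(cfg$p_mapped_per_concern)) {
    p <- cfg$p_mapped_per_concern[[cc]]
    phat <- mean(d$truth$mapped_tier1[d$truth$concern == cc])
    se <- sqrt(p * (1 - p) / n_each)
    expect_lt(abs(phat - p), 3 * se)
  }
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_config(p_mapped_per_concern = c(most = 1.2, less = 0.5,
                                                         ambiguous = 0.5,
                                                         no = 0.5)),
               "probabilities")
  expect_error(synthetic_config(duplicate_rate = -0.1), "probabilities")
  expect_error(
    generate_synthetic(synthetic_config(
      n_per_concern = c(most = 5L, less = 5L, ambiguous = 5L, no = 5L),
      duplicates_per_concern = c(most = 10L, less = 0L, ambiguous = 0L,
                                 no = 0L))),
    "cannot exceed")
})

test_that("fixture_from_counts round-trips through contingency", {
  fx <- fixture_from_counts(tibble::tibble(
    concern = "most", mapped = 276L, unmapped = 51L))
  expect_equal(contingency(fx, 1)$percent_mapped, 84)

  expect_equal(nrow(fixture_from_counts(tibble::tibble(
    concern = "most", mapped = 0L, unmapped = 0L))), 0L)

  set.seed(77)
  for (i in 1:20) {
    counts <- tibble::tibble(
      concern = c("most", "less", "ambiguous", "no"),
      mapped = sample(0:200, 4L),
      unmapped = sample(0:200, 4L)
    )
    fx <- fixture_from_counts(counts)
    s <- contingency(fx, 1)
    back <- dplyr::left_join(counts, s, by = "concern")
    keep <- back$mapped.x + back$unmapped.x > 0
    expect_equal(back$mapped.y[keep], back$mapped.x[keep])
    expect_equal(back$unmapped.y[keep], back$unmapped.x[keep])
  }
})

test_that("pipeline on generated data recovers the configured structure", {
  cfg <- small_synthetic_config(seed = 101,
                                n = c(most = 60L, less = 60L,
                                      ambiguous = 20L, no = 60L))
  d <- generate_synthetic(cfg)
  paths <- write_synthetic(d, tempfile("synth"))
  prof <- suppressWarnings(
    dictox_pipeline(paths[["dictrank"]], paths[["annotations"]]))
  # consolidation recovers the pre-duplication drug count exactly
  expect_equal(nrow(prof), nrow(d$truth))
  # panels agree with ground truth except where hERG/QT priority or manual
  # corrections legitimately override
  cmp <- dplyr::left_join(prof[, c("generic_name", "panel")],
                          d$truth[, c("generic_name", "true_class")],
                          by = "generic_name")
  overridden <- cmp$panel != cmp$true_class
  expect_true(all(cmp$panel[overridden] == "herg"))
})

test_that("masked-value imputation is recovered exactly from ground truth", {
  cfg <- small_synthetic_config(seed = 55,
                                n = c(most = 50L, less = 50L,
                                      ambiguous = 20L, no = 50L))
  d <- generate_synthetic(cfg)
  paths <- write_synthetic(d, tempfile("synth"))
  prof <- suppressWarnings(
    dictox_pipeline(paths[["dictrank"]], paths[["annotations"]]))
  sens <- sensitivity_run(prof)
  imputed <- sort(unique(
    sens$report$generic_name[sens$report$action == "imputed_fu_0.5"]))
  expect_equal(imputed,
               sort(d$truth$generic_name[d$truth$masked_ppb]))
})
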