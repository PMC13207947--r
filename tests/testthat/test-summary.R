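test_that("contingency reproduces hand-computable percentages", {
  fx <- fixture_from_counts(tibble::tibble(
    concern = c("most", "no"), mapped = c(276L, 0L), unmapped = c(51L, 1L)
  ))
  s <- contingency(fx, 1)
  expect_equal(s$percent_mapped[s$concern == "most"], 84)
  expect_equal(s$percent_mapped[s$concern == "no"], 0)
  expect_equal(s$mapped + s$unmapped, c(327L, 1L))
})

test_that("contingency matches a brute-force per-drug count and is
           order-invariant", {
  for (seed in 1:20) {
    d <- generate_synthetic(small_synthetic_config(seed = seed))
    entries <- entries_from_truth(d$truth)
    for (tier in 1:3) {
      s <- contingency(entries, tier)
      # brute force: loop over drugs, classify one at a time
      for (cc in unique(entries$concern)) {
        sub <- entries[entries$concern == cc, ]
        m <- 0L
        for (i in seq_len(nrow(sub))) {
          if (tier_membership(sub$panel[i], tier)) m <- m + 1L
        }
        expect_equal(s$mapped[s$concern == cc], m)
        expect_equal(s$unmapped[s$concern == cc], nrow(sub) - m)
      }
    }
    shuffled <- entries[sample.int(nrow(entries)), ]
    expect_equal(contingency(shuffled, 1), contingency(entries, 1))
  }
})

test_that("tier percentages are monotone nonincreasing across tiers", {
  d <- generate_synthetic(small_synthetic_config(seed = 5))
  entries <- entries_from_truth(d$truth)
  sums <- lapply(1:3, function(t) contingency(entries, t))
  for (cc in unique(entries$concern)) {
    pct <- vapply(sums, function(s) s$percent_mapped[s$concern == cc],
                  numeric(1))
    expect_true(all(diff(pct) <= 0), info = cc)
  }
})

test_that("severity-margin table matches brute-force binning", {
  entries <- tibble::tibble(
    severity = c("mild", "moderate", "severe"),
    margin = c(0.1, 1, 10)
  )
  tab <- severity_margin_table(entries)
  counts <- as.matrix(tab$counts[, -1L])
  expect_equal(sum(counts), 3)
  expect_equal(max(counts), 1)  # one count per distinct bin

  same <- severity_margin_table(tibble::tibble(
    severity = rep("severe", 5), margin = rep(2, 5)))
  expect_equal(max(as.matrix(same$counts[, -1L])), 5)

  set.seed(31)
  for (rep in 1:10) {
    n <- 200
    entries <- tibble::tibble(
      severity = sample(c("mild", "moderate", "severe"), n, replace = TRUE),
      margin = c(rlnorm(n - 2, 0, 3), NA, NA)
    )
    tab <- severity_margin_table(entries)
    edges <- c(-Inf, -4:2, Inf)
    for (sv in unique(entries$severity)) {
      l10 <- log10(entries$margin[entries$severity == sv])
      l10 <- l10[!is.na(l10)]
      brute <- vapply(seq_len(length(edges) - 1L), function(b) {
        sum(l10 >= edges[b] & l10 < edges[b + 1L])
      }, numeric(1))
      got <- as.numeric(tab$counts[tab$counts$severity == sv, -1L])
      expect_equal(got, brute, info = sv)
    }
    expect_equal(sum(as.matrix(tab$counts[, -1L])),
                 sum(!is.na(entries$margin)))
  }
})

test_that("severity-margin table reports per-severity mean log margins", {
  entries <- tibble::tibble(severity = c("mild", "mild", "severe"),
                            margin = c(0.01, 1, 100))
  tab <- severity_margin_table(entries)
  expect_equal(tab$means$mean_log10_margin[tab$means$severity == "mild"], -1)
  expect_equal(tab$means$mean_log10_margin[tab$means$severity == "severe"], 2)
})

test_that("sensitivity run imputes fu = 0.5 and leaves classification alone", {
  entries <- tibble::tibble(
    generic_name = c("a", "b", "c"),
    concern = c("most", "most", "less"),
    severity = "none",
    panel = c("herg", "opioid", "other"),
    annotation_status = "annotated",
    affinity_nM = c(100, NA, 100),
    ppb = c(NA, 0.5, 0.5),
    fu = c(NA, 0.5, 0.5),
    cmax_total_nM = c(200, 300, NA),
    cmax_unbound_nM = c(NA, 150, NA),
    engagement_at_cmaxu = c(NA, NA, NA),
    margin = c(NA, NA, NA),
    complete = c(FALSE, FALSE, FALSE)
  )
  out <- sensitivity_run(entries)
  # ppb missing, cmax 200 -> cmax_u = 100
  expect_equal(out$entries$cmax_unbound_nM[1L], 100)
  expect_equal(out$entries$engagement_at_cmaxu[1L], 100 / 200)
  expect_setequal(out$report$action[out$report$generic_name == "a"],
                  "imputed_fu_0.5")
  expect_true("excluded_missing_cmax" %in%
                out$report$action[out$report$generic_name == "c"])
  expect_true("curve_only_missing_affinity" %in%
                out$report$action[out$report$generic_name == "b"])
  # classification counts identical to the unimputed contingency
  expect_equal(out$summaries[[1L]]$mapped, contingency(entries, 1)$mapped)
})

test_that("sensitivity summary equals the primary summary on complete data", {
  d <- generate_synthetic(small_synthetic_config(seed = 17))
  entries <- entries_from_truth(d$truth)
  entries$ppb <- 0.5
  entries$fu <- 0.5
  entries$affinity_nM <- 100
  entries$cmax_total_nM <- 100
  entries$cmax_unbound_nM <- 50
  out <- sensitivity_run(entries)
  expect_equal(out$summaries[[1L]], contingency(entries, 1))
  expect_equal(sum(out$report$action == "imputed_fu_0.5"), 0L)
  expect_equal(out$entries$margin, entries$margin)
})
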