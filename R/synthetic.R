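#' Configuration for the synthetic dataset generator
#'
#' Describes a DICTrank-like study population: the per-concern sample sizes
#' observed after consolidation (327 / 507 / 105 / 328 for most / less /
#' ambiguous / no concern), the probability per concern category that a
#' drug maps to one of the 18 key risk-target classes (calibrated to the
#' tiered summary proportions 0.84 / 0.66 / 0.54 / 0.44), class weights
#' giving hERG about 20% of the most-concern group, lognormal affinity and
#' Cmax, Beta-distributed protein binding, element-wise data availability
#' (0.811 protein binding, 0.738 affinity, 0.535 Cmax), and a salt-form
#' duplicate rate sized so that ~1318 raw rows consolidate to the unique
#' drug count.
#'
#' @param n_per_concern named integer vector (most, less, ambiguous, no).
#' @param p_mapped_per_concern per-concern probability of carrying a key
#'   risk-target class (tier-1 mapped).
#' @param p_herg_most target share of hERG among the most-concern group.
#' @param p_broad_given_mapped probability a mapped drug falls in a broad
#'   therapeutic class rather than a key class.
#' @param p_excl_given_mapped probability a mapped drug falls in one of the
#'   tier-3 exclusion classes.
#' @param p_other_given_unmapped split of unmapped drugs between "other"
#'   and no pharmacological target.
#' @param affinity_logmean,affinity_logsd lognormal parameters for the
#'   IC50/EC50 in nM (defaults: median 100 nM, sdlog 1.5).
#' @param cmax_logmean,cmax_logsd lognormal parameters for total Cmax in nM
#'   (defaults: median 300 nM, sdlog 1.2).
#' @param ppb_alpha,ppb_beta Beta parameters for the bound fraction
#'   (default Beta(5, 2), median ~0.74).
#' @param availability named availability rates for ppb, affinity, cmax.
#' @param duplicates_per_concern named integer vector of salt-form
#'   duplicate rows to inject per concern category; the default
#'   (14, 21, 1, 15) takes the 1267 unique drugs back up to 1318 raw rows
#'   with raw marginals (341, 528, 106, 343). Set to `NULL` to use
#'   `duplicate_rate` instead.
#' @param duplicate_rate fraction of drugs also emitted under a salt-form
#'   alias row; used only when `duplicates_per_concern` is `NULL`.
#' @param severity_coupling slope of the logistic link from log10 margin to
#'   severity (larger = stronger severity-margin trend).
#' @param seed integer RNG seed; identical seed and config give identical
#'   output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_concern = c(most = 327L, less = 507L,
                                               ambiguous = 105L, no = 328L),
                             p_mapped_per_concern = c(most = 0.84, less = 0.66,
                                                      ambiguous = 0.54,
                                                      no = 0.44),
                             p_herg_most = 0.20,
                             p_broad_given_mapped = 0.06,
                             p_excl_given_mapped = 0.05,
                             p_other_given_unmapped = 0.5,
                             affinity_logmean = log(100),
                             affinity_logsd = 1.5,
                             cmax_logmean = log(300), cmax_logsd = 1.2,
                             ppb_alpha = 5, ppb_beta = 2,
                             availability = c(ppb = 0.811, affinity = 0.738,
                                              cmax = 0.535),
                             duplicates_per_concern = c(most = 14L, less = 21L,
                                                        ambiguous = 1L,
                                                        no = 15L),
                             duplicate_rate = 0.04,
                             severity_coupling = 1.2,
                             seed = 1L) {
  cfg <- list(
    n_per_concern = n_per_concern,
    p_mapped_per_concern = p_mapped_per_concern,
    p_herg_most = p_herg_most,
    p_broad_given_mapped = p_broad_given_mapped,
    p_excl_given_mapped = p_excl_given_mapped,
    p_other_given_unmapped = p_other_given_unmapped,
    affinity_logmean = affinity_logmean, affinity_logsd = affinity_logsd,
    cmax_logmean = cmax_logmean, cmax_logsd = cmax_logsd,
    ppb_alpha = ppb_alpha, ppb_beta = ppb_beta,
    availability = availability,
    duplicates_per_concern = duplicates_per_concern,
    duplicate_rate = duplicate_rate,
    severity_coupling = severity_coupling,
    seed = as.integer(seed)
  )
  probs <- c(cfg$p_mapped_per_concern, cfg$p_herg_most,
             cfg$p_broad_given_mapped, cfg$p_excl_given_mapped,
             cfg$p_other_given_unmapped, cfg$availability,
             cfg$duplicate_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$n_per_concern < 0)) {
    stop("sample sizes must be nonnegative", call. = FALSE)
  }
  structure(cfg, class = c("synthetic_config", "list"))
}

# a display spelling per canonical class key, taken from the synonym table
class_display_name <- function(keys, config = default_config()) {
  vapply(keys, function(k) config$class_synonyms[[k]][[1L]], character(1),
         USE.NAMES = FALSE)
}

#' Generate a synthetic DICTrank-like dataset with ground truth
#'
#' Emulates the structure the pipeline consumes: a concern-labelled drug
#' table (with salt-form duplicate rows), a pharmacology annotation table
#' (affinities and Cmax emitted in mixed units to exercise harmonisation,
#' with element-wise missingness at the configured availability rates),
#' and a ground-truth table recording every drug's true class, mapped
#' status, pre-masking pharmacology and which fields were masked. hERG
#' drugs carry QT-prolongation keywords; severity is coupled to the true
#' exposure margin so the severity-versus-margin trend is recoverable.
#'
#' @param config a [synthetic_config()].
#' @return List with tibbles `dictrank`, `annotations`, `truth`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  set.seed(config$seed)
  concerns <- rep(names(config$n_per_concern), config$n_per_concern)
  n <- length(concerns)
  name <- sprintf("drug%05d", seq_len(n))

  # class assignment: mapped drugs draw a key class (hERG upweighted so the
  # most-concern group lands near the configured share), or occasionally a
  # broad-therapeutic or tier-3 exclusion class; unmapped drugs split
  # between "other" and no pharmacological target
  p_map <- config$p_mapped_per_concern[concerns]
  mapped <- runif(n) < p_map
  keys <- key_risk_classes()
  p_herg_given_mapped <- config$p_herg_most /
    config$p_mapped_per_concern[["most"]]
  w_rest <- (1 - p_herg_given_mapped) / (length(keys) - 1L)
  key_w <- setNames(rep(w_rest, length(keys)), keys)
  key_w["herg"] <- p_herg_given_mapped
  true_class <- character(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    if (!mapped[i]) {
      true_class[i] <- if (u[i] < config$p_other_given_unmapped) "other"
        else "no_pharmacological_target"
    } else if (u[i] < config$p_broad_given_mapped) {
      true_class[i] <- sample(broad_therapeutic_classes(), 1L)
    } else if (u[i] < config$p_broad_given_mapped + config$p_excl_given_mapped) {
      true_class[i] <- sample(tier3_exclusion_classes(), 1L)
    } else {
      true_class[i] <- sample(keys, 1L, prob = key_w)
    }
  }

  affinity_nM <- rlnorm(n, config$affinity_logmean, config$affinity_logsd)
  cmax_nM <- rlnorm(n, config$cmax_logmean, config$cmax_logsd)
  ppb <- rbeta(n, config$ppb_alpha, config$ppb_beta)
  margin <- cmax_nM * (1 - ppb) / affinity_nM

  # severity ~ Binomial(2, p) on (mild, moderate, severe), with p a
  # logistic function of log10 margin: larger free exposure relative to
  # affinity shifts mass toward severe events
  p_sev <- stats::plogis(config$severity_coupling * log10(margin))
  sev_draw <- rbinom(n, 2L, p_sev)
  severity <- c("mild", "moderate", "severe")[sev_draw + 1L]
  severity[concerns == "no"] <- "none"

  toxicity <- ifelse(true_class == "herg", "arrhythmia",
                     sample(c("arrhythmia", "heart damage", "mixed"), n,
                            replace = TRUE))
  toxicity[concerns == "no"] <- ""
  keywords <- ifelse(
    true_class == "herg", "QT prolongation; Torsades de Pointes",
    sample(c("hypertension", "tachycardia", "edema", ""), n, replace = TRUE)
  )
  keywords[concerns == "no"] <- ""

  # element-wise masking at the configured availability rates
  miss_ppb <- runif(n) >= config$availability[["ppb"]]
  miss_aff <- runif(n) >= config$availability[["affinity"]]
  miss_cmax <- runif(n) >= config$availability[["cmax"]]

  mw <- rlnorm(n, log(350), 0.3)
  # emit quantities in mixed units so ingest must harmonise
  aff_unit <- sample(c("nM", "uM"), n, replace = TRUE)
  aff_str <- ifelse(aff_unit == "nM",
                    sprintf("%.6g nM", affinity_nM),
                    sprintf("%.6g uM", affinity_nM / 1e3))
  cmax_unit <- sample(c("nM", "ng/mL"), n, replace = TRUE)
  cmax_str <- ifelse(cmax_unit == "nM",
                     sprintf("%.6g nM", cmax_nM),
                     sprintf("%.6g ng/mL", cmax_nM * mw / 1e6 * 1e3))
  aff_str[miss_aff] <- NA_character_
  cmax_str[miss_cmax] <- NA_character_
  ppb_out <- ifelse(miss_ppb, NA_real_, ppb)

  dictrank <- tibble::tibble(
    `Compound Name` = name,
    `DICT Concern Category` = paste(stringr::str_to_title(concerns), "Concern"),
    `Severity` = ifelse(severity == "none", "", severity),
    `Toxicity Type` = toxicity,
    `Keywords` = keywords
  )
  # salt-form duplicate rows: same drug, same labels, aliased name
  if (!is.null(config$duplicates_per_concern)) {
    dpc <- config$duplicates_per_concern
    if (any(dpc > config$n_per_concern[names(dpc)])) {
      stop("duplicates_per_concern cannot exceed n_per_concern",
           call. = FALSE)
    }
    dup_idx <- unlist(lapply(names(dpc), function(cc) {
      pool <- which(concerns == cc)
      if (dpc[[cc]] == 0L) integer(0)
      else pool[sample.int(length(pool), dpc[[cc]])]
    }))
    n_dup <- length(dup_idx)
  } else {
    n_dup <- floor(config$duplicate_rate * n)
    dup_idx <- if (n_dup > 0L) sample.int(n, n_dup) else integer(0)
  }
  if (n_dup > 0L) {
    salts <- sample(c("hydrochloride", "citrate", "sodium", "maleate"),
                    n_dup, replace = TRUE)
    dup_rows <- dictrank[dup_idx, , drop = FALSE]
    dup_rows$`Compound Name` <- paste(dup_rows$`Compound Name`, salts)
    dictrank <- dplyr::bind_rows(dictrank, dup_rows)
    dictrank <- dictrank[sample.int(nrow(dictrank)), , drop = FALSE]
  }

  has_target <- true_class != "no_pharmacological_target"
  annotations <- tibble::tibble(
    generic_name = name[has_target],
    target_name = paste0(true_class[has_target], "_target"),
    target_class = class_display_name(true_class[has_target]),
    mode = sample(c("agonist", "antagonist_or_inhibitor"), sum(has_target),
                  replace = TRUE),
    affinity = aff_str[has_target],
    ppb = ppb_out[has_target],
    cmax = cmax_str[has_target],
    molecular_weight = round(mw[has_target], 2)
  )

  truth <- tibble::tibble(
    generic_name = name,
    concern = concerns,
    severity = severity,
    true_class = true_class,
    mapped_tier1 = !true_class %in% c("other", "no_pharmacological_target"),
    affinity_nM = affinity_nM,
    cmax_total_nM = cmax_nM,
    ppb = ppb,
    margin = margin,
    masked_ppb = miss_ppb & has_target,
    masked_affinity = miss_aff & has_target,
    masked_cmax = miss_cmax & has_target
  )

  list(dictrank = dictrank, annotations = annotations, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same delimited formats the ingest step reads, plus the
#' ground-truth CSV.
#'
#' @param dataset list from [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dictrank = file.path(dir, "dictrank.csv"),
    annotations = file.path(dir, "annotations.csv"),
    truth = file.path(dir, "ground_truth.csv")
  )
  readr::write_csv(dataset$dictrank, paths[["dictrank"]])
  readr::write_csv(dataset$annotations, paths[["annotations"]])
  readr::write_csv(dataset$truth, paths[["truth"]])
  invisible(paths)
}

#' Deterministic classified fixture from contingency counts
#'
#' Builds a classified drug list realising exactly the requested
#' concern-by-mapped counts, with placeholder pharmacology, so the summary
#' operations can be checked against published contingency figures. Mapped
#' drugs are placed on the hERG panel (mapped at every tier); unmapped
#' drugs on "other".
#'
#' @param counts tibble with columns `concern`, `mapped`, `unmapped`
#'   (nonnegative integers).
#' @return Classified-entry tibble with columns `generic_name`, `concern`,
#'   `severity`, `panel`, `panel_rule`.
#' @export
#' @examples
#' fx <- fixture_from_counts(
#'   tibble::tibble(concern = "most", mapped = 276, unmapped = 51))
#' contingency(fx, 1)$percent_mapped  # 84
fixture_from_counts <- function(counts) {
  if (any(counts$mapped < 0 | counts$unmapped < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    cc <- counts$concern[[i]]
    m <- counts$mapped[[i]]
    um <- counts$unmapped[[i]]
    tibble::tibble(
      generic_name = c(sprintf("fx_%s_m%04d", cc, seq_len(m)),
                       sprintf("fx_%s_u%04d", cc, seq_len(um))),
      concern = cc,
      severity = "none",
      panel = c(rep("herg", m), rep("other", um)),
      panel_rule = "direct"
    )
  })
  rows
}
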