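#' The cardiovascular risk-target taxonomy
#'
#' Eighteen target classes recurrently associated with elevated
#' cardiovascular risk: the hERG potassium channel; adrenergic, dopamine,
#' serotonin, androgen, sex-hormone and opioid receptors; cyclooxygenase;
#' sodium and calcium channels; muscarinic and glucocorticoid receptors;
#' phosphodiesterase; topoisomerase; ACE; the AT1 receptor; monoamine
#' transporters; and acetylcholinesterase. Alongside these sit broad
#' therapeutic classes (excluded at tier 2 of the summaries), a second
#' exclusion set (removed at tier 3), an "other" bucket, and "no
#' pharmacological target".
#'
#' @return Character vector of canonical class keys.
#' @export
key_risk_classes <- function() {
  c("herg", "adrenergic", "dopamine", "serotonin", "androgen", "sex_hormone",
    "opioid", "cyclooxygenase", "sodium_channel", "calcium_channel",
    "muscarinic", "glucocorticoid", "phosphodiesterase", "topoisomerase",
    "ace", "at1", "monoamine_transporter", "acetylcholinesterase")
}

#' @rdname key_risk_classes
#' @export
broad_therapeutic_classes <- function() {
  c("antibacterial", "antiviral", "antifungal", "antiparasitic",
    "antidiabetic", "antihistamine", "statin")
}

#' @rdname key_risk_classes
#' @export
tier3_exclusion_classes <- function() {
  c("antineoplastic", "gaba", "vegfr_egfr", "anticoagulant_antiplatelet")
}

all_panel_classes <- function() {
  c(key_risk_classes(), broad_therapeutic_classes(), tier3_exclusion_classes(),
    "other", "no_pharmacological_target")
}

#' Map free-text target-class labels to canonical keys
#'
#' Matches against the synonym table in the configuration
#' (case-insensitive, whitespace-squished). Labels matching no synonym map
#' to `"other"`; missing/empty labels map to `NA` (resolved to
#' `"no_pharmacological_target"` during panel assignment).
#'
#' @param x character vector of class labels.
#' @param config configuration list supplying `class_synonyms`.
#' @return Character vector of canonical keys.
#' @export
normalize_target_class <- function(x, config = default_config()) {
  syn <- config$class_synonyms
  lookup <- setNames(
    rep(names(syn), lengths(syn)),
    stringr::str_squish(tolower(unlist(syn)))
  )
  key <- stringr::str_squish(tolower(as.character(x)))
  out <- unname(lookup[key])
  out[is.na(out) & !is.na(key) & nzchar(key)] <- "other"
  out
}

#' Manual panel corrections
#'
#' The human-in-the-loop correction table applied before any automatic
#' rule: each named drug is forced onto the given panel. The shipped
#' default corrects two known misassignments — moxifloxacin (therapeutic
#' target DNA gyrase, safety-relevant target hERG) and probenecid
#' (wrongly tagged AT1; no cardiovascular mechanism, so "other").
#'
#' @param path optional CSV with columns `generic_name`, `panel`; defaults
#'   to the table shipped with the package.
#' @return Tibble with columns `generic_name`, `panel`.
#' @export
default_corrections <- function(path = system.file("extdata",
                                                   "manual_corrections.csv",
                                                   package = "dictox")) {
  if (!nzchar(path) || !file.exists(path)) {
    return(tibble::tibble(generic_name = c("moxifloxacin", "probenecid"),
                          panel = c("herg", "other")))
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# does any keyword contain a QT/Torsades term? (case-insensitive substring)
matches_qt_terms <- function(keywords, qt_terms) {
  if (length(keywords) == 0L) {
    return(FALSE)
  }
  kw <- tolower(keywords)
  any(vapply(tolower(qt_terms),
             function(term) any(stringr::str_detect(kw, stringr::fixed(term))),
             logical(1)))
}

#' Assign one drug to a risk-target panel
#'
#' Applies the panel-assignment rules in priority order: a manual
#' correction wins outright; otherwise any hERG-class annotation or a
#' QT-prolongation / Torsades keyword forces the hERG panel (these drugs
#' are assigned a priori to hERG regardless of other plausible
#' mechanisms); otherwise the first annotated target class is used
#' directly; a drug with no annotated target maps to
#' `"no_pharmacological_target"`.
#'
#' @param generic_name drug name (for the correction lookup).
#' @param target_classes character vector of canonical class keys annotated
#'   for the drug (may be empty or `NA`).
#' @param keywords character vector of adverse-event keywords.
#' @param corrections correction tibble ([default_corrections()]).
#' @param config configuration list supplying `qt_terms`.
#' @return List with `panel` (canonical key) and `rule` (one of
#'   `"manual_correction"`, `"herg_priority"`, `"direct"`).
#' @export
assign_panel <- function(generic_name, target_classes, keywords = character(0),
                         corrections = default_corrections(),
                         config = default_config()) {
  hit <- match(generic_name, corrections$generic_name)
  if (!is.na(hit)) {
    return(list(panel = corrections$panel[[hit]], rule = "manual_correction"))
  }
  classes <- target_classes[!is.na(target_classes)]
  if ("herg" %in% classes || matches_qt_terms(keywords, config$qt_terms)) {
    return(list(panel = "herg", rule = "herg_priority"))
  }
  if (length(classes) == 0L) {
    return(list(panel = "no_pharmacological_target", rule = "direct"))
  }
  list(panel = classes[[1L]], rule = "direct")
}

#' Assign panels for a merged drug-annotation table
#'
#' Collapses the (possibly multi-target) merged table to one row per drug,
#' choosing the panel with [assign_panel()] and carrying forward the
#' pharmacology of the annotation row that backs the assignment (the
#' hERG-class row when hERG priority fired on a hERG annotation, otherwise
#' the first listed row).
#'
#' @param merged tibble from [merge_annotations()].
#' @param corrections correction tibble.
#' @param config configuration list.
#' @return One row per drug with added columns `panel` and `panel_rule`.
#' @export
assign_panels <- function(merged, corrections = default_corrections(),
                          config = default_config()) {
  merged$target_class_key <- normalize_target_class(merged$target_class, config)
  split_idx <- split(seq_len(nrow(merged)), merged$generic_name)
  rows <- lapply(split_idx, function(idx) {
    sub <- merged[idx, , drop = FALSE]
    a <- assign_panel(sub$generic_name[[1L]], sub$target_class_key,
                      unlist(sub$keywords[1L]), corrections, config)
    backing <- which(sub$target_class_key == a$panel)
    pick <- if (length(backing) > 0L) backing[[1L]] else 1L
    out <- sub[pick, , drop = FALSE]
    out$panel <- a$panel
    out$panel_rule <- a$rule
    out
  })
  out <- dplyr::bind_rows(rows)
  out[order(match(out$generic_name, unique(merged$generic_name))), ,
      drop = FALSE]
}

#' Tier membership of a panel assignment
#'
#' Decides whether a drug counts as "mapped" to the key risk targets at
#' each stringency tier. Tier 1 maps every drug whose panel is anything
#' other than `"other"` or `"no_pharmacological_target"`. Tier 2
#' additionally excludes the broad therapeutic classes (antibacterials,
#' antivirals, antifungals, antiparasitics, antidiabetics, antihistamines,
#' statins). Tier 3 further excludes antineoplastics, GABA-acting drugs,
#' VEGFR/EGFR inhibitors and anticoagulants/antiplatelets. Membership is
#' monotone: mapped at tier 3 implies mapped at tiers 2 and 1.
#'
#' @param panel character vector of canonical panel keys.
#' @param tier 1, 2 or 3.
#' @return Logical vector: mapped at the given tier.
#' @export
tier_membership <- function(panel, tier) {
  if (!tier %in% 1:3) {
    stop("tier must be 1, 2 or 3", call. = FALSE)
  }
  mapped <- !panel %in% c("other", "no_pharmacological_target")
  if (tier >= 2) {
    mapped <- mapped & !panel %in% broad_therapeutic_classes()
  }
  if (tier >= 3) {
    mapped <- mapped & !panel %in% tier3_exclusion_classes()
  }
  mapped
}
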