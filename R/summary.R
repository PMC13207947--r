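# round half away from zero, to integer percent (the reporting convention;
# base round() would take 0.5 to the even digit)
round_percent <- function(x) floor(x + 0.5)

#' Concern-by-mapped contingency summary for one tier
#'
#' Counts, for each concern category, how many drugs are mapped to the key
#' risk-target classes at the requested stringency tier (see
#' [tier_membership()]), and the integer percentage mapped.
#'
#' @param entries tibble with columns `concern` and `panel`.
#' @param tier 1, 2 or 3.
#' @return A `tier_summary` tibble with columns `tier`, `concern`,
#'   `mapped`, `unmapped`, `percent_mapped`; one row per concern category
#'   present, ordered most/less/ambiguous/no.
#' @export
#' @examples
#' entries <- fixture_from_counts(
#'   tibble::tibble(concern = "most", mapped = 276, unmapped = 51))
#' contingency(entries, tier = 1)   # 84% mapped
contingency <- function(entries, tier) {
  if (!tier %in% 1:3) {
    stop("tier must be 1, 2 or 3", call. = FALSE)
  }
  mapped_flag <- tier_membership(entries$panel, tier)
  tab <- tibble::tibble(concern = entries$concern, mapped_flag = mapped_flag)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$concern),
    mapped = sum(.data$mapped_flag),
    unmapped = sum(!.data$mapped_flag),
    .groups = "drop"
  )
  out <- out[order(match(out$concern, concern_levels())), , drop = FALSE]
  out <- tibble::add_column(out, tier = tier, .before = 1L)
  out$percent_mapped <- round_percent(100 * out$mapped /
                                        (out$mapped + out$unmapped))
  class(out) <- c("tier_summary", class(out))
  out
}

#' @export
print.tier_summary <- function(x, ...) {
  cat("Tier", x$tier[[1L]], "concern vs key-risk-target summary\n")
  NextMethod()
  invisible(x)
}

#' Severity versus exposure-margin frequency table
#'
#' Bins the exposure-to-affinity margin (`Cmax,u / affinity`) of
#' complete-data drugs on the log10 scale and crosses the bins with the
#' severity label, reproducing the severity-versus-margin frequency view
#' used for the most-concern drugs. Also reports the mean log10 margin per
#' severity, the summary behind "exposure relative to affinity is lower
#' for drugs with milder events".
#'
#' @param entries tibble with columns `severity` and `margin`; rows with
#'   missing margin are ignored.
#' @param bin_edges margin-scale bin edges; defaults to integer powers of
#'   ten from 1e-4 to 1e2. Outer bins are open.
#' @return A `severity_margin_table`: list with `counts` (tibble, one row
#'   per severity, one column per log10 bin) and `means` (tibble of
#'   severity, n, mean_log10_margin).
#' @export
severity_margin_table <- function(entries,
                                  bin_edges = default_config()$margin_bin_edges) {
  keep <- !is.na(entries$margin)
  entries <- entries[keep, , drop = FALSE]
  edges <- c(-Inf, log10(bin_edges), Inf)
  labels <- c(paste0("<", log10(bin_edges)[1L]),
              paste0("[", log10(bin_edges)[-length(bin_edges)], ",",
                     log10(bin_edges)[-1L], ")"),
              paste0(">=", log10(bin_edges)[length(bin_edges)]))
  if (nrow(entries) == 0L) {
    counts <- tibble::tibble(severity = character(0))
    means <- tibble::tibble(severity = character(0), n = integer(0),
                            mean_log10_margin = numeric(0))
    return(structure(list(counts = counts, means = means, labels = labels),
                     class = "severity_margin_table"))
  }
  bin <- cut(log10(entries$margin), breaks = edges, labels = labels,
             right = FALSE)
  tab <- table(factor(entries$severity,
                      levels = intersect(severity_levels(),
                                         unique(entries$severity))),
               bin)
  counts <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "severity")
  means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(severity = entries$severity,
                                   l10 = log10(entries$margin)),
                    .data$severity),
    n = dplyr::n(),
    mean_log10_margin = mean(.data$l10),
    .groups = "drop"
  )
  means <- means[order(match(means$severity, severity_levels())), ,
                 drop = FALSE]
  structure(list(counts = counts, means = means, labels = labels),
            class = "severity_margin_table")
}

#' @export
print.severity_margin_table <- function(x, ...) {
  cat("Severity vs log10(Cmax,u / affinity) frequency table\n")
  print(x$counts)
  cat("\nMean log10 margin by severity\n")
  print(x$means)
  invisible(x)
}

#' Sensitivity analysis with fraction-unbound imputation
#'
#' Re-runs the tiered summaries over all drugs, including those with
#' incomplete pharmacology, under the stated imputation rules: drugs
#' lacking plasma protein binding get fraction unbound 0.5; drugs lacking
#' Cmax keep their classification but contribute no engagement or margin;
#' drugs lacking affinity are flagged curve-only. Classification counts are
#' unaffected by imputation — only the exposure metrics change.
#'
#' @param entries classified profile tibble ([build_pharm_profiles()]).
#' @param config configuration list supplying `fu_impute`.
#' @return A list with `entries` (the table after imputation, with an
#'   `imputed_fu` flag), `summaries` (tier summaries for tiers 1-3),
#'   and `report` (tibble of `generic_name`, `action`).
#' @export
sensitivity_run <- function(entries, config = default_config()) {
  fu_imp <- config$fu_impute
  out <- entries
  needs_fu <- is.na(out$ppb)
  # unannotated drugs have no pharmacology to impute into
  if ("annotation_status" %in% names(out)) {
    needs_fu <- needs_fu & out$annotation_status == "annotated"
  }
  out$imputed_fu <- needs_fu
  out$fu[needs_fu] <- fu_imp
  # recompute exposure metrics with the imputed fu where Cmax is known
  have_cmax <- !is.na(out$cmax_total_nM)
  recompute <- needs_fu & have_cmax
  out$cmax_unbound_nM[recompute] <- out$cmax_total_nM[recompute] * fu_imp
  have_aff <- !is.na(out$affinity_nM)
  idx <- recompute & have_aff
  out$engagement_at_cmaxu[idx] <- out$cmax_unbound_nM[idx] /
    (out$affinity_nM[idx] + out$cmax_unbound_nM[idx])
  out$margin[idx] <- out$cmax_unbound_nM[idx] / out$affinity_nM[idx]

  report <- dplyr::bind_rows(
    tibble::tibble(generic_name = out$generic_name[needs_fu],
                   action = "imputed_fu_0.5"),
    tibble::tibble(generic_name = out$generic_name[!have_cmax],
                   action = "excluded_missing_cmax"),
    tibble::tibble(generic_name = out$generic_name[!have_aff],
                   action = "curve_only_missing_affinity")
  )
  summaries <- lapply(1:3, function(t) contingency(out, t))
  list(entries = out, summaries = summaries, report = report)
}

#' Write the per-drug engagement table
#'
#' Fixed-column CSV of the harmonised profiles: name, affinity, fraction
#' unbound, total and unbound Cmax (all nM), engagement at Cmax,u, margin,
#' panel and completeness flag.
#'
#' @param entries profile tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_engagement_table <- function(entries, path) {
  cols <- c("generic_name", "concern", "severity", "panel", "panel_rule",
            "annotation_status", "affinity_nM", "ppb", "fu", "cmax_total_nM",
            "cmax_unbound_nM", "engagement_at_cmaxu", "margin", "complete")
  keep <- intersect(cols, names(entries))
  tab <- entries[keep]
  tab$unit <- "nM"
  readr::write_csv(tab, path)
  invisible(path)
}

#' Write tier summaries
#'
#' @param summaries a `tier_summary` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tier_summary <- function(summaries, path) {
  if (inherits(summaries, "tier_summary")) {
    summaries <- list(summaries)
  }
  readr::write_csv(dplyr::bind_rows(summaries), path)
  invisible(path)
}

#' Run the full ingest-classify-profile pipeline
#'
#' Convenience wrapper: parse the DICTrank-style table, consolidate to
#' unique generic drugs, join the annotations, assign risk-target panels
#' and build harmonised pharmacology profiles.
#'
#' @param dictrank_path path to the concern-labelled drug table.
#' @param annotations_path path to the pharmacology annotation table.
#' @param config configuration list.
#' @param corrections manual-correction tibble.
#' @return Classified profile tibble, one row per unique generic drug.
#' @export
dictox_pipeline <- function(dictrank_path, annotations_path,
                            config = default_config(),
                            corrections = default_corrections()) {
  records <- parse_dictrank_table(dictrank_path, config)
  drugs <- consolidate_records(records)
  annotations <- parse_annotation_table(annotations_path, config)
  merged <- merge_annotations(drugs, annotations)
  classified <- assign_panels(merged, corrections, config)
  build_pharm_profiles(classified, config)
}
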