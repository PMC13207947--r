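#' Benchmark a candidate against reference drugs sharing its target class
#'
#' Places a new candidate among marketed reference drugs acting on the same
#' target class, ranked by predicted target engagement at the unbound Cmax.
#' A candidate whose free exposure reaches its affinity (margin >= 1,
#' equivalently engagement >= 0.5) is flagged for particular scrutiny.
#'
#' @param candidate list or one-row data frame with `generic_name`,
#'   `target_class` (canonical key or free text), `affinity_nM`, `ppb`,
#'   `cmax_total_nM`; must be complete.
#' @param references classified profile tibble ([dictox_pipeline()] or
#'   [build_pharm_profiles()]); filtered internally to the candidate's
#'   class and to rows with computable engagement.
#' @param config configuration list.
#' @return A `benchmark_report`: list with `candidate` (name, class,
#'   engagement, margin, `exceeds_affinity_flag`), `references` (tibble
#'   sorted by rank), `candidate_rank` (1 = highest engagement; ties broken
#'   by larger margin, then name), and `n_total`.
#' @export
benchmark_candidate <- function(candidate, references,
                                config = default_config()) {
  cand_class <- normalize_target_class(candidate$target_class, config)
  need <- c("affinity_nM", "ppb", "cmax_total_nM")
  vals <- vapply(need, function(f) as.numeric(candidate[[f]]), numeric(1))
  if (any(is.na(vals))) {
    stop("candidate must have complete affinity, ppb and cmax data",
         call. = FALSE)
  }
  cmax_u <- unbound_cmax(vals[["cmax_total_nM"]], vals[["ppb"]])
  eng <- fractional_engagement(cmax_u, vals[["affinity_nM"]])
  margin <- cmax_u / vals[["affinity_nM"]]

  refs <- references[!is.na(references$engagement_at_cmaxu) &
                       references$panel == cand_class, , drop = FALSE]
  if (nrow(refs) == 0L) {
    warning("no reference drugs with complete data in class '", cand_class,
            "'; candidate ranked 1 of 1", call. = FALSE)
  }
  pool <- tibble::tibble(
    generic_name = c(as.character(candidate$generic_name), refs$generic_name),
    concern = c("candidate", as.character(refs$concern %||%
                                            rep(NA, nrow(refs)))),
    severity = c("candidate", as.character(refs$severity %||%
                                             rep(NA, nrow(refs)))),
    engagement_at_cmaxu = c(eng, refs$engagement_at_cmaxu),
    margin = c(margin, refs$margin),
    is_candidate = c(TRUE, rep(FALSE, nrow(refs)))
  )
  ord <- order(-pool$engagement_at_cmaxu, -pool$margin, pool$generic_name)
  pool <- pool[ord, , drop = FALSE]
  pool$rank <- seq_len(nrow(pool))
  structure(
    list(
      candidate = list(generic_name = as.character(candidate$generic_name),
                       target_class = cand_class,
                       engagement_at_cmaxu = eng, margin = margin,
                       exceeds_affinity_flag = cmax_u >= vals[["affinity_nM"]]),
      references = pool[!pool$is_candidate, , drop = FALSE],
      candidate_rank = pool$rank[pool$is_candidate],
      n_total = nrow(pool)
    ),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Candidate benchmark:", x$candidate$generic_name, "in class",
      x$candidate$target_class, "\n")
  cat("  engagement at Cmax,u:",
      format(round(x$candidate$engagement_at_cmaxu, 3)),
      " margin:", format(signif(x$candidate$margin, 3)), "\n")
  cat("  rank", x$candidate_rank, "of", x$n_total,
      if (x$candidate$exceeds_affinity_flag)
        "-- free Cmax reaches affinity: scrutinize\n" else "\n")
  invisible(x)
}

# long table of curve points for the drugs in one panel
panel_curves <- function(entries, config) {
  with_aff <- entries[!is.na(entries$affinity_nM), , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(with_aff)), function(i) {
    row <- with_aff[i, ]
    conc <- engagement_grid(row$affinity_nM, config$curve_grid)
    tibble::tibble(
      generic_name = row$generic_name,
      concern = row$concern,
      severity = row$severity,
      concentration_nM = conc,
      engagement = fractional_engagement(conc, row$affinity_nM)
    )
  })
}

build_panel_plot <- function(entries, panel_name, config) {
  curves <- panel_curves(entries, config)
  markers <- entries[!is.na(entries$affinity_nM) &
                       !is.na(entries$cmax_unbound_nM) &
                       entries$cmax_unbound_nM > 0, , drop = FALSE]
  no_aff <- entries[is.na(entries$affinity_nM), , drop = FALSE]
  p <- ggplot2::ggplot()
  if (nrow(curves) > 0L) {
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$concentration_nM, y = .data$engagement,
                   group = .data$generic_name, colour = .data$concern,
                   linetype = .data$severity)
    )
  }
  if (nrow(markers) > 0L) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(
        generic_name = markers$generic_name,
        concern = markers$concern,
        severity = markers$severity,
        concentration_nM = markers$cmax_unbound_nM,
        engagement = markers$engagement_at_cmaxu
      ),
      ggplot2::aes(x = .data$concentration_nM, y = .data$engagement,
                   colour = .data$concern, shape = .data$severity),
      size = 2.5
    )
  }
  if (nrow(no_aff) > 0L) {
    # affinity unknown: drawn as horizontal reference lines at spaced heights
    ys <- seq(0.05, 0.95, length.out = nrow(no_aff) + 2L)[-c(1L, nrow(no_aff) + 2L)]
    p <- p + ggplot2::geom_hline(
      data = tibble::tibble(generic_name = no_aff$generic_name,
                            concern = no_aff$concern, y = ys),
      ggplot2::aes(yintercept = .data$y, colour = .data$concern),
      linetype = "dotted"
    )
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(title = panel_name, x = "free concentration (nM)",
                  y = "fractional target engagement") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Render the risk-target panel figures
#'
#' One figure per target-class panel: engagement curves on a log
#' concentration axis, coloured by concern and styled by severity, with a
#' marker at `(Cmax,u, engagement at Cmax,u)` for each drug with complete
#' exposure data. Drugs with missing Cmax show the bare curve; drugs with
#' missing affinity are drawn as dotted horizontal lines at evenly spaced
#' heights. Drugs in the "other" bucket are split into four panels by
#' concern category. Empty panels are skipped (with a log entry in the
#' `"skipped"` attribute).
#'
#' @param entries classified profile tibble.
#' @param out_dir optional directory; when given, each panel is written as
#'   a PNG named `panel_<class>.png`.
#' @param config configuration list.
#' @return Named list of ggplot objects (invisible when writing files);
#'   attribute `"files"` carries written paths, `"skipped"` the empty
#'   panels.
#' @export
render_panels <- function(entries, out_dir = NULL, config = default_config()) {
  drawable <- entries[entries$panel != "no_pharmacological_target", ,
                      drop = FALSE]
  plots <- list()
  skipped <- character(0)
  classes <- setdiff(all_panel_classes(), c("other", "no_pharmacological_target"))
  for (cls in classes) {
    sub <- drawable[drawable$panel == cls, , drop = FALSE]
    if (nrow(sub) == 0L) {
      skipped <- c(skipped, cls)
      next
    }
    plots[[cls]] <- build_panel_plot(sub, cls, config)
  }
  other <- drawable[drawable$panel == "other", , drop = FALSE]
  for (cc in concern_levels()) {
    sub <- other[other$concern == cc, , drop = FALSE]
    nm <- paste0("other_", cc)
    if (nrow(sub) == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    plots[[nm]] <- build_panel_plot(sub, paste("other:", cc, "concern"),
                                    config)
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(plots)) {
      f <- file.path(out_dir, paste0("panel_", nm, ".png"))
      ggplot2::ggsave(f, plots[[nm]], width = 7, height = 5, dpi = 150)
      files <- c(files, f)
    }
  }
  attr(plots, "files") <- files
  attr(plots, "skipped") <- skipped
  if (is.null(out_dir)) plots else invisible(plots)
}
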