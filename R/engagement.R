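#' Fractional target engagement (Emax model)
#'
#' Engagement of a target at free drug concentration `c` under the
#' hyperbolic Emax model with Hill coefficient 1:
#' \deqn{E(c) = \frac{E_{max} \, c}{EC_{50} + c}}
#' `affinity` is the EC50 for agonists and the IC50 for antagonists and
#' inhibitors — the two are treated identically here, with the mode of
#' action retained only as metadata. `e_max` is fixed at 1 by convention
#' (full engagement at saturation).
#'
#' @param c free drug concentration in nM; `>= 0`. Vectorised.
#' @param affinity EC50/IC50 in nM; must be `> 0`.
#' @param e_max maximal engagement, in (0, 1].
#' @return Engagement fraction(s) in \[0, `e_max`\]; exactly 0 at `c = 0`,
#'   exactly `e_max / 2` at `c = affinity`.
#' @export
#' @examples
#' fractional_engagement(100, 100)      # 0.5
#' fractional_engagement(900, 100)      # 0.9
fractional_engagement <- function(c, affinity, e_max = 1) {
  if (any(!is.finite(affinity)) || any(affinity <= 0)) {
    stop("affinity must be a positive, finite concentration", call. = FALSE)
  }
  if (any(e_max <= 0) || any(e_max > 1)) {
    stop("e_max must lie in (0, 1]", call. = FALSE)
  }
  if (any(c < 0)) {
    stop("concentration must be nonnegative", call. = FALSE)
  }
  e_max * c / (affinity + c)
}

#' Unbound maximum plasma concentration
#'
#' The pharmacologically active (free) exposure:
#' \deqn{C_{max,u} = C_{max} \times (1 - \mathrm{ppb})}
#' where `ppb` is the fraction of drug bound to plasma proteins.
#'
#' @param cmax_total total Cmax in nM; `>= 0`. Vectorised.
#' @param ppb bound fraction in \[0, 1\].
#' @return Unbound Cmax in nM; equals `cmax_total` at `ppb = 0`, zero at
#'   `ppb = 1`.
#' @export
#' @examples
#' unbound_cmax(1000, 0.9)  # 100
unbound_cmax <- function(cmax_total, ppb) {
  if (any(!is.na(ppb) & (ppb < 0 | ppb > 1))) {
    stop("plasma protein binding must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.na(cmax_total) & cmax_total < 0)) {
    stop("cmax_total must be nonnegative", call. = FALSE)
  }
  cmax_total * (1 - ppb)
}

# log-spaced concentration grid spanning the configured multiples of the
# affinity
engagement_grid <- function(affinity, grid = default_config()$curve_grid) {
  10^seq(log10(grid$lower_mult * affinity),
         log10(grid$upper_mult * affinity),
         length.out = grid$n)
}

#' Evaluate a drug's concentration-response profile
#'
#' Builds the full engagement curve over a log-spaced concentration grid
#' and, when exposure data are available, the engagement at the unbound
#' Cmax and the exposure-to-affinity margin `Cmax,u / affinity`. Missing
#' Cmax or protein binding propagate as missing outputs — the curve is
#' still produced, mirroring how incomplete drugs are displayed.
#'
#' @param profile a list or one-row data frame with `affinity_nM`
#'   (required), and optionally `ppb` (bound fraction), `cmax_total_nM`,
#'   `e_max` (default 1).
#' @param config configuration list supplying `curve_grid`.
#' @return An object of class `"engagement_result"`: a list with `curve`
#'   (tibble of `concentration_nM`, `engagement`), `engagement_at_cmaxu`,
#'   `margin`, `cmax_unbound_nM` (each `NA` when inputs are missing).
#' @export
evaluate_profile <- function(profile, config = default_config()) {
  affinity <- profile$affinity_nM
  if (is.null(affinity) || is.na(affinity)) {
    stop("evaluate_profile needs a harmonised affinity (affinity_nM)",
         call. = FALSE)
  }
  e_max <- profile$e_max %||% 1
  if (is.na(e_max)) e_max <- 1
  conc <- engagement_grid(affinity, config$curve_grid)
  curve <- tibble::tibble(
    concentration_nM = conc,
    engagement = fractional_engagement(conc, affinity, e_max)
  )
  ppb <- profile$ppb %||% NA_real_
  cmax <- profile$cmax_total_nM %||% NA_real_
  if (!is.na(ppb) && !is.na(cmax)) {
    cmax_u <- unbound_cmax(cmax, ppb)
    eng <- fractional_engagement(cmax_u, affinity, e_max)
    margin <- cmax_u / affinity
  } else {
    cmax_u <- NA_real_
    eng <- NA_real_
    margin <- NA_real_
  }
  structure(
    list(curve = curve, engagement_at_cmaxu = eng, margin = margin,
         cmax_unbound_nM = cmax_u, affinity_nM = affinity, e_max = e_max),
    class = "engagement_result"
  )
}

#' @export
print.engagement_result <- function(x, ...) {
  cat("<engagement_result>\n")
  cat("  affinity: ", format(x$affinity_nM), " nM (Emax = ", x$e_max, ")\n",
      sep = "")
  if (is.na(x$engagement_at_cmaxu)) {
    cat("  exposure data missing: curve only\n")
  } else {
    cat("  Cmax,u: ", format(x$cmax_unbound_nM), " nM;  engagement ",
        format(round(x$engagement_at_cmaxu, 3)), ";  margin ",
        format(signif(x$margin, 3)), "\n", sep = "")
  }
  cat("  curve: ", nrow(x$curve), " points over [",
      format(signif(min(x$curve$concentration_nM), 3)), ", ",
      format(signif(max(x$curve$concentration_nM), 3)), "] nM\n", sep = "")
  invisible(x)
}

#' Build harmonised per-drug pharmacology profiles
#'
#' Takes classified drug entries (one row per drug, carrying the raw
#' affinity / Cmax quantity strings and protein binding of the annotation
#' backing the panel assignment) and produces the harmonised profile used
#' by all downstream computations: affinity in nM (median over multiple
#' reported values), fraction unbound, total and unbound Cmax in nM,
#' engagement at Cmax,u, the margin `Cmax,u / affinity`, and a completeness
#' flag.
#'
#' @param entries tibble with columns `generic_name`, `affinity`, `ppb`,
#'   `cmax`, `molecular_weight` (quantity strings may be `;`-separated).
#' @param config configuration list.
#' @return The input with added columns `affinity_nM`, `fu`,
#'   `cmax_total_nM`, `cmax_unbound_nM`, `engagement_at_cmaxu`, `margin`,
#'   `complete`.
#' @export
build_pharm_profiles <- function(entries, config = default_config()) {
  n <- nrow(entries)
  affinity_nM <- numeric(n)
  cmax_total_nM <- numeric(n)
  for (i in seq_len(n)) {
    mw <- entries$molecular_weight[[i]] %||% NA_real_
    affinity_nM[i] <- harmonize_quantity_field(entries$affinity[[i]], mw)
    cmax_total_nM[i] <- harmonize_quantity_field(entries$cmax[[i]], mw)
  }
  ppb <- entries$ppb
  out <- entries
  out$affinity_nM <- affinity_nM
  out$fu <- 1 - ppb
  out$cmax_total_nM <- cmax_total_nM
  out$cmax_unbound_nM <- ifelse(is.na(ppb) | is.na(cmax_total_nM),
                                NA_real_, cmax_total_nM * (1 - ppb))
  # same algebra as fractional_engagement(), with NA propagation per row
  out$engagement_at_cmaxu <- out$cmax_unbound_nM /
    (affinity_nM + out$cmax_unbound_nM)
  out$margin <- ifelse(is.na(out$cmax_unbound_nM) | is.na(affinity_nM),
                       NA_real_, out$cmax_unbound_nM / affinity_nM)
  out$complete <- !is.na(affinity_nM) & !is.na(ppb) & !is.na(cmax_total_nM)
  out
}
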