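#' @title Concern and severity scales
#' @description The four cardiotoxicity concern categories and the severity
#'   qualifiers, ordered from most to least severe. The ordering drives
#'   conflict resolution when duplicate entries for one generic drug
#'   disagree: the more severe label is retained.
#' @return Character vector of levels, most severe first.
#' @export
concern_levels <- function() c("most", "less", "ambiguous", "no")

#' @rdname concern_levels
#' @export
severity_levels <- function() c("severe", "moderate", "mild", "none")

toxicity_type_levels <- function() c("arrhythmia", "heart_damage", "mixed", "none")

# Map a free-text concern label onto the four-category scale; NA if it
# cannot be mapped. Matching is insensitive to case, punctuation and the
# word "concern" ("Most concern", "most-concern", "MOST" all map to "most").
normalize_concern <- function(x) {
  key <- stringr::str_squish(stringr::str_replace_all(tolower(x), "[^a-z]+", " "))
  key <- stringr::str_remove_all(key, "\\bdict\\b|\\bconcern\\b|\\bcategory\\b")
  key <- stringr::str_squish(key)
  out <- rep(NA_character_, length(x))
  out[stringr::str_detect(key, "\\bmost\\b|\\bhigh(est)?\\b")] <- "most"
  out[stringr::str_detect(key, "\\bless\\b|\\blow\\b")] <- "less"
  out[stringr::str_detect(key, "\\bambig")] <- "ambiguous"
  out[is.na(out) & stringr::str_detect(key, "^no$|\\bno\\b|\\bnone\\b")] <- "no"
  out
}

normalize_severity <- function(x) {
  key <- tolower(stringr::str_squish(as.character(x)))
  out <- rep("none", length(x))
  out[stringr::str_detect(key, "severe")] <- "severe"
  out[stringr::str_detect(key, "moderate")] <- "moderate"
  out[stringr::str_detect(key, "mild")] <- "mild"
  out[is.na(key) | key == ""] <- "none"
  out
}

normalize_toxicity_type <- function(x) {
  key <- tolower(stringr::str_squish(as.character(x)))
  out <- rep("none", length(x))
  out[stringr::str_detect(key, "arrhythm")] <- "arrhythmia"
  out[stringr::str_detect(key, "damage")] <- "heart_damage"
  out[stringr::str_detect(key, "mixed|both")] <- "mixed"
  out[is.na(key) | key == ""] <- "none"
  out
}

#' Normalise a drug name to its generic form
#'
#' Lowercases, trims, and strips configured salt / ester / formulation
#' tokens (e.g. "citrate", "hydrochloride", "18F") from the tail of the
#' name, so that trade-name and salt-form rows of the same active drug
#' collapse onto one generic name. The operation is idempotent.
#'
#' @param raw_name character vector of drug names; must be non-empty strings.
#' @param suffix_tokens character vector of tail tokens to strip; defaults
#'   to the list in [default_config()].
#' @return Character vector of normalised generic names.
#' @export
#' @examples
#' normalize_drug_name("Sildenafil citrate")  # "sildenafil"
#' normalize_drug_name("morphine")            # unchanged
normalize_drug_name <- function(raw_name,
                                suffix_tokens = default_config()$suffix_tokens) {
  if (length(raw_name) == 0L || any(is.na(raw_name)) ||
      any(!nzchar(stringr::str_squish(raw_name)))) {
    stop("drug names must be non-empty strings", call. = FALSE)
  }
  suffixes <- tolower(suffix_tokens)
  vapply(raw_name, function(nm) {
    tokens <- stringr::str_split_1(stringr::str_squish(tolower(nm)), "\\s+")
    while (length(tokens) > 1L && tokens[length(tokens)] %in% suffixes) {
      tokens <- tokens[-length(tokens)]
    }
    paste(tokens, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Resolve config header aliases against the actual header (case-insensitive,
# whitespace-squished). Returns the matching column name or NA.
match_column <- function(header, aliases) {
  norm <- stringr::str_squish(tolower(header))
  hit <- which(norm %in% stringr::str_squish(tolower(aliases)))
  if (length(hit) == 0L) NA_character_ else header[hit[1L]]
}

read_delimited <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheet files requires the 'readxl' package; ",
           "export the sheet to CSV instead", call. = FALSE)
    }
    return(tibble::as_tibble(readxl::read_excel(path)))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    stop("input file is empty: ", path, call. = FALSE)
  }
  if (ext == "tsv" || grepl("\t", first)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

split_keywords <- function(x) {
  lapply(as.character(x), function(k) {
    if (is.na(k) || !nzchar(stringr::str_squish(k))) {
      return(character(0))
    }
    stringr::str_squish(stringr::str_split_1(k, "[;,|]"))
  })
}

#' Parse a DICTrank-style drug table
#'
#' Reads a delimited (CSV/TSV; optionally XLSX) table of concern-labelled
#' drugs and returns one normalised record per row: the raw name, the
#' generic name (salt/trade suffixes stripped), the four-category concern
#' label, severity, toxicity type, and adverse-event keywords. Header names
#' are matched case-insensitively against the aliases in
#' `config$columns`; only the name and concern columns are mandatory.
#'
#' Rows whose concern label cannot be mapped onto the four-category scale
#' are excluded from the returned records but reported in the
#' `"unmapped_concern"` attribute (and via a warning) rather than silently
#' dropped.
#'
#' @param path path to the table.
#' @param config configuration list (see [default_config()]); supplies
#'   header aliases and the suffix-token list.
#' @return A tibble of drug records with columns `raw_name`,
#'   `generic_name`, `concern`, `severity`, `toxicity_type`, `keywords`
#'   (list-column). Attribute `"unmapped_concern"` holds any rows with
#'   unrecognised concern labels.
#' @export
parse_dictrank_table <- function(path, config = default_config()) {
  raw <- read_delimited(path)
  if (nrow(raw) == 0L) {
    stop("input file has a header but no rows: ", path, call. = FALSE)
  }
  header <- names(raw)
  cols <- config$columns
  name_col <- match_column(header, cols$raw_name)
  concern_col <- match_column(header, cols$concern)
  if (is.na(name_col)) {
    stop("no drug-name column found; expected one of: ",
         paste(cols$raw_name, collapse = ", "), call. = FALSE)
  }
  if (is.na(concern_col)) {
    stop("no concern column found; expected one of: ",
         paste(cols$concern, collapse = ", "), call. = FALSE)
  }
  severity_col <- match_column(header, cols$severity)
  type_col <- match_column(header, cols$toxicity_type)
  kw_col <- match_column(header, cols$keywords)

  records <- tibble::tibble(
    raw_name = as.character(raw[[name_col]]),
    generic_name = normalize_drug_name(as.character(raw[[name_col]]),
                                       config$suffix_tokens),
    concern = normalize_concern(as.character(raw[[concern_col]])),
    severity = if (is.na(severity_col)) "none" else
      normalize_severity(raw[[severity_col]]),
    toxicity_type = if (is.na(type_col)) "none" else
      normalize_toxicity_type(raw[[type_col]]),
    keywords = if (is.na(kw_col)) rep(list(character(0)), nrow(raw)) else
      split_keywords(raw[[kw_col]])
  )

  bad <- is.na(records$concern)
  unmapped <- records[bad, , drop = FALSE]
  records <- records[!bad, , drop = FALSE]
  if (nrow(unmapped) > 0L) {
    warning(nrow(unmapped), " row(s) had unrecognised concern labels and were ",
            "excluded; see attr(, \"unmapped_concern\")", call. = FALSE)
  }
  attr(records, "unmapped_concern") <- unmapped
  records
}

#' Consolidate duplicate drug records to unique generic names
#'
#' Collapses rows sharing a generic name (trade-name or salt-form
#' duplicates) into a single record. When duplicates disagree, the more
#' severe concern (most > less > ambiguous > no) and the more severe
#' severity are retained — safety screening should not understate risk —
#' and every such conflict is recorded in the `"conflicts"` attribute.
#' Keywords are unioned; two distinct non-"none" toxicity types collapse to
#' "mixed".
#'
#' @param records drug-record tibble from [parse_dictrank_table()].
#' @return Tibble with one row per `generic_name`, carrying a
#'   `"conflicts"` attribute listing each name whose duplicates disagreed
#'   on concern or severity.
#' @export
consolidate_records <- function(records) {
  if (nrow(records) == 0L) {
    out <- records
    attr(out, "conflicts") <- tibble::tibble(generic_name = character(0),
                                             field = character(0),
                                             values = character(0))
    return(out)
  }
  c_lv <- concern_levels()
  s_lv <- severity_levels()
  grouped <- dplyr::group_by(records, .data$generic_name)
  out <- dplyr::summarise(
    grouped,
    raw_name = .data$raw_name[[1L]],
    concern = c_lv[min(match(.data$concern, c_lv))],
    severity = s_lv[min(match(.data$severity, s_lv))],
    toxicity_type = {
      tt <- setdiff(unique(.data$toxicity_type), "none")
      if (length(tt) == 0L) "none" else if (length(tt) == 1L) tt else "mixed"
    },
    keywords = list(unique(unlist(.data$keywords))),
    .groups = "drop"
  )
  out <- dplyr::relocate(out, "raw_name", .before = "generic_name")

  conflict_rows <- dplyr::summarise(
    grouped,
    concern_conflict = dplyr::n_distinct(.data$concern) > 1L,
    severity_conflict = dplyr::n_distinct(.data$severity) > 1L,
    concern_values = paste(sort(unique(.data$concern)), collapse = "/"),
    severity_values = paste(sort(unique(.data$severity)), collapse = "/"),
    .groups = "drop"
  )
  conflicts <- dplyr::bind_rows(
    tibble::tibble(
      generic_name = conflict_rows$generic_name[conflict_rows$concern_conflict],
      field = "concern",
      values = conflict_rows$concern_values[conflict_rows$concern_conflict]
    ),
    tibble::tibble(
      generic_name = conflict_rows$generic_name[conflict_rows$severity_conflict],
      field = "severity",
      values = conflict_rows$severity_values[conflict_rows$severity_conflict]
    )
  )
  attr(out, "conflicts") <- conflicts
  out
}

#' Parse a pharmacology annotation table
#'
#' Reads the per-drug target annotation table: target name and class, mode
#' of action, one or more affinity values with units (separated by `;`),
#' plasma protein binding (bound fraction in \[0, 1\]), total Cmax with
#' units, and molecular weight in g/mol. Drug names are normalised with the
#' same suffix-stripping rule as the DICTrank table so the two join.
#'
#' @param path path to the table.
#' @param config configuration list.
#' @return Tibble with columns `generic_name`, `target_name`,
#'   `target_class`, `mode`, `affinity` (character; `;`-separated quantity
#'   strings), `ppb`, `cmax` (quantity string), `molecular_weight`.
#' @export
parse_annotation_table <- function(path, config = default_config()) {
  raw <- read_delimited(path)
  header <- names(raw)
  cols <- config$annotation_columns
  pick <- function(field, required = FALSE) {
    col <- match_column(header, cols[[field]])
    if (required && is.na(col)) {
      stop("annotation table lacks a ", field, " column; expected one of: ",
           paste(cols[[field]], collapse = ", "), call. = FALSE)
    }
    if (is.na(col)) rep(NA, nrow(raw)) else raw[[col]]
  }
  ppb <- suppressWarnings(as.numeric(pick("ppb")))
  if (any(!is.na(ppb) & (ppb < 0 | ppb > 1))) {
    stop("plasma protein binding values must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    generic_name = normalize_drug_name(as.character(pick("generic_name", TRUE)),
                                       config$suffix_tokens),
    target_name = as.character(pick("target_name")),
    target_class = as.character(pick("target_class", TRUE)),
    mode = as.character(pick("mode")),
    affinity = as.character(pick("affinity")),
    ppb = ppb,
    cmax = as.character(pick("cmax")),
    molecular_weight = suppressWarnings(as.numeric(pick("molecular_weight")))
  )
}

#' Join drug records with their pharmacology annotations
#'
#' Left-joins annotations onto drugs by generic name. Every drug is kept:
#' drugs without an annotation get `annotation_status = "unannotated"`.
#' Annotations whose generic name matches no drug are excluded from the
#' result but listed in the `"unmatched_annotations"` attribute.
#'
#' @param drugs consolidated drug records ([consolidate_records()]).
#' @param annotations annotation tibble ([parse_annotation_table()]).
#' @return Joined tibble (one row per drug-target pair, or per drug when
#'   unannotated) with an `annotation_status` column.
#' @export
merge_annotations <- function(drugs, annotations) {
  dup <- duplicated(annotations[c("generic_name", "target_name")])
  if (any(dup)) {
    stop("duplicate annotation keys for: ",
         paste(unique(annotations$generic_name[dup]), collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::left_join(drugs, annotations, by = "generic_name")
  joined$annotation_status <- ifelse(is.na(joined$target_class),
                                     "unannotated", "annotated")
  unmatched <- annotations[!annotations$generic_name %in% drugs$generic_name, ,
                           drop = FALSE]
  if (nrow(unmatched) > 0L) {
    warning(nrow(unmatched), " annotation(s) matched no drug; see ",
            "attr(, \"unmatched_annotations\")", call. = FALSE)
  }
  attr(joined, "unmatched_annotations") <- unmatched
  joined
}
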