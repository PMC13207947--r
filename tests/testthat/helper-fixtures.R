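# In-code fixtures shared across test files.

# write a small DICTrank-style CSV and return its path
write_toy_dictrank <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

toy_dictrank_rows <- function() {
  tibble::tibble(
    `Compound Name` = c("Sildenafil citrate", "Metoprolol tartrate",
                        "Amoxicillin", "Placebozumab"),
    `DICT Concern Category` = c("Most Concern", "Less Concern",
                                "No Concern", "Ambiguous Concern"),
    Severity = c("severe", "mild", "", "moderate"),
    `Toxicity Type` = c("arrhythmia", "heart damage", "", "mixed"),
    Keywords = c("QT prolongation; hypotension", "bradycardia", "", "edema")
  )
}

toy_annotation_rows <- function() {
  tibble::tibble(
    generic_name = c("sildenafil", "metoprolol"),
    target_name = c("PDE5", "beta-1 adrenoceptor"),
    target_class = c("phosphodiesterase", "adrenergic receptor"),
    mode = c("antagonist_or_inhibitor", "antagonist_or_inhibitor"),
    affinity = c("3.5 nM", "0.1 uM"),
    ppb = c(0.96, 0.12),
    cmax = c("440 ng/mL", "0.5 uM"),
    molecular_weight = c(474.6, 267.4)
  )
}

# classified entries derived straight from a synthetic ground-truth table,
# bypassing file I/O, for fast randomized checks
entries_from_truth <- function(truth) {
  tibble::tibble(
    generic_name = truth$generic_name,
    concern = truth$concern,
    severity = truth$severity,
    panel = truth$true_class,
    margin = truth$margin,
    engagement_at_cmaxu = truth$margin / (1 + truth$margin)
  )
}

small_synthetic_config <- function(seed, n = c(most = 30L, less = 40L,
                                               ambiguous = 10L, no = 30L)) {
  synthetic_config(n_per_concern = n, duplicates_per_concern = NULL,
                   duplicate_rate = 0.05, seed = seed)
}
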