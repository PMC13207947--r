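#' Default pipeline configuration
#'
#' Returns the configuration list used by the ingest, classification and
#' summary steps. Everything a site might need to edit lives here rather
#' than in code: the header-to-field mapping for DICTrank-style tables, the
#' salt/ester suffix tokens stripped during name normalisation, the QT /
#' Torsades keyword list that triggers a-priori hERG panel assignment, the
#' free-text synonyms recognised for each target class, and the curve-grid
#' and margin-binning conventions.
#'
#' @details
#' The configuration is an ordinary named list and can be serialised to and
#' from YAML with [write_config()] and [read_config()]. Site overrides are
#' merged shallowly per top-level key: supplying `suffix_tokens` replaces the
#' whole token vector.
#'
#' Key entries:
#' \describe{
#'   \item{columns}{named list mapping each drug-record field to the header
#'     names (case-insensitive) accepted for it.}
#'   \item{suffix_tokens}{salt, ester and formulation tokens stripped from
#'     the tail of drug names (e.g. `"citrate"`, `"hydrochloride"`,
#'     `"18f"`).}
#'   \item{qt_terms}{case-insensitive substrings of adverse-event keywords
#'     that force assignment to the hERG panel.}
#'   \item{class_synonyms}{named list mapping canonical target-class keys to
#'     recognised free-text spellings.}
#'   \item{aggregate}{how multiple reported values for one quantity are
#'     combined; only `"median"` is currently implemented.}
#'   \item{curve_grid}{log-spaced concentration grid for engagement curves:
#'     `n` points from `lower_mult * affinity` to `upper_mult * affinity`.}
#'   \item{margin_bin_edges}{bin edges (on the margin scale) for the
#'     severity-versus-margin frequency table; defaults to integer powers of
#'     ten from 1e-4 to 1e2, with open outer bins.}
#'   \item{fu_impute}{fraction unbound assumed when plasma protein binding
#'     is missing in the sensitivity analysis (default 0.5).}
#' }
#'
#' @return A named list.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  list(
    columns = list(
      raw_name      = c("raw_name", "compound name", "drug name", "name",
                        "trade name", "product name"),
      concern       = c("concern", "dict concern", "dictrank concern category",
                        "dict concern category", "concern category"),
      severity      = c("severity", "dict severity", "severity category"),
      toxicity_type = c("toxicity_type", "toxicity type",
                        "type of cardiotoxicity", "cardiotoxicity type"),
      keywords      = c("keywords", "keyword", "adverse event keywords",
                        "label keywords")
    ),
    annotation_columns = list(
      generic_name     = c("generic_name", "generic name", "drug", "name"),
      target_name      = c("target_name", "target name", "target"),
      target_class     = c("target_class", "target class", "class"),
      mode             = c("mode", "mode of action", "moa", "action"),
      affinity         = c("affinity", "affinity_values", "affinity values",
                           "ec50/ic50", "potency"),
      ppb              = c("ppb", "plasma protein binding",
                           "protein binding", "fraction bound"),
      cmax             = c("cmax", "cmax_total", "total cmax",
                           "maximum plasma concentration"),
      molecular_weight = c("molecular_weight", "molecular weight", "mw")
    ),
    suffix_tokens = c(
      "citrate", "hydrochloride", "hcl", "dihydrochloride", "sodium",
      "potassium", "calcium", "sulfate", "sulphate", "maleate", "tartrate",
      "bitartrate", "mesylate", "besylate", "tosylate", "fumarate",
      "succinate", "phosphate", "diphosphate", "acetate", "propionate",
      "valerate", "palmitate", "stearate", "lactate", "gluconate",
      "carbonate", "nitrate", "bromide", "chloride", "iodide", "oxalate",
      "salicylate", "benzoate", "embonate", "pamoate", "hydrobromide",
      "dihydrate", "monohydrate", "trihydrate", "hemihydrate", "anhydrous",
      "disodium", "dipotassium", "tromethamine", "meglumine", "18f", "123i",
      "131i", "99mtc"
    ),
    qt_terms = c("qt", "torsade"),
    class_synonyms = list(
      herg = c("herg", "herg/potassium channel", "potassium channel",
               "herg channel", "kv11.1", "ikr"),
      adrenergic = c("adrenergic receptor", "adrenergic", "adrenoreceptor",
                     "adrenoceptor", "alpha adrenergic receptor",
                     "beta adrenergic receptor"),
      dopamine = c("dopamine receptor", "dopamine"),
      serotonin = c("serotonin receptor", "serotonin", "5-ht receptor",
                    "5ht receptor"),
      androgen = c("androgen receptor", "androgen"),
      sex_hormone = c("sex hormone receptor", "sex hormone",
                      "estrogen receptor", "progesterone receptor"),
      opioid = c("opioid receptor", "opioid"),
      cyclooxygenase = c("cyclooxygenase", "cox", "cox-1", "cox-2"),
      sodium_channel = c("sodium channel", "na channel", "nav1.5"),
      calcium_channel = c("calcium channel", "ca channel", "l-type calcium channel"),
      muscarinic = c("muscarinic receptor", "muscarinic",
                     "acetylcholine receptor (muscarinic)"),
      glucocorticoid = c("glucocorticoid receptor", "glucocorticoid"),
      phosphodiesterase = c("phosphodiesterase", "pde", "pde5", "pde3"),
      topoisomerase = c("topoisomerase", "topoisomerase ii", "topoisomerase i"),
      ace = c("ace", "angiotensin-converting enzyme",
              "angiotensin converting enzyme"),
      at1 = c("at1", "at1 receptor", "angiotensin ii type 1 receptor",
              "angiotensin receptor"),
      monoamine_transporter = c("monoamine transporter", "net", "sert", "dat",
                                "norepinephrine transporter",
                                "serotonin transporter", "dopamine transporter"),
      acetylcholinesterase = c("acetylcholinesterase", "ache"),
      antibacterial = c("antibacterial", "antibiotic"),
      antiviral = c("antiviral"),
      antifungal = c("antifungal"),
      antiparasitic = c("antiparasitic", "antimalarial", "anthelmintic"),
      antidiabetic = c("antidiabetic", "antihyperglycemic"),
      antihistamine = c("antihistamine", "histamine receptor", "h1 receptor"),
      statin = c("statin", "hmg-coa reductase", "lipid lowering"),
      antineoplastic = c("antineoplastic", "antineoplastics", "cytotoxic"),
      gaba = c("gaba", "gaba receptor", "gaba-a receptor", "gabaergic"),
      vegfr_egfr = c("vegfr_egfr", "vegfr", "egfr", "vegfr/egfr",
                     "vegfr/egfr inhibitor"),
      anticoagulant_antiplatelet = c("anticoagulant_antiplatelet",
                                     "anticoagulant", "antiplatelet",
                                     "anticoagulant-antiplatelet"),
      other = c("other", "miscellaneous"),
      no_pharmacological_target = c("no_pharmacological_target", "no target",
                                    "none", "no pharmacological target")
    ),
    aggregate = "median",
    curve_grid = list(n = 200L, lower_mult = 1e-2, upper_mult = 1e4),
    margin_bin_edges = 10^(-4:2),
    fu_impute = 0.5
  )
}

#' Read a configuration file
#'
#' Loads a YAML configuration and merges it over [default_config()]:
#' any top-level key present in the file replaces the default wholesale.
#'
#' @param path path to a YAML file; `NULL` returns the defaults unchanged.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  for (key in names(user)) {
    cfg[[key]] <- user[[key]]
  }
  cfg
}

#' Write a configuration file
#'
#' @param config configuration list, e.g. from [default_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
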