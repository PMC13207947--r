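---
title: "Target-engagement screening for cardiotoxicity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-engagement screening for cardiotoxicity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dictox)
```

## The scientific problem

Cardiac and hemodynamic liabilities are among the commonest reasons drug
candidates fail. Long before clinical data exist, three quantities are
routinely measurable or predictable: a candidate's in vitro affinity for a
pharmacological target (EC50 for agonists, IC50 for antagonists and
inhibitors), its expected peak plasma concentration (Cmax), and its plasma
protein binding. `dictox` turns these into a screening-oriented risk
readout: how much of a cardiovascular risk target will the drug engage at
clinically realistic free exposure, and how does that compare with drugs
whose cardiac-safety record is known from labelling?

The reference population the package is built around is a DICTrank-style
table: drugs labelled with one of four cardiotoxicity concern categories
(most, less, no, ambiguous), a severity qualifier (mild, moderate,
severe), a toxicity type, and adverse-event keywords.

## The engagement model and its assumptions

Engagement at free concentration $C$ is the hyperbolic Emax model

$$E(C) = \frac{E_{max}\,C}{EC_{50} + C},$$

with three deliberate simplifications:

- **$E_{max} = 1$ for every drug.** The maximal-effect parameter is fixed
  at full engagement, so curves are comparable across drugs and the only
  drug-specific parameter is the affinity. This symbolises complete
  target occupancy at saturation rather than any measured efficacy.
- **Hill coefficient 1, not configurable.** The hyperbola is the model;
  steeper or shallower empirical curves are out of scope.
- **Agonists and antagonists are treated identically.** The mode of
  action is carried as metadata only; EC50 and IC50 enter the same
  formula.

The clinically relevant exposure is the unbound peak concentration
$C_{max,u} = C_{max}(1-\mathrm{ppb})$. Two consequences of the algebra are
used as invariants throughout the test suite: engagement depends on
$(C, EC_{50})$ only through their ratio, and $C_{max,u} \ge EC_{50}$
(margin ≥ 1) holds exactly when engagement at $C_{max,u} \ge 0.5$.

A real limitation inherited by anything built on this model: for
intracellular targets, unbound *plasma* concentration can misrepresent
exposure at the site of action, and active metabolites are not modelled.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| affinity (EC50/IC50) | nM | — (data) | harmonised to nM; median over multiple reported values |
| Cmax | nM | — (data) | mass-per-volume inputs converted via molecular weight |
| ppb (bound fraction) | fraction | — (data) | fu = 1 − ppb |
| `e_max` | — | 1 | comparability across drugs |
| curve grid | nM | 200 log-spaced points, $10^{-2}$–$10^{4}\times$ affinity | spans negligible-to-saturating engagement for any drug; a repository convention, configurable |
| margin bins | log10 | integer powers of ten, $10^{-4}$–$10^{2}$, open outer bins | severity-vs-margin frequency table |
| `fu_impute` | fraction | 0.5 | sensitivity analysis for missing protein binding |

Unit harmonisation uses exact decimal factors for molar units and
`nM = mg/L / MW × 10^6` for mass-per-volume units; a mass unit without a
molecular weight is a loud error, not a silent skip, so data problems
surface at ingest. Multiple reported values are aggregated by the median
(midpoint for even counts — the conventional, deterministic choice), and
the same rule is applied uniformly to affinity, Cmax and protein binding.

## Ingest, consolidation and classification choices

- **Name normalisation** lowercases and strips configured salt / ester /
  formulation tokens from the tail of the name ("sildenafil citrate" →
  "sildenafil"). The token list is configuration, not code, and the
  operation is idempotent.
- **Duplicate consolidation** keeps, when duplicated rows disagree, the
  *more severe* concern and severity. Neither label source defines the
  resolution rule; a safety screen should not understate risk, and every
  conflict is logged for audit. Distinct toxicity types collapse to
  "mixed". Rows with unmappable concern labels are excluded but reported.
- **Panel assignment** applies, in order: a manual-correction table (the
  shipped one moves moxifloxacin to the hERG panel and probenecid to
  "other"), then the a-priori hERG rule — any hERG-class annotation *or*
  a QT/Torsades keyword forces the hERG panel, matched as a
  case-insensitive substring over a configurable term list seeded with
  "QT" and "Torsade" — then the first annotated class. Multi-target drugs
  therefore resolve to hERG first, else their first listed class.
- **Tier membership.** Tier 1 counts a drug as mapped whenever its panel
  is anything but "other" or "no pharmacological target" — including the
  broad therapeutic classes, which is what makes the tier-1 → tier-2
  arithmetic of the published counts consistent. Tier 2 removes the broad
  therapeutic classes (a configurable list: antibacterials, antivirals,
  antifungals, antiparasitics, antidiabetics, antihistamines, statins;
  treated as possibly non-exhaustive). Tier 3 further removes
  antineoplastics, GABA-acting drugs, VEGFR/EGFR inhibitors and
  anticoagulants/antiplatelets. Membership is monotone by construction.
- **Percentages** are rounded to the nearest integer (half away from
  zero), matching the reporting style of the summaries the package
  reproduces.

The summaries are deliberately descriptive: no tests, confidence
intervals or models are produced, because the association being
summarised is a screening heuristic, not an inferential claim.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` exists so every pipeline stage is testable with
known ground truth and no downloads. Its defaults encode the study
population the pipeline is designed for:

- per-concern sample sizes 327 / 507 / 105 / 328 (most / less / ambiguous
  / no), taken back up to 1318 raw rows by injecting 14 / 21 / 1 / 15
  salt-form duplicate aliases per category;
- per-concern probabilities of carrying a key risk-target class
  0.84 / 0.66 / 0.54 / 0.44, with hERG weighted so that it accounts for
  about 20% of the most-concern group, and small fractions of mapped
  drugs placed in broad-therapeutic and tier-3 exclusion classes;
- data availability 81.1% (protein binding), 73.8% (affinity), 53.5%
  (Cmax), applied element-wise;
- lognormal affinity (median 100 nM, sdlog 1.5) and Cmax (median 300 nM,
  sdlog 1.2), Beta(5, 2) bound fraction. No distributional forms are
  published for these quantities; lognormal concentrations and a
  Beta-distributed bound fraction are the standard pharmacology choices,
  and these parameters span margins well above and below 1 so both sides
  of the decision boundary are exercised;
- severity coupled to the true margin through a Binomial(2, p) draw with
  p a logistic function of log10 margin, so the severity-versus-margin
  trend is recoverable by the summary statistics.

What it does **not** emulate: real drug names or real per-drug
pharmacology, correlations between affinity and exposure induced by dose
selection, assay-to-assay affinity variability, class-specific exposure
distributions, or label-text noise. Passing tests on synthetic data
therefore demonstrate that the *pipeline machinery* is correct and that
configured structure is recovered at the expected statistical precision —
they do not validate the biological claim that the 18 target classes
predict cardiotoxicity for new chemical matter.

## Numerical and degenerate-input conventions

- Engagement is exactly 0 at $C = 0$ and exactly 0.5 at $C = EC_{50}$;
  no tolerance is involved.
- Benchmark ranking sorts by engagement, breaking ties by larger margin
  and then name order, so reports are deterministic and independent of
  reference ordering. An empty reference set yields rank 1 of 1 with a
  warning rather than an error.
- Missing inputs propagate as missing outputs: a drug without Cmax still
  gets its full curve (and appears in classification counts) but
  contributes no engagement or margin; a drug without affinity is
  "curve-only" and is drawn as a dotted horizontal line at evenly spaced
  heights in [0.05, 0.95] — a pure plotting convention, never a numeric
  value.
- The sensitivity analysis imputes fu = 0.5 only for annotated drugs
  (an unannotated drug has no pharmacology to impute into) and never
  changes classification counts — only exposure metrics.
- Empty histograms, empty panels and empty record lists are returned as
  empty structures, not errors.

## Problem sizes used by the test suite

The suite checks the exact published contingency percentages from their
printed numerator/denominator pairs; consolidation on a full-size
(1318-row) generated population; engagement-model properties on 1000+
random cases; brute-force oracle equivalence (contingency, medians,
benchmark ranks, margin histograms) on 100 random datasets of up to ~160
drugs; and parameter recovery on a 10,000-drug population, where
per-concern mapped fractions must fall within three binomial standard
errors of their configured values and the imputation report must match
the masked-value ground truth exactly. These sizes give the binomial
checks enough power to catch calibration errors while keeping the suite
fast to run routinely.

## Known limitations

Drug-level reproduction of any particular published figure set is out of
scope: per-drug annotations behind such figures are not published, so
panels are reproduced structurally (curves, markers, missing-data
conventions), not drug-by-drug. The taxonomy's receptor-subtype structure
(α/β adrenergic, 5-HT subtypes) is not modelled beyond free-text labels.
Trade-name-to-generic resolution beyond suffix stripping requires a
user-supplied synonym table.
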