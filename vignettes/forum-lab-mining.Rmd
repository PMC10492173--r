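---
title: "Mining laboratory results from patient-forum text and testing equivalence with published cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining laboratory results from patient-forum text and testing equivalence with published cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumlabs)
```

## The problem

People with polycystic ovary syndrome (PCOS) — a heterogeneous endocrine
condition affecting a substantial fraction of people with ovaries — discuss
their laboratory results in online support forums in large numbers. Those
posts are a potential research resource: a forum cohort is cheap, large, and
free of the recruitment filters that shape clinical studies. But before such
a cohort can be used it must be validated: do the laboratory values mined
from forum text resemble the values published for research-recruited PCOS
cohorts?

`forumlabs` implements that validation as a reusable, testable pipeline.
Because the raw forum dump cannot be shipped, the package pairs the analysis
stages with a ground-truthed synthetic-forum generator, so every stage —
screening, extraction, quality control, statistics — is exercised offline
under known conditions.

## The equivalence model

Classical significance tests cannot conclude *sameness*; failing to reject
"no difference" is not evidence of none. The package therefore uses the two
one-sided tests (TOST) procedure. For groups summarized by (n, mean, SD),
the equivalence boundary is

$$ b = d \cdot SD_{pooled}, \qquad d = 0.499, $$

a medium Cohen effect size times the degrees-of-freedom-pooled standard
deviation of the two groups. TOST tests the null that the means differ by at
least $b$; rejecting both one-sided nulls (reported p is the larger of the
two one-sided p values) concludes that any difference is smaller than a
medium effect. When equivalence is not concluded, a one-sided pooled
$t$ test assigns a direction (literature lower / higher). Each comparison
thus lands in exactly one of four states: equivalent, literature-lower,
literature-higher, or inconclusive (neither procedure rejects; rare but
representable and logged).

Two modelling choices deserve note:

* **Pooled, not Welch, errors.** The boundary is defined on the pooled SD,
  so the test statistics use pooled-variance errors with
  $df = n_1 + n_2 - 2$ for internal consistency. Welch errors and
  Satterthwaite df are available via `boundary_spec(welch = TRUE)`; for a
  handful of borderline comparisons (e.g. cells with p just above .05
  under pooling) the two error models disagree, which is worth knowing when
  interpreting verdicts near the threshold.
* **Aggregate SD as an input.** The aggregate literature mean is the
  sample-size-weighted mean of study means and the aggregate n is the sum
  over reporting studies — both recomputable from the per-study table. The
  printed aggregate SDs in the source table are *not* recoverable by any
  standard pooling formula, so the package treats them as data: aggregate
  comparisons take the printed SD as an input, and the package's own pooled
  SD across studies is reported in a separate column
  (`agg_pooled_sd_calc`) rather than silently substituted.
* **No multiplicity correction.** The comparisons are exploratory and read
  jointly; α is fixed at .05 throughout.

```{r tost-example}
tost(5.8, 3.1, 214, 5.9, 6.4, 1883)$p
```

## The test catalog

Every stage that reasons about laboratory tests is driven by a JSON catalog
(28 tests: the PCOS panel plus age and BMI). Per test it records synonyms,
the canonical reporting unit, alternate units with multiplicative conversion
factors (e.g. glucose mmol/L × 18.016 → mg/dL; DHEA-S µmol/L × 36.85 →
µg/dL, the factor implied by the standard reference-range pair 59–328 µg/dL
≡ 1.6–8.9 µmol/L), a healthy reference range, and a **condition-plausible
range**: the healthy range widened to admit PCOS-typical dysregulation
(upper bound ×3 for androgen-axis tests — androgens, LH, AMH, fasting
insulin, HOMA-IR — and ×2 otherwise; lower bound halved). A few tests carry
per-catalog overrides where that mechanical rule is clinically too tight:
TSH down to 0.05 mU/L (suppression), prolactin up to 200 ng/mL (mild
hyperprolactinemia), progesterone/estradiol spanning cycle-phase extremes,
ALT up to 500 U/L. The overrides live in the data file, not the code.

The plausible range powers three different decisions:

* **Unit inference for bare numbers.** A number with no unit is interpreted
  under the canonical unit and every alternate; interpretations outside the
  plausible range are discarded. One survivor converts cleanly. Several
  survivors whose canonical values disagree by more than 20% (configurable)
  resolve to the canonical-unit reading when plausible and are flagged
  *uncertain* — progesterone, estradiol, and vitamin D are the classic
  offenders, their common units having large overlapping numeric ranges.
  No survivor is an explicit rejection record, never a silent drop.
* **Mistranscription checks for stated units.** A stated unit whose
  converted value is plausible is accepted — a total testosterone of
  90 ng/dL is high but condition-typical, not an error. A stated unit that
  is implausible triggers reinterpretation only when exactly one accepted
  unit makes the value plausible (a DHEA-S of "8 µg/dL" is only sensible in
  µmol/L); anything else is rejected.
* **Reprocessing.** Values flagged uncertain (or with |z| > 2) are re-run
  through inference once with the plausible bounds widened ×1.5, mirroring
  a second manual look at flagged records.

## The synthetic forum

The generator emulates the statistical and textual structure of a
condition-specific forum, not natural-language fluency. Latent cohorts are
drawn per person: each test included with the prevalence observed in the
forum summary table (the fraction of test sets reporting it), values drawn
from a normal — or, for right-skewed analytes (LH, PRL, fasting insulin,
AMH, progesterone, SHBG, HOMA-IR, whose forum medians sit far below their
means) lognormal — distribution with the forum table's mean and SD,
truncated to the condition-plausible range. Truncating to the plausible
range (rather than merely at zero) makes every embedded value physiologic by
construction, which is the coherent reading of a condition-affected cohort:
with the forum-scale SDs, several analytes would otherwise place a few
percent of draws outside any defensible plausibility bound and extraction
losses would reflect the generator, not the extractor.

Posts are rendered in eight styles mirroring how results actually appear:
full names with units, abbreviations with units, bare numbers, alternate
units (rendered with enough decimals that the round-trip conversion stays
within half an ulp of the canonical precision), mistyped unit labels
(number kept, label swapped — only generated when the swap is unambiguously
recoverable, and kept rare at 2% weight, since real mistranscriptions are
described as exceedingly rare), panels split across two same-day posts,
verbatim reposts weeks later, and distractor posts (no results; some
mention test names without numbers, so the screen cannot win on keywords
alone). The default mix is half distractors; the true style mix of the real
forum is unobserved, so this is declared a free parameter. Timestamps are
uniform over a five-year window; split pairs share a UTC calendar day.
Everything is seeded: identical (spec, arguments, seed) reproduce the corpus
byte for byte.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: colloquial phrasings outside the template
families, medication context, cross-post age references, typos in numbers
(as opposed to units), and comment threads (the analysis uses posts only).
Real-corpus extraction would lean on the same catalog machinery but
recall/precision measured here are upper bounds specific to the synthetic
conditions.

## Screening

Posts are tokenized (lowercase, punctuation stripped, every digit run
mapped to a `<num>` class token; slashes split tokens, so "LH/FSH"
tokenizes as `lh fsh`). Embeddings are fit GloVe-style — weighted least
squares on the log co-occurrence matrix (window 5, 1/distance weighting,
weight cap $x_{max} = 100$, $\alpha = 0.75$, d = 50) by full-batch Adam.
The classifier is the standard small text CNN: frozen embedding lookup,
parallel width-{2,3,4,5} convolutions (32 filters each), ReLU, global max
pooling, one dense sigmoid output, binary cross-entropy, Adam with early
stopping on a stratified held-out split (25%). The architecture is a
deliberate stand-in: it matches the scale appropriate to a training budget
of a few hundred labeled posts. The decision threshold defaults to 0.5.

A keyword-rule baseline (any catalog synonym plus any number) ships
alongside; every downstream stage accepts either model, so pipeline
correctness never hinges on neural training.

## Quality control

Within each test, values flagged uncertain or with |z| > 2 (z against the
test's own mean/SD) are routed to reprocessing; values with |z| > 4 are
removed in a **single pass** against the pre-removal mean and SD. One pass
is the minimal reading of a one-shot cleaning step — iterated trimming would
change removal rates. The 4-sigma allowance is deliberately loose:
dysregulated cohorts produce extreme but genuine values. Summaries cover
tests with at least 20 post-removal observations and report median,
quartiles, and observed extremes as separate fields (the rendered table
prints "median (min–max)", matching the convention of the source tables
whose parenthesized ranges span observed extremes).

## Numerical and degenerate-input choices

* Zero spread (SD = 0) disables z flagging and removal rather than erroring.
* Duplicate detection compares values at 9 significant digits; canonical
  values are exact products of rendered numbers and catalog factors, so
  verbatim reposts collapse reliably.
* Unit strings are normalized (case, spacing, µ→u, IU≡U) before lookup;
  identity-factor aliases (mIU/mL vs U/L) count as one interpretation
  during inference, not two.
* A split-pair render for a person with fewer than two panel tests falls
  back to a single abbreviated post; a mistype with no unambiguous swap
  falls back likewise, and the ground-truth style tag records what was
  actually rendered.
* TOST with a zero boundary (both SDs zero) is refused; a degenerate
  boundary inside the procedure yields "never equivalent" with a flag
  rather than a spurious verdict.
* p values from the analytic `pt` path are verified in the test suite
  against numerical integration of the t density to 10⁻⁶ across a
  thousand randomized inputs.

## Problem sizes used in the test suite

Module tests run on corpora of 80–400 posts with reduced embedding
dimensions and filter counts; the end-to-end acceptance run uses the
default study conditions (2,000 posts, d = 50, 32 filters, 300 labeled
posts), chosen to emulate the scale of the source analysis's screening
budget while remaining a desk-scale experiment. At that scale the screen's
held-out accuracy, end-to-end value recovery (≥ 95% of embedded values
reaching a test set at the correct canonical value), and per-test mean
recovery (within 3 standard errors) are all exercised against generator
truth.

## Known limitations

* The printed aggregate SDs are opaque inputs (see above); verdicts against
  the aggregate inherit whatever convention produced them.
* Extraction patterns are synonym-anchored ("value then name" phrasings are
  not matched); the generator renders within the matchable families, so
  real-corpus recall would be lower.
* Cycle-phase text is captured as free text but deliberately not used to
  normalize hormone values; fasting status of glucose/insulin mentions is
  taken at face value from the matched synonym.
* Ages are taken only from explicit statements; approximating ages from
  other posts by the same account would require account linkage the
  synthetic corpus does not model.
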