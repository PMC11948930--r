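---
title: "Methods: survey-vs-record concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survey-vs-record concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrconcord)
```

# The problem

Longitudinal cohort studies often collect physician-diagnosed conditions by
self-report ("has a doctor or other health professional told you that you
have ...?") while linked electronic health records (EHR) provide coded
diagnoses from clinical encounters. Neither source is a gold standard:
surveys suffer recall error, nonresponse and misunderstanding of diagnostic
labels; records miss care delivered outside the covered systems and depend
on coding practice. `ehrconcord` implements the full comparison pipeline for
this setting: rule-based case ascertainment on both channels, agreement
statistics on the resulting 2x2 tables, harmonization of continuous
(height/weight) and behavioral (smoking, alcohol) measures, and a synthetic
linked-cohort generator with a closed-form oracle so every stage can be
validated against known truth.

# Case ascertainment

## Medical records

An encounter record carries a source (VHA or MDR; purchased-care encounters
are ingested under VHA, since the two are pooled in the source systems), a
setting (inpatient/outpatient), an event date (admission date for inpatient
stays) and diagnosis codes with positions. Codes are normalized by
upper-casing and removing the decimal point; matching against a condition's
code set is by prefix by default — published code lists usually include
truncated parent codes — with an exact mode per entry.

Two criteria are implemented:

* **Sensitive**: one matching code in any diagnostic position, inpatient or
  outpatient, inside the observation window (default 1999-10-01 to
  2020-09-18). The diagnosis date is the earliest matching encounter or
  admission date.
* **Specific**: at least one matching inpatient record, or matching
  outpatient records on at least two *distinct* event dates. The
  distinct-date reading of "two outpatient codes" follows the standard
  claims "rule of two", which exists precisely to discount double-coding
  within a single visit; a switch (`distinct_dates = FALSE`) restores the
  literal two-codes reading. The diagnosis date is the earliest qualifying
  matching date.

A participant positive under specific criteria is always positive under
sensitive criteria on the same records (the specific rule only removes
qualifying configurations), which the test suite verifies against an
exhaustive per-record evaluator.

Temporally restricted analyses only count records strictly *before* a
per-participant reference date: a same-day code cannot be shown to precede
the survey answer, so the boundary is exclusive. Codes flagged as personal
history are excluded there because they carry no usable diagnosis date. The
reference date is the survey date of first self-report for survey-positive
participants and the last completed survey date for survey-negative
participants, so negatives face a comparable look-back; participants missing
at every wave have no anchor and are excluded from the restricted
comparison. Both choices are exposed as data (the reference dates are an
explicit argument of `ascertain_ehr_cohort()`), so the sensitivity of a
result to the anchoring rule can be measured directly.

When VHA and MDR verdicts are merged, the union rule applies: positive if
either source is positive, with the earliest available diagnosis date.

## Surveys

Survey classification is carry-forward: a "yes" for a condition at any wave
makes the participant a positive case from that wave onward, anchored at the
survey date of first self-report; a later "no" does not revoke it (the
follow-up item asks about a recall window, and a diagnosis once reported is
treated as established). A participant who never answers "yes" but answers
"no" at some wave is negative; missing at every wave is missing, and
missing participants are dropped from the 2x2 table rather than imputed.
Baseline ("ever") and follow-up ("past 3 years") items are treated
identically as yes/no evidence, which is exactly what the carry-forward
rule consumes.

# Agreement statistics

With survey status in rows and record status in columns, the retained pairs
form a 2x2 table with cells $a$ (both positive), $b$ (survey only), $c$
(record only), $d$ (both negative), $N = a+b+c+d$. The package computes the
Cicchetti–Feinstein proportions of specific agreement

$$\mathrm{PA} = \frac{2a}{N + (a - d)} = \frac{2a}{2a + b + c}, \qquad
  \mathrm{NA} = \frac{2d}{N - (a - d)} = \frac{2d}{2d + b + c},$$

and Youden's $J = \text{sensitivity} + \text{specificity} - 1$ with the
medical record as the reference standard (sensitivity $a/(a+c)$,
specificity $d/(b+d)$), the orientation used when self-report is evaluated
for its ability to detect recorded diagnoses. $J$ is prevalence-independent,
which the suite property-tests by scaling the table margins. The two
algebraic forms of PA/NA are both implemented and property-tested for
identity. The cells $a$ and $d$ are *concordant* cells, not "true"
positives/negatives — neither channel is a gold standard, so no cell is
privileged as truth.

Undefined statistics (empty margins, e.g. a condition nobody has) are
reported as absent (`NA`), never coerced to 0, to avoid silently biasing
summaries over rare conditions.

## Reconstructing cells from printed tables

Published concordance tables typically print only $N$, the two positive
margins and the rounded statistics. Given the margins, PA depends on the
cells only through $a$, so the set of integer $a$ whose PA rounds
(half-up, one decimal, as a percentage — the convention of printed tables)
to the published value can be enumerated (`reconstruct_cells()`), the
remaining cells filled in from the margins, and NA and $J$ recomputed
(`check_printed_row()`, `validate_printed_table()`). This turns a printed
table into an internal-consistency check without access to the underlying
data. When a single representative value is needed,
`reconstruct_statistics()` uses the candidate whose exact PA is closest to
the printed value — the midpoint of the rounding interval, the least
extreme table consistent with what was printed. The rounded NA and $J$ are
usually, but not always, constant across candidates; the candidate ranges
are returned so stability can be checked rather than assumed.

# Measurements and behaviors

Heights below 48 in or above 95 in and weights below 80 lb or above 500 lb
are dropped as physiologically implausible (strict bounds; boundary values
are retained). One height per participant per source is the modal value,
falling back to the first recorded height when all values are distinct
(modal ties also break toward the earliest-dated modal value, consistent
with that fallback). Weights pair with a survey when measured within 365
days on either side of the survey date — the "within 1 year" window read
symmetrically, with a one-sided switch — taking the measurement closest to
the survey and breaking equidistant ties toward the earlier, pre-survey
measurement, which cannot have been influenced by the survey.

Bland–Altman summaries use differences defined as record minus survey, the
sample SD (denominator $n-1$), and limits of agreement at the mean ±2 SD
exactly (not 1.96); the outside proportion counts pairs strictly beyond a
limit.

Alcohol: survey problem drinking is endorsement of at least 1 of the 5
PHQ risky-drinking items; all five "no" is negative; no endorsement with
any item missing is missing (the unanswered item could have been the
endorsement — a conservative choice, since the alternative fabricates
negatives). The record-side AUDIT-C screen uses the assessment closest in
time *strictly prior* to the survey, same-day duplicates resolved to the
highest score, and sex-specific misuse cutoffs (≥3 women, ≥4 men).
Smoking: ever-smoker from the lifetime-100-cigarettes item with
carry-forward; the record-side status is the assessment closest to the
survey date on *either* side (the prior-only restriction is specific to
AUDIT-C), ties toward the earlier record.

# Utilization categories

Per participant, the observation period runs from the first to the last
VHA encounter at or before the cutoff (2020-09-18). Categories: *regular*
(≥1 encounter/year on average), *irregular* (<1/year on average, ≥1
encounter), *high-frequency* (>1 encounter in every year of the period),
*none*. Two under-determined corners are resolved as follows and exposed
through the profile fields: "every year" is evaluated over consecutive
365.25-day intervals anchored at the first encounter (calendar years would
make the result depend on enrollment phase); the final partial interval is
held to the >1 standard only when it is at least half a year long, and when
no interval qualifies the participant is not high-frequency (no vacuous
passes). Observation time is floored at one year so a single-visit
participant is classifiable (1 encounter / 1 year = regular) instead of
dividing by zero.

# The synthetic cohort generator

The study data this pipeline is designed for are not publicly releasable,
so validation uses simulated cohorts with known truth. The generative model
is deliberately the simplest one whose downstream agreement has a closed
form: per participant and condition, true status $T \sim
\text{Bernoulli}(p)$; the survey channel reports positive with probability
$s_1$ if $T=1$ and $1-c_1$ if $T=0$; the record channel codes the condition
with probability $s_2$ / $1-c_2$; channels are conditionally independent
given $T$. A coupling knob `shared_error_prob` evaluates both channels on
one shared uniform draw with the given probability (preserving the
marginals while correlating errors); it defaults to 0 and the closed form
in `expected_agreement()` covers both cases:

$$P(S{=}1, E{=}1 \mid T) = \rho\,\min(p_S, p_E) + (1-\rho)\, p_S\, p_E .$$

Record-positive participants receive $1 + \text{Poisson}(\mu - 1)$ coded
encounters on uniform dates in the window (so every record-positive case
has at least one code, making the channel flag recoverable by sensitive
ascertainment); all participants receive background encounters with a
non-matching filler code at a Poisson rate per person-year. Encounters are
assigned to MDR with a configurable fraction (default 0.3), to the
inpatient setting with default fraction 0.1, and to 1 of 3 diagnostic
positions. Survey-positive participants first report at a uniformly chosen
responded wave; wave nonresponse (default response probability 0.7) is
independent of truth, so dropping all-missing participants does not bias
the conditional 2x2 probabilities — which is why the closed-form oracle
remains exact for the pipeline estimate.

Default conditions are three archetypes spanning the ranges seen in this
literature — a common chronic condition (prevalence 0.25), a common
symptomatic one (0.18), and a rare one (0.006), with channel sensitivities
0.5–0.8 and specificities 0.93–0.999. Wave dates default to six triennial
waves 2001–2016 inside the 1999-10-01–2020-09-18 window. Heights and
weights: true values N(68, 4) in and N(190, 35) lb; self-report adds a
+0.12 in height bias and a −5.7 lb weight bias plus noise, vitals measure
truth with small device noise — reproducing the familiar pattern of
over-reported height and under-reported weight. Behavior channels use
analogous two-channel error rates. Each output table draws from its own
seeded stream, so adding a table leaves the others byte-identical.

What the generator does *not* emulate: real ICD hierarchies and coding
drift, comorbidity correlations, informative nonresponse, panel sampling
weights, and secular trends in utilization. Passing parameter-recovery
tests therefore demonstrates that the pipeline's logic is faithful to its
stated rules, not that any particular real-world agreement value is
correct.

# Numerical choices and problem sizes

Rounding for printed-precision comparisons is half away from zero
(`round_half_up()`), the convention of formatted tables, not R's default
round-half-even; comparisons happen at one decimal for percentages and two
for $J$. Cell probabilities in the oracle are checked to sum to 1 within
1e-12. Validation runs use a 100,000-participant cohort for parameter
recovery (statistics within 3 binomial standard errors of the closed form),
200,000 latent draws for the dual-positive rate check, and 100 cohorts of
1,000 participants for the criterion/temporality/scope monotonicity sweep;
these sizes put Monte-Carlo error well below the effects being checked
while keeping the default test run fast.

# Known limitations

* The agreement statistics come without confidence intervals (none are
  produced by the source methodology); the reconstruction utilities
  quantify only rounding ambiguity, not sampling error.
* Prefix matching treats a parent code as covering all children; a code
  list that intends exact matching must say so per entry.
* The utilization year-partition is one defensible reading of an
  under-specified rule; profiles expose the raw counts and period so other
  partitions can be computed.
* `expected_agreement()` describes the generator's channel model, not any
  observational dataset; applying it to real data would assume conditional
  independence that real channels likely violate.

# A worked example

```{r example}
cfg <- sim_config(n_participants = 2000, seed = 42)
cohort <- generate_cohort(cfg)
report <- run_concordance(cohort, criterion = "sensitive",
                          temporality = "any", scope = "combined")
format_condition_table(report$conditions)
expected_agreement(cfg, "hypertension")[
  , c("positive_agreement", "negative_agreement", "youden_j")]
```
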