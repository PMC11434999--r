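---
title: "Reporting odds ratio disproportionality and side-effect profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio disproportionality and side-effect profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorsignal)
```

## The problem

Spontaneous adverse-event report databases such as the FDA Adverse Event
Reporting System (FAERS) collect voluntary reports of suspected adverse
drug reactions. They have no denominator — the number of patients actually
exposed to each drug is unknown — so incidence cannot be estimated. What
*can* be estimated is disproportionality: whether a drug-event pair is
reported more often than the rest of the database would predict. The
reporting odds ratio (ROR) is the classical disproportionality statistic.
`rorsignal` implements an end-to-end ROR pipeline motivated by a concrete
question in oncology pharmacovigilance: which antineoplastic agents
(ATC class L01) are disproportionately reported with taste and smell
disorders, and how do their side-effect spectra differ?

Taste and smell disorders matter in chemotherapy because they reduce food
intake and quality of life. They are coded at the MedDRA preferred-term
(PT) level; the package bundles the 14 PTs of the "Taste and smell
disorders" standardized MedDRA query (SMQ 20000046) — seven taste terms
(dysgeusia, ageusia, taste disorder, hypogeusia, gustatory hallucination,
hypergeusia, abnormal gustometry) and seven smell terms (anosmia,
parosmia, hyposmia, olfactory hallucination, olfactory nerve disorder,
abnormal olfactory test, olfactory dysfunction) — excluding congenital
anosmia, which is not a drug effect (`smq_taste_smell()`).

## The data model

FAERS quarterly extracts are dollar-delimited text tables.
`read_faers_table()` ingests the three used here — DEMO (one row per case
version: age, age unit, gender), DRUG (drug mentions per report), REAC
(reaction PTs per report). `deduplicate()` applies the FAERS convention
that later case versions supersede earlier submissions of the same case:
DEMO keeps, per case id, the row with the highest case version (ties
broken by the lexicographically highest primary id); DRUG and REAC
collapse exact-duplicate rows. `build_table_a()` then inner-joins the
three tables on primary id — a report absent from any of the three
carries incomplete information and is excluded — and derives per-report
taste/smell flags by exact case-insensitive PT matching. Drug names are
normalized by case-folding and whitespace collapsing only; no fuzzy
matching is attempted, because public extracts are typically run through
vendor name curation first.

`build_table_b()` derives the demographic table: reports exposed to at
least one exposure-set drug, with age strictly in years (decade codes are
multiplied by ten; months/weeks/days/hours entries are dropped rather than
converted, since sub-year ages in an adult oncology question are almost
always data errors), ages restricted to [0, 120], and gender restricted
to male/female (unknown codes dropped).

## The estimator

For a drug (or drug class, or demographic stratum) and an event PT set,
`make_contingency()` counts distinct reports into the standard 2x2
layout: `a` drug-and-event, `b` drug-without-event, `c` other reports
with event, `d` other reports without. The background is always the full
joined table — all drugs, not only antineoplastics — so the ROR is
anchored against the whole database:

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc}.$$

`ror_test()` is the core estimator and returns a classed object with
`print`, `coef`, and `confint` methods. Three numerical choices matter:

* **Haldane correction.** 0.5 is added to every cell
  (`haldane_correct()`) before computing the ROR and its confidence
  interval, which keeps both finite when cells are zero. The correction
  is applied exactly once; double correction is an error. Note the
  correction does not always pull the odds ratio toward 1 — when the
  discordant cells are small it can push it outward — but the
  perturbation vanishes at screening-scale counts.
* **Exact p from raw counts.** The two-sided Fisher exact p-value
  (`fisher_p()`) is computed on the *uncorrected* integer counts, where
  the conditional hypergeometric test is defined: with margins fixed, the
  p-value is the sum of point probabilities of all tables no more
  probable than the observed one, with the conventional 1e-7 relative
  tolerance for probability ties. The test is implemented as a vectorized
  hypergeometric summation so that screening thousands of drugs is cheap;
  it agrees with `stats::fisher.test()` to 1e-12 and with exhaustive
  enumeration to 1e-10 over every table with total at most 60 (tested).
* **Capped significance.** For volcano plots, `neg_log10_p()` reports
  `-log10(p)` capped at 308; p-values that underflow double precision map
  to the cap.

Wald intervals use `exp(ln ROR ± z sqrt(1/a + 1/b + 1/c + 1/d))`. With the
published demographic cells for the age split (4561, 387134, 8077,
946863) this reproduces ROR 1.381, 95% CI 1.332-1.432 on uncorrected
counts, which is why `stratum_association()` defaults to no correction —
demographic cells are large enough that the correction is immaterial
anyway (1.381134 vs 1.381199).

`disproportionality()` screens every distinct drug against a fixed event
set and flags signals by the conventional criteria *p* < 0.05, ROR > 1,
and at least 100 event reports (all three configurable; the event-count
rule is deliberately `>= 100`). No multiplicity adjustment is applied
across drugs — this mirrors standard ROR screening practice, and users
should treat flagged drugs as hypotheses, not confirmed effects. The
`plot` method draws the volcano (lnROR against capped `-log10 p`).

`class_signal_fraction()` and `class_association()` lift the same
machinery to ATC L01 subclasses (alkylating agents L01A through other
antineoplastics L01X): a report exposed to drugs of several classes
counts as exposed in each class's table, since each class's 2x2 is
constructed independently against the full background.

## Profiling side-effect spectra

`build_lnror_matrix()` assembles the signal-drug x PT matrix of
single-PT lnRORs (Haldane-corrected, hence finite everywhere). Columns
are restricted to SMQ terms with at least `pt_min_reports` reports
database-wide (default 3000, the scale of a full FAERS snapshot, where it
retains dysgeusia, ageusia, taste disorder, anosmia, parosmia,
hypogeusia, and hyposmia and drops the five terms with only hundreds of
reports or fewer); on smaller databases the threshold should be scaled
accordingly.

`ward_cluster()` clusters the rows with Ward's minimum-variance criterion
on Euclidean distances (the Ward.D2 formulation; merge heights equal
`sqrt(2 * deltaSS)`); rows are not re-standardized by default because
lnROR cells already share a scale (a `scale_rows` flag exists). The merge
sequence is verified in the tests against a brute-force agglomeration
that recomputes the within-cluster sum-of-squares increase of every
candidate merge from scratch.

`lnror_pca()` performs PCA on the column correlation matrix (columns
centred and scaled). Because eigenvector signs are arbitrary, components
are oriented deterministically: each component's largest-magnitude
loading is made positive, or the first component can instead be oriented
against an external vector (e.g. the overall per-drug lnROR) via
`orient`. `interpret_components()` correlates component scores with the
PT columns — the standard way of naming components (overall risk,
taste-versus-smell contrast, decrease-versus-change) — and
`regress_pc1_on_lnror()` quantifies how much of the leading axis is
overall reporting risk.

## The synthetic generator

Real FAERS snapshots are tens of gigabytes and change quarterly, so the
package ships a generative emulator (`synthetic_config()`,
`simulate_faers()`) that makes every downstream stage testable against a
known truth. Per report it draws an integer age from a three-component
normal mixture truncated to [0, 120] (defaults give ~29% aged 70+,
matching the demographic margin of a large oncology report set), a gender
(57% female), independent Bernoulli exposures over a configurable drug
panel plus exactly one background (non-antineoplastic) drug, and
independent Bernoulli PT occurrences over the 14 SMQ terms plus 20 filler
terms (nausea, fatigue, ...). Baseline SMQ probabilities are proportional
to the reference per-PT record counts of the SMQ table, scaled to a
combined taste/smell rate of 0.94% — so the synthetic PT frequency
profile mirrors a real snapshot's, from dysgeusia (common) down to
abnormal olfactory tests (vanishingly rare).

Associations are injected on the odds scale: exposure to a drug with a
configured signal multiplies that PT's event odds by the target ROR, so
the population odds ratio equals the target exactly and
parameter-recovery experiments are well defined; the same mechanism
applies an elderly (70+) odds multiplier to all SMQ terms (default
1.381). Dirty data is emulated by re-emitting 5% of cases as stale
earlier case versions (which deduplication must remove), corrupting 5% of
ages (sub-year units, out-of-range values, missing), 1% decade-coded
ages, and 2% unknown genders. Exposures are drawn independently per
report; co-medication confounding is deliberately not modelled.

The generator returns a ground-truth ledger (per-report exposure and
event indicator matrices plus eligibility flags). `ledger_contingency()`
and `ledger_table_b()` read exact realized counts from it, and the test
suite verifies they are *identical* to what the file-level pipeline
(write, read, deduplicate, join) recomputes — so fast ledger-based
simulation studies are certified stand-ins for the full file path.

What passing tests on synthetic data do **not** show: robustness to
reporting biases (notoriety and Weber effects), name curation errors,
correlated co-medication, term-hierarchy effects, or real FAERS marginal
structure. The generator validates the statistical machinery, not the
epidemiology.

## Validation studies and chosen problem sizes

Three replicated studies (exported, also run by `scripts/acceptance.R`)
probe the estimator end to end; their conditions are fixed choices of the
package, stated here once:

* **CI coverage** (`ror_recovery_study()`): one probe drug, injected
  dysgeusia ROR 4.0, 200,000 reports per replicate, 8% exposure, age
  effect off — the age tilt is removed because odds ratios are
  non-collapsible, so marginalizing over an age effect would bias the
  target slightly away from 4.0 and muddy what is being measured. Across
  100 replicates the Haldane-corrected Wald 95% CI should cover 4.0 in
  at least 93.
* **Null calibration** (`null_signal_study()`): eight drugs, no injected
  signals, 150,000 reports at 8% exposure — sized so null drugs sit near
  the 100-event eligibility threshold. Because the signal criteria
  require ROR > 1 on top of *p* < 0.05, the expected null flag rate is
  ~2.5%, and at most 10% of eligible drugs should be flagged over 50
  replicates.
* **Planted profiles** (`planted_profile_study()`): nine drugs in three
  archetypes (all seven analysis PTs elevated by 2.5 lnROR units;
  taste terms only; baseline), 200,000 reports, combined taste/smell
  rate 3%, PT threshold 60 (the 3000-report cut scaled to this database
  size, preserving the gap between hyposmia and the rarer terms).
  Ward clustering at k = 3 should recover the archetypes (Rand index
  >= 0.9) and the PCA contrast component should correlate positively
  with every taste PT and negatively with every smell PT.

Unit tests run reduced versions of these (fewer replicates, smaller n)
so the default suite stays fast; the full-size studies run in the
acceptance script and the acceptance test file.

## A worked example

```{r example}
cfg <- synthetic_config(n_reports = 100000, seed = 7)
sim <- simulate_faers(cfg)
ta <- build_table_a(deduplicate(sim$demo), deduplicate(sim$drug),
                    deduplicate(sim$reac))
count_tsd_reports(ta, cfg$drugs$name)

# scaled signal criteria for a 100k-report database
screen <- disproportionality(ta, min_events = 25)
summary(screen)
```

Of the two planted defaults, sunitinib (all 14 terms at ROR 2.5) is
flagged with its interval covering the target, while vismodegib (taste
terms at ROR 4, but only 0.5% exposure) shows a strongly elevated
estimate yet too few event reports to clear the count criterion — the
rule that deliberately mutes rarely exposed drugs.

```{r demographics}
tb <- build_table_b(deduplicate(sim$demo), deduplicate(sim$drug),
                    deduplicate(sim$reac), cfg$drugs$name)
stratum_association(dichotomize(tb, "age", cutoff = 70))
```

## Known limitations

* The ROR is a relative reporting signal, not a risk estimate; nothing
  here adjusts for confounding, co-medication, or reporting dynamics.
* Deduplication trusts case ids; near-duplicate cases submitted under
  different case ids are not collapsed.
* The exact test and the screen operate per drug-event pair with no
  multiplicity control, by design.
* The bundled ATC map is a curated subset for convenience and testing;
  production analyses should supply a complete, current map.
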