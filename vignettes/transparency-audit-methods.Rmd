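---
title: "Methods: auditing clinical trial transparency at research institutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing clinical trial transparency at research institutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdash)
```

`ctdash` audits a cohort of registered interventional clinical trials led by
university medical centers (UMCs) against seven transparency practices and
assembles the results into a per-institution dashboard. This vignette
explains the models and rules the package implements, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open.

## The cohort model

A trial enters the audit when it is (1) interventional, (2) considered
complete per its registry status, and (3) has a completion date inside the
configured window (2009–2017 by default). Filters run in that fixed order
and each excluded trial is tallied under the first reason that removes it;
trials with no completion date fall under the window reason and are logged.
The tally always conserves counts: input = included + duplicates + sum of
exclusions.

Registry status vocabularies drift over time, so the set of "complete"
statuses is a parameter (`cohort_criteria()`, default `Completed`,
`Terminated`, `Suspended`, `Unknown status`). When auditing a real export
whose vocabulary differs, override the set rather than editing status
strings in the data.

The same trial may be registered in both ClinicalTrials.gov and DRKS. A
cross-registration is detected when either record's secondary identifiers
contain the other's registration number after canonicalization (uppercase,
internal spaces and hyphens stripped). The ClinicalTrials.gov member is
retained because it carries the structured summary-results field the
summary-results metric needs; the DRKS member's registry references are
merged onto it and its identifier is remembered so that either number
counts as the trial's own during text matching. Which member the original
audits retained is not documented; retaining the richer record is this
package's choice and is symmetric in where the cross-reference was
recorded.

## Dates with partial resolution

Registries mix day-resolved, month-resolved and year-only dates. The
package keeps the source resolution in a dedicated vector class
(`partial_date`) instead of imputing at parse time, because two rules
depend on resolution:

* **Prospective registration** is month-granular by definition: a trial is
  prospectively registered when registered in the same or an earlier
  calendar month than its start. Day fields are ignored; if either date
  lacks a month the trial is *not assessable* and leaves the denominator,
  rather than being guessed.
* **Timeliness** needs day-level arithmetic. Month-resolved dates are
  imputed to the first of the month only at this point, day-resolved dates
  keep their day, and year-only dates are treated as not assessable. The
  first-of-month imputation is the conservative deterministic choice (it
  can only make a deadline earlier, never later); the original audit does
  not document its imputation, so this one is fixed and stated here.

## Denominator discipline

Every metric flag is `TRUE`, `FALSE` or *absent* (`NA`), and absent is used
exactly when the trial falls outside the metric's sample:

* TRN in abstract: requires a non-dissertation publication with a PubMed
  identifier and an abstract text.
* TRN in full text: requires a retrieved full text.
* TRN in both: requires both of the above to be assessable.
* Publication link in registry: requires a publication with a DOI or PMID.
* Timeliness at N years, per route: requires the N-year window after
  completion to have closed before the route's observation date — the
  registry download date for summary results, the publication search date
  for publications, and *both* for the either-route metric.
* Open access: requires a DOI and a dated record in the open-access
  evidence source.

Dissertations carry publication metadata but are excluded from every
publication-based metric (their flags are absent, and a dissertation-only
trial counts as unreported on the publication route, not as out of
sample). Aggregation then simply counts `TRUE` over non-`NA` per group, so
the denominators printed in any view are the metric's own by construction.

The observation dates live in `followup_context()`. The registry download
date defaults to 2022-11-01. The manual publication search predates the
registry download and its exact per-tranche cutoffs are not part of the
package's inputs; the default 2022-02-15 is an assumption chosen to sit
between the search tranches, and real-data runs should set both dates
explicitly.

## TRN detection

Registration numbers are found with a registry-pattern inventory:
`NCT` + 8 digits, `DRKS` + 8 digits, `ISRCTN` + 8 digits, and the EudraCT
`YYYY-NNNNNN-CC` form. Matching is case-insensitive, tolerates one
optional space or hyphen between prefix and digits, and guards both ends
against longer digit runs (so a 7- or 9-digit "NCT" string is not a hit).
Hits are canonicalized (uppercase, separator removed; EudraCT keeps its
internal hyphens) and deduplicated per registry keeping the first
occurrence's offset. Whether the original tolerated further punctuation
variants is unstated; the inventory is a config surface
(`trn_patterns()`), and canonicalization is idempotent so detector output
can be fed back through the detector unchanged.

A publication matches a trial when any detected number equals the trial's
own or a known cross-registration's. Full-text matching operates on the
extracted plain text; PDF conversion is out of scope.

## Open-access hierarchy

Each open-access location maps to a candidate status: an article in a
fully open-access journal is *gold*; openly licensed on the publisher page
of a subscription journal, *hybrid*; a repository copy, *green*; free on
the publisher page without a clear license, *bronze*. A publication gets
the highest candidate under the descending order gold > hybrid > green >
bronze > closed (no locations = closed). The result is invariant to the
order of the evidence rows.

## Interval estimation

All proportions carry two-sided 95% continuity-corrected Wilson score
intervals (`wilson_cc_interval()`, z = 1.959964), the closed-form
Newcombe variant, clipped to [0, 1] with the lower bound exactly 0 at
x = 0 and the upper exactly 1 at x = n. The continuity correction matters
at the small denominators common in per-institution, per-year slices: at
0/44 the plain Wilson upper bound is 8%, the corrected one 10%. The
package's tests verify the closed form against an independent root-finding
oracle on the corrected score equation and check empirical coverage
(≥ 93% at the probed configurations; the correction is conservative).

Printed percentages round half away from zero (`percent_round()`); whether
the original rounded half-up or half-even cannot be distinguished from
printed values, so one convention is asserted and used everywhere,
including the CSV export and the dashboard tooltips.

Cross-institution spread is summarised by the median, sample standard
deviation (n − 1), minimum and maximum of per-UMC point estimates;
institutions with an empty denominator are excluded from the spread but
counted. A single-institution spread reports sd = 0 with a warning.

Summary-results rates for the EU registry are never recomputed from trial
records: they arrive as per-sponsor tracker history rows (due count,
reported count, snapshot date) and pass through to the dashboard, with the
percentage recomputed from the counts when absent and validated when
present. Where several tracker sponsor names map to one institution, the
name with the most trials represents it, ties broken lexicographically and
logged.

## The synthetic cohort

`generate_cohort()` is truth-first: it samples one Bernoulli flag per
behavior per trial (prospective registration, publication existence,
dissertation status, TRN in abstract, TRN in full text, registry link,
summary results per registry, cross-registration, plus the denominator
toggles — start date, PMID, abstract, full text, DOI, dated open-access
record), then renders registry records, publication texts and open-access
locations that realize those flags exactly. Because every classifier in
the pipeline is deterministic, pipeline tallies must equal the truth-table
tallies *exactly* for every metric and denominator; the test suite asserts
this at a 35-institution × 80-trial scale (2,800 trials, the size chosen
to keep the end-to-end check under a minute on one CPU).

Default rates approximate the pooled rates observed across German UMCs:
prospective ≈ 0.55, TRN in abstract 0.38, TRN in full text 0.60, registry
links 0.58 (ClinicalTrials.gov) and 0.23 (DRKS), summary results 0.08 and
0.03, open access ≈ 0.54, registry mix 78% ClinicalTrials.gov, completion
years 2009–2017. Timely reporting is deliberately *not* a sampled flag —
it is determined by the sampled reporting-delay distribution (63% of
reports within 24 months by default), which makes 2-year
either-route reporting come out near the observed 41% once publication
and summary-results prevalence are accounted for, and keeps the generator
free of inconsistent flag combinations. DRKS-style records carry
month-resolved dates and ClinicalTrials.gov-style records day-resolved
ones, so both granularity branches are exercised. Cross-registered pairs
place the reciprocal secondary identifier on a randomly chosen side (or
both), exercising deduplication in both directions.

What the generator does **not** emulate: realistic registry prose (texts
are templates sufficient for the regex scanner), delayed or inaccurate
registry data entry, misspelled or truncated registration numbers,
multi-institution trials (each synthetic trial has one lead institution),
and publication-search imperfections (the mapping file is exact by
construction). A green test suite therefore demonstrates that the
*classifiers and bookkeeping* are exact, not that real registry data are
clean; on real exports the registry-data caveats listed on each dashboard
panel apply.

One statistical note on the rate-recovery test: the paper-shaped demo
checks 13 configured rates at once against their binomial sampling
intervals on a ~3,000-trial cohort. Thirteen simultaneous 95% checks would
fail spuriously about half the time under a perfectly faithful generator,
so the per-comparison level is Šidák-adjusted to hold the family-wise
false-alarm rate at 5%; the per-rate tolerance is still the binomial
sampling scale.

## Dashboard and exports

The dashboard is a static site: pooled, comparative and per-institution
pages, each plot an inline SVG whose tooltips carry the absolute
numerator/denominator, with a methods-and-limitations note beside every
panel and an explicit "no data" placeholder where a denominator is empty.
Every number shown in HTML is backed by the tidy CSV export (single source
of truth, asserted by a cross-format test), and the JSON dataset
round-trips losslessly. Outputs are a pure function of the inputs — no
timestamps — so repeated runs are byte-identical; the provenance block
embedded in each export records the input digests, cohort size and
observation dates of the snapshot. A static rendering was chosen over an
interactive server to keep the artifact dependency-free and testable while
preserving the three views and the absolute-number tooltips.

## Known limitations

* Registry data quality bounds everything: wrong completion dates or
  statuses propagate into eligibility and timeliness.
* DRKS summary-results detection is keyword-based and may miss unusually
  titled reports; the keyword list is configurable.
* The publication mapping is an input (the manual search is not
  reproduced); trials whose earliest publication was missed upstream count
  as unpublished here.
* EU-registry reporting rates are pass-through from the tracker and are
  not recomputed or verified against trial records.
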