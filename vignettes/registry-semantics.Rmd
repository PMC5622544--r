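---
title: "Models and methods of the semantic cancer registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the semantic cancer registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odsreg)
```

This vignette is the package's own account of its models and the design
choices behind them: what the cohort simulator assumes, how tabular
registry data become RDF, what the ontology-driven query dialect can and
cannot express, how timelines, enrichment p-values and treatment trees
are computed, and where the limits of synthetic data lie.

## The cohort simulator

### Model

Patients are generated in strata defined by gender and 5-year age bins
(0–4, 5–9, …, 80–84, 85+; the last bin is open-ended). Every categorical
choice is a draw from a *stacked* cumulative distribution: the categories
of a weight table partition `[0, 1)` into half-open bands in list order,
and a uniform draw selects the band it falls in. Three stacks are chained
per patient:

1. **Diagnosis stack per stratum.** The shipped 60–64 table assigns
   breast 0.23, lung 0.17, prostate 0.17, colorectal 0.08 and an "other"
   remainder of 0.35; in list order the cumulative boundaries are 0.23,
   0.40, 0.57, 0.65, 1.00, so a draw of 0.60 yields a colorectal
   diagnosis. Tables for the other strata are plausible defaults chosen
   once (a generic mix with a large "other" mass), not calibrated values.
   A single diagnosis table serves both genders of a stratum, which is
   why a male draw can land on breast cancer; this mirrors the stack
   design rather than epidemiology (see *Limitations*).
2. **Therapy stack per diagnosis.** Colorectal cases draw therapies from
   teletherapy 0.44, chemotherapy 0.44, surgical treatment 0.12; the
   other diagnosis categories carry defaults of the same shape. The
   *number* of therapies follows a geometric stopping rule: after each
   therapy a continuation draw with probability `therapy_continue_prob`
   (default 0.5) adds another, capped at `max_therapies` (6). This is the
   simplest memoryless rule producing "one or more" therapies. Therapy
   durations are uniform on 1–3 months and laid out contiguously from
   the diagnosis month, so therapy *k*+1 starts the month after therapy
   *k* ends.
3. **Monthly course chain per diagnosis.** Disease evolution is a
   first-order Markov chain over course states (stable disease, partial
   and complete remission, progression, recurrence, death) iterated
   monthly from an initial state (stable disease) until absorption
   (death or complete remission) or `max_course_months` (60). A course
   *event* is recorded whenever the state changes; events carry a
   consecutive 1-based `order` and strictly increasing dates, and
   nothing follows death. The default transition table and the more
   aggressive lung-cancer override are design choices giving a mean
   absorption time of roughly a year; they are configuration, not fitted
   values.

A configurable fraction of patients (default 0.10 per stratum) receives
a second diagnosis, sampled from the same stratum stack *without
replacement* and dated 1–36 months after the first. The mechanism is
intentionally minimal: the only constraint honoured is that the
multi-diagnosis fraction matches its configured value.

### Secondary attributes

Birth dates are back-computed from a uniform age inside the stratum at
the first diagnosis date, which is itself uniform within ±2 years of a
fixed index date (2010-01-01); month is the model's native time unit, so
days carry no signal. Patient conditions (weight, height, ASA class) are
drawn from per-gender normal/categorical defaults; the Karnofsky index
starts at 90 or 100 and moves with the course chain (−10 on progression
or recurrence, +10 on complete remission, 0 at death, clamped to
[0, 100]), one condition row per course event. ICD-10 codes per
diagnosis come from per-diagnosis (and for colorectal, per-gender)
stacks; the gender asymmetry in the colorectal code stack (rectal C20
heavier in males) exists so that the enrichment analysis has a real
signal to find. Grading, TNM fields and stage are small fixed stacks
that add attribute diversity only — nothing downstream weighs them.

### Reproducibility

All sampling flows through R's global RNG; `simulate_cohort(seed = s)`
is byte-reproducible for fixed configuration and `n`. Internally the
cohort is generated in chunks of 1000 patients with column-wise
accumulators; chunking affects performance only, not the draw sequence.

## From tables to RDF

The mapping rules (`inst/extdata/mapping-rules.yaml`) declare, per CSV
table: the ontology class (or a *class column* — therapy and course rows
are typed with their row-specific subclass, never the generic parent),
the key column that mints the individual IRI
(`<ns>individual/<table>/<key>`), datatype columns with their XSD kind,
and foreign-key columns with their object property and inverse. Each
diagnosis additionally spawns one pathological-structure individual
typed with the cancer class (and an anatomical one where a site is
known), because the query templates navigate
`hasPathologicalStructure` to a *typed* node rather than filtering a
literal.

Patients, diagnoses and therapies are deliberately over-linked:
`Patient –hasDiagnosis→ Diagnosis`, `Diagnosis –hasTherapy→ Therapy`,
`Therapy –hasDiagnosis→ Diagnosis`, `Therapy –hasPatient→ Patient` (a
derived two-hop link) and `Patient –hasTherapy→ Therapy` all hold at
once. The printed query shapes navigate these links in both directions
— therapy-rooted dashboards hop `hasPatient`, patient-rooted filters hop
`hasTherapy` — so the store asserts all of them rather than choosing a
canonical direction.

Patient age is materialised as an integer property on the patient (from
the first condition row) because the query templates filter
`?s ods:age` directly; recomputing age from birth dates inside SPARQL
would need arithmetic the dialect does not carry. Gender is a plain
`"M"`/`"F"` literal for the same reason: the templates compare
`str(?var) = 'M'`.

Instead of a description-logic reasoner, the transformation applies
structural validation: every individual typed, every object link
resolving to an existing individual, domains and ranges conforming to
the ontology's declarations. A dangling foreign key or an unknown
subclass value aborts the transformation naming the offending row.

The store itself is an in-memory triple table with canonical Turtle
persistence (sorted statements, stable prefixes), so saving the same
store twice is byte-identical and round-trips preserve the triple set
exactly. No RDF/SPARQL library for R is involved; the Turtle subset
reader/writer and the SPARQL evaluator below are part of the package,
and one test cross-checks the Turtle writer against an independent
Python RDF parser.

## The query dialect

A query model is a tree: a root class, object-property hops (each with a
class constraint), datatype filters, and an optional aggregation.
Emission is deterministic and follows a fixed variable scheme — `?s` for
the root, `?a0, ?a1, …` for root children in declaration order, parent
name plus a per-depth counter for deeper nodes (`?a01`, `?a12`), and
`?t`/`?ta0` for type variables.

Subclass semantics are resolved *client-side*: every class constraint is
expanded into `FILTER (?t IN (<subclass closure>))` with the closure
enumerated in depth-first pre-order, lexicographic among siblings, and
the root class **last**. The store therefore needs no RDFS entailment,
and the emitted text is self-contained. The closure order is part of
the emission contract (tested token-for-token), not an implementation
accident.

The namespace deserves a note: a prefix IRI without a terminal `#` or
`/` cannot serve as a namespace, because local names would concatenate
directly onto it. The package default is
`http://www.imib.es/ontologies/disease-times#`.

`execute_sparql()` implements exactly the conjunctive dialect the
builder emits — nested group joins, `FILTER ... IN`, the comparators
`= != < <= > >=`, `str()` equality, `DISTINCT`,
`count`/`avg`/`min`/`max` with `group by`, `order by` — with bag
semantics and deterministic order under `order by`. `UNION`,
`OPTIONAL`, property paths and updates are out of scope by design: the
builder never produces them, and keeping the evaluator co-extensive
with the emitter keeps both testable against a row-filter oracle.
String comparison uses exact match after `str()` coercion; numeric
comparison coerces the literal; dates compare lexicographically, which
is correct for ISO-8601 strings.

Saved templates are versioned JSON; a filter value `"?"` (or `"?slot"`)
is a parameter slot filled at load time, so one stored dashboard can be
instantiated per age range — the package's reading of "dashboards over
several age ranges" is one query per configured range. Defined classes
are *virtual*: the stored query is re-executed on demand and no triples
are materialised, so membership always reflects the current store
without equivalence axioms or a reasoner.

## Timelines

A patient timeline normalises events to 0-based calendar months from
each diagnosis date (month delta = `year*12 + month` difference). A
therapy spanning `[start, end]` contributes to every calendar month the
interval overlaps, partial months included — with month as the time
grain there is no defensible finer rule. Course events sit at their
month; when two course events share a month the one with the higher
`order` wins, keeping a single course track per month. The last
encounter is the maximum date over the patient's conditions, therapies
and courses, a pragmatic reading of an otherwise unspecified field.

The group matrix counts *patients* per (month, event-category); a
patient contributes at most 1 to a cell however many of their therapies
of that class overlap the month. Re-filtering recomputes the matrix
over the subgroup satisfying a condition — "category present at month
m" or "first therapy is the category" — so refiltered cells are bounded
by the original cells, an idempotence/monotonicity pair the test suite
asserts together with a per-patient oracle for every cell. An
unsatisfiable condition returns a zero matrix flagged `empty` rather
than an error, because an empty subgroup is a legitimate exploratory
outcome.

## Enrichment

For a code observed `k` times among the `n` diagnoses of a group, with
`M` occurrences among all `population` diagnoses of the registry, the
enrichment p-value is the hypergeometric upper tail `P(X ≥ k)`. The
counts are diagnoses, not patients (a patient with two diagnoses
contributes two draws), and the population is the total number of
diagnoses — the parameterisation in which the draw-without-replacement
model is dimensionally coherent. The sum is computed in log space via
`lchoose`, summed from the dominant term, so registry-scale counts do
not overflow; the suite checks agreement with direct pmf summation to
1e-12 relative error over the full small-count grid. `k = 0` returns
exactly 1 and `k > min(M, n)` exactly 0, short-circuited before any
floating-point work.

A literal "as printed" variant of the formula — denominator
`choose(N, i)` with `N` the number of distinct codes — is available
behind `as_printed = TRUE` for comparison. It is not a calibrated tail
probability (its denominator varies with the summation index and mixes
code counts with diagnosis counts) and is excluded from all analyses;
it exists so the difference is inspectable rather than silent. No
multiple-testing correction is applied by default; `bh = TRUE` adds a
Benjamini–Hochberg column for users who want one.

## Treatment trees

The recommender needs no graphical-model machinery: therapy sequences
cannot cycle once unrolled over periods, so the model is a tree whose
node at path (t1, …, tp) carries the empirical conditional probability
of tp given the prefix, with support counts. Sequences are therapy
classes ordered by start date, binned into periods (month by default,
quarter optionally), one class per period (the first wins). Every node
carries an explicit "no further therapy" child, so probabilities sum to
1 and supports are conserved from root to leaves — both asserted
exactly in the tests. Unrolling is bounded by `max_period` (default
24); repeated application of the same therapy simply repeats a label
along the path. Re-ranking after an observed treatment is a walk down
the tree; an unseen path falls back to its longest observed prefix,
flagged. Laplace add-one smoothing is available for tiny cohorts and
off by default, because unsmoothed frequencies are the quantity the
recovery tests measure.

## Problem sizes and numerical choices

The test suite and the acceptance script use sizes chosen to make
binomial noise small relative to the quantities checked while staying
desk-scale: 20,000 patients for recovering the 60–64 stratum
probabilities (3 binomial standard errors of 0.08 at that size is about
±0.006), 500 patients and 100 randomised query models for the
SPARQL-versus-oracle equivalence, 1000 patients for RDF count
conservation, 200 for timeline properties, 2000 (one stratum) for the
recommender recovery. Weight tables are renormalised when they sum to
within 1% of one and rejected otherwise; cumulative boundaries clamp
their last element to exactly 1 to absorb float drift; categorical
bands are half-open (`[lo, hi)`) so boundary draws resolve
deterministically; all deterministic orderings (closure enumeration,
IRI sorts, tie-breaks) use byte order, never locale collation.

## Limitations

Synthetic data demonstrate mechanism, not medicine. The generator
reproduces configured marginal distributions and a Markov course
process; it does not model gender-specific incidence (outside the
colorectal ICD stack), age-dependent therapy choice, correlated
comorbidity, informative censoring, or any survival structure beyond
the monthly transition table — so passing distribution-recovery tests
says the machinery is faithful to its configuration, not that the
configuration is faithful to a population. The enrichment analysis
inherits whatever signal the code stacks encode. The query dialect is
co-extensive with the builder; hand-written SPARQL using constructs
outside it is rejected rather than approximated. The ontology is a
self-contained minimal vocabulary (~100 classes) with annotations in
place of imports; equivalences to external ontologies are recorded as
comments, not axioms, and no reasoning is performed.
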