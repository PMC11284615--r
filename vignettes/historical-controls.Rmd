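---
title: "Extracting historical control data from SEND studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting historical control data from SEND studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records how `sendhc` models the problem of pooling
negative-control data across SEND toxicology studies, the conventions it
fixes where the SEND standard leaves room, and what its synthetic test
data do and do not establish about behavior on real submissions.

## The data model

A SEND study is a folder of SAS XPT v5 transport files, one per domain.
`read_xpt()` maps each file to a `domain_table`: the records as a plain
data frame plus per-variable metadata (label, character/numeric kind,
declared length). Parsing and serialization of the transport format are
delegated to `haven`; `sendhc` adds the validation the pipeline depends
on — the v5 library-header check (v8 transports are rejected explicitly,
malformed headers are reported with the failing byte offset), detection of
empty libraries, 8/40-character name/label limits enforced before any
bytes are written, and a 200-byte cap on character lengths.

Two transport-format facts shape the contract:

- SAS transport cannot distinguish a blank character value from a missing
  one. `sendhc` normalizes both to `NA` on read and on table
  construction, which is what makes `read_xpt(write_xpt(t))` an exact
  identity on records, variable order, labels and kinds.
- The format stamps creation/modification datetimes into fixed header
  offsets. `write_xpt()` pins these to a constant, so generated fixtures
  are byte-identical for identical seeds and cleaned files differ from
  their inputs only where values changed.

Split datasets (`lb1.xpt`, `lb2.xpt`) are concatenated under their shared
`DOMAIN` code; the `DOMAIN` variable takes precedence over the filename
stem because filename casing is unreliable across sponsors. Supplemental
qualifier files (`supp--.xpt`) are imported into a pass-through table but
not consulted by any query.

## The database

`create_schema()` lays out one SQLite table per domain of a packaged
manifest (a tab-delimited resource targeting the SEND IG 3.1 variable
sets; the version string is recorded in a metadata table). Import is
deliberately dumb: every record of every readable domain is inserted
verbatim, character variables as TEXT and numeric as REAL, with no date
parsing or term mapping at load time. Variables not in the manifest are
added as new nullable columns rather than dropped — sponsors add custom
variables, and the verbatim-load guarantee (database rows reproduce the
source XPT exactly, as value multisets per variable) is load-bearing for
everything downstream. Each study is one transaction; a batch import
continues past failed studies and reports per-study status. Replacing an
existing study is explicit (`replace = TRUE`); the default refuses
silent overwrite.

## The filter chain

Queries compose left to right: study-level filters produce a study set,
subject-level filters refine a subject set, then findings are extracted
and annotated. Every filter with a `NULL` criterion is the identity on its
input, every filter's output rows are a subset of its input rows (with
`incl_uncertain = FALSE`), and the subject-level filters commute — the
test suite asserts all six orderings of sex, species/strain and route give
identical sets.

Rows the data cannot classify are never silently guessed. Each filter
either drops them (default) or, with `incl_uncertain = TRUE`, keeps them
with a short message in `UNCERTAIN_MSG`, concatenated with `"; "` when
several filters flag the same row. Examples: a study with no SDESIGN
parameter, a trial set with no TCNTRL parameter, a subject with missing
SEX, a finding whose age cannot be derived, a study with no SE domain
(every finding phase-Uncertain).

Conventions fixed here:

- **Negative controls.** A trial set is a negative control when its
  TCNTRL value (after optional vocabulary mapping, uppercased) contains
  one of VEHICLE, PLACEBO, SHAM, UNTREATED, NO TREATMENT, NEGATIVE and
  does not contain POSITIVE. Explicit positive controls are always
  excluded, even under `incl_uncertain`; unrecognized values are
  uncertain, not excluded, so a sponsor's idiosyncratic label can be
  recovered deliberately.
- **Attribute precedence.** Species and strain resolve per subject as
  DM > trial-set TX parameter > TS parameter. Route resolves as
  EX.EXROUTE (any dosing record of the subject) > TS ROUTE parameter.
  Dosing records state what was actually administered to that animal,
  while TS states the plan, so EX wins where both exist; this ordering is
  a package decision, documented rather than standard-mandated.
- **Partial dates.** TS study start dates may be year- or month-precision
  ISO 8601. A partial date matches a query interval if any completion of
  it does. This keeps month-precision legacy studies in scope rather than
  silently dropping them. The interval test is inclusive on both ends and
  open where a bound is `NULL`; an inverted range is an error.
- **Comparisons.** All equality comparisons are case-insensitive after
  vocabulary mapping when a vocabulary is supplied; without one, a
  built-in sex codelist still makes "Male" and "M" compare equal, and
  other axes fall back to raw case-insensitive comparison.

## Age and phase derivation

`derive_age_days()` resolves an animal's age at a finding in whole days,
in priority order:

1. finding date (`--DTC`) and birth date → calendar-day difference;
2. birth date and reference start date → `(RFSTDTC − BRTHDTC)` plus the
   study-day offset;
3. DM `AGE`/`AGEU` converted to days plus the study-day offset;
4. otherwise `NA`.

The study-day offset encodes the SEND convention that day 1 is the
reference start day and day 0 does not exist: offset `= --DY − 1` for
`--DY ≥ 1`, `= --DY` for negative days; `--DY = 0` is an error. When
`--DY` is absent but the finding date and RFSTDTC are both present, the
calendar difference is the same offset, and is used; with neither, the
offset is 0 (age at reference start). Unit conversions use the mean
Gregorian month (30.4375 days) and year (365.25 days); weeks are 7 days.
These constants are package choices — SEND does not prescribe them — and
results are rounded to the nearest whole day. A derivation that comes out
negative (inconsistent source dates) is returned as `NA` rather than a
nonsensical age.

Age-range filtering is inclusive on both ends, so contiguous query bands
like 60–120 and 120–180 days both contain a 120-day animal; analyses that
must partition should use half-open bands themselves.

`get_findings_phase()` locates each finding in its subject's SE epoch by
the half-open rule `SESTDTC ≤ --DTC < SEENDTC`, the final epoch's missing
end date meaning "until the end of the record". Undated findings fall
back to comparing `--DY` against epoch day bounds derived from RFSTDTC.
Epoch labels classify by case-insensitive keyword, first match wins:
screening keywords (screen, pre-treat, pretreat, acclimat, baseline), then
recovery (recovery, post-treat, posttreat, washout), then treatment
(treat, dos, exposure). Ordering matters — "PRETREATMENT" must classify
as Screening even though it contains "treat". Anything else, and any
subject without SE data, is Uncertain.

## Aggregation

Background incidence is computed per (specimen, finding), optionally per
severity. The denominator is the number of distinct control animals with
at least one MI record for that specimen whose MISTAT is not NOT DONE —
i.e. animals in which the tissue was actually examined, which is the
pathology convention; when every selected animal has every tissue
examined, this reduces to the cohort size. The numerator counts distinct
affected animals, not records, so an animal recorded twice with the same
finding counts once, and vocabulary-merged synonyms pool by animal (a
merge can therefore never decrease a surviving finding's count). The
percentage is rounded half-up at two decimals; base R's banker's rounding
would turn 24/873 into 2.74 where the dashboard convention prints 2.75.

Reference ranges group numeric standardized results (`--STRESN`) by test
code, specimen and unit (and sex on request), reporting n, arithmetic
mean, and sample standard deviation (n − 1 denominator, `NA` for a single
observation). Groups with mixed units split; they are never pooled.
Non-numeric results are excluded from computation but tallied in an
`n_excluded` attribute so silent data loss is visible.

## Terminology harmonization

`gen_vocab()` reads tab-delimited CT files — tolerant of both a minimal
header (codelist / submission value / synonyms / extensible) and the
published CDISC CT export headers — into a vocabulary restricted to ten
codelists: sex, strain/substrain, species, SEND severity, route of
administration response, standardized disposition term, specimen,
anatomical location, non-neoplastic finding type, SEND control type.
Every preferred value maps to itself; synonyms are uppercased and
trimmed. Matching is exact after uppercase/trim — no fuzzy matching,
because harmonization must be auditable. Within one layer, a synonym
mapped to two different preferred values is a fatal error; user
"extensible" files form a second layer that overrides the CT layer with a
logged warning, since user mappings are intentional. The JSON layout is a
top-level object keyed by codelist, each a flat synonym → preferred
object, plus a `_meta` object with provenance and extensible flags, with
stable key ordering for diffability. Both the JSON schema and the
variable → codelist bindings (`default_bindings()`: DM SEX/STRAIN/SPECIES,
MI MISPEC/MIANTREG/MISTRESC/MISEV, EX EXROUTE, DS DSDECOD, TX TXVAL on
TCNTRL parameter rows, TS TSVAL on SPECIES rows) are implementation-
defined surfaces of this package.

`standardize_file()` rewrites each XPT file with bound-variable values
replaced on vocabulary hits; misses are preserved verbatim (not
uppercased) and tallied, unbound variables are untouched, and record
counts and variable sets are invariant. Because preferred values map to
themselves, cleaning is idempotent, which the suite verifies at the
record level across the full cohort. In-place overwrite is refused.

## The synthetic study generator

`study_spec()`/`make_study()` realize a conventional 4-week repeat-dose
rat gavage study: a vehicle-control and a high-dose trial set of 10
animals each (alternating male/female), a 2-week acclimatization epoch,
4-week dosing, 2-week recovery; animals are 56–62 days old at reference
start (8 weeks ± a seeded 0–6-day jitter, the usual age for young-adult
rat studies); terminal microscopic findings on study day 28; clinical
chemistry drawn from stated normal distributions; eight weekly-paced body
weights. Every planted quantity — control ids, sexes, ages, finding
counts, per-test μ/σ — is recorded as ground truth beside the bundle and
is recoverable exactly by reading the files back, which is what makes
planted-truth recovery a meaningful end-to-end test. The default
three-study root stresses the uncertain paths deliberately: one study
omits SE (phase becomes Uncertain), one omits TCNTRL (controls become
uncertain), and designs/start dates differ so study-level filters have
something to do.

The harmonization cohort (`make_usecase2_fixture()`) plants 873 control
animals across three studies, both lung/bronchus and spleen examined in
every animal, with 6 + 48 + 2 lung/bronchus records under three synonym
terms and 21 + 3 spleen records under two, one record per affected animal
on distinct animals. Which animals carry findings is seed-dependent; the
counts — and hence the pre-clean incidences of 0.69%/2.41% and post-clean
6.41%/2.75% — are not.

What the generator does **not** emulate: correlation between endpoints
(organ weights, pathology and chemistry are independent), staggered
per-animal start dates within a study, dropped/early-death animals,
multi-record findings per animal, non-ASCII sponsor idiosyncrasies, or
SENDIG conformance in full. Passing tests therefore demonstrate the
pipeline's arithmetic and invariants, not robustness to every real
submission's quirks.

## Test scale and numerics

The suite runs at desk scale: 20-animal default studies, the 873-animal
cohort, a 200-animal study for reference-range recovery (tolerance
3σ/√n on the mean), 20 seeds for planted-truth and incidence-oracle
properties, 100 randomized tables for XPT round-trip identity, and 1,000
random date/day combinations for the age oracle. The incidence oracle is
a deliberately naive record-loop recount, independent of the grouped
implementation; the age oracle is a scalar transcription of the
resolution rules using R's calendar arithmetic.

## Known limitations

- SQLite only; no concurrent writers; no schema migration between
  manifest versions.
- XPT v5 only (the FDA submission format); no v8/v9, CPORT,
  Dataset-JSON or define.xml.
- Treated-group extraction, dose–response queries and TK/PC domains are
  out of scope; the query layer is controls-only.
- Ten CT codelists; fuzzy matching is deliberately absent.
- ASCII in/out for transport files; bytes ≥ 0x80 pass through with a
  warning.
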