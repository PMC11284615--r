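# sendhc

Historical control analysis for CDISC SEND toxicology studies.

Nonclinical safety studies submitted to regulators follow the CDISC
Standard for Exchange of Nonclinical Data (SEND): each study is a folder of
SAS XPT v5 transport files, one per *domain* (DM demographics, TS trial
summary, TX trial sets, EX dosing, DS disposition, SE subject elements,
BW body weight, LB laboratory results, MI microscopic findings). A
recurring question in study interpretation is whether a finding in treated
animals exceeds its *background incidence* — the rate at which matched
control animals from past studies show the same finding spontaneously.
Answering it requires pooling control data across many studies, which in
practice is blocked by two problems: the data are scattered across
submission folders, and synonymous terms ("ALVEOLAR MACROPHAGES,
INCREASED" vs "CELLULARITY, INCREASED") fragment the counts.

`sendhc` addresses both for toxicologists and nonclinical statisticians:

- **Database layer** — build and maintain a single-file SQLite database
  with one table per SEND domain, loading XPT content verbatim (no
  transformation at load time).
- **Query layer** — a composable filter chain that selects studies (design,
  start date) and negative-control subjects (control type, sex,
  species/strain, route), extracts findings domains, and derives each
  animal's **age in days** and the **study phase**
  (Screening/Treatment/Recovery) of every record.
- **Aggregation** — background incidence per (specimen, finding),

  ```
  incidence% = 100 × n_affected / n_examined
  ```

  with `n_examined` the distinct control animals in which the tissue was
  actually examined (MISTAT ≠ NOT DONE) and `n_affected` the distinct
  animals with ≥ 1 matching record; and reference ranges (n, mean, sample
  SD) for quantitative domains, never pooling across units.
- **Terminology harmonization** — build a JSON vocabulary from
  tab-delimited controlled-terminology (CT) files (synonym → preferred
  submission value, extensible user mappings layered on top) and rewrite
  SEND XPT files with harmonized terms, preserving everything else
  byte-for-byte and reporting every change.
- **Synthetic studies** — a deterministic generator of SEND bundles with
  planted ground truth (control ids, ages, phases, finding counts, test
  distributions), so the whole pipeline is testable without access to
  confidential submission data.

## Worked example

Build a demo database from three generated studies and query the male
control animals of the parallel-design studies:

```r
library(sendhc)

root <- file.path(tempdir(), "demo")
make_multi_study_root(root, seed = 101)

db <- init_environment(file.path(tempdir(), "send.db"), create = TRUE)
create_schema(db)
import_studies(db, root)
create_indexes(db)

studies  <- get_studies_sdesign(db, "PARALLEL")
studies  <- get_studies_ststdtc(db, "2015-01-01", "2019-12-31", prior = studies)
controls <- get_control_subj(db, studies)
controls <- get_subj_sex(db, controls, "M")
controls <- get_subj_species_strain(db, controls, "RAT", "SPRAGUE-DAWLEY")
controls <- get_subj_route(db, controls, "ORAL GAVAGE")
nrow(controls)
#> [1] 10

mi <- get_subj_data(db, controls, "MI")
mi <- get_findings_subj_age(mi, controls, 60, 120)
mi <- get_findings_phase(db, mi, "Treatment")
incidence_table(mi, controls)
#>   SPECIMEN      FINDING N_AFFECTED N_EXAMINED INCIDENCE_PCT
#> 1    LIVER INFLAMMATION          3          5            60
#> 2    LIVER     NECROSIS          1          5            20
#> 3    LIVER UNREMARKABLE          1          5            20

reference_ranges(get_subj_data(db, controls, "LB"), controls)
#>   TESTCD                       TEST  SPEC UNITS  SEX  N   MEAN       SD
#> 1    ALT   Alanine Aminotransferase SERUM   U/L <NA> 10 49.670 7.475046
#> 2    AST Aspartate Aminotransferase SERUM   U/L <NA> 10 72.744 8.398647
disconnect_db(db)
```

Ten male vehicle-control rats match the filters, but only five carry
phase-resolved microscopic findings: one generated study deliberately
omits the SE domain, so its records classify as phase-Uncertain and drop
out unless `incl_uncertain = TRUE` is passed. Of the five examined livers,
three show inflammation (60%), one necrosis (20%) — the background rates a
reviewer would weigh against a concurrent-study finding. The LB table
shows the pooled control reference ranges (the generator draws ALT from
Normal(50, 5), AST from Normal(80, 10)).

Terminology cleaning works on folders of XPT files:

```r
vocab <- gen_vocab("ct.tsv", json_out = "vocab.json")
standardize_file("raw_study/", "clean_study/", vocab)
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "sendhc.R", package = "sendhc")`; see its header for
the `db` / `clean` / `query` / `report` commands.

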