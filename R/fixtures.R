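# Run code under a private, seeded RNG stream without disturbing the
# caller's .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

date_of_study_day <- function(rfstdtc, day) {
  d <- as.Date(rfstdtc)
  format(d + ifelse(day >= 1, day - 1, day), "%Y-%m-%d")
}

#' Specify a synthetic SEND study
#'
#' Captures everything the generator needs to realize one study as a bundle
#' of XPT files with planted, recoverable ground truth. Defaults describe a
#' conventional 4-week rat gavage study with a vehicle-control and a
#' high-dose trial set of 10 animals each (half male, half female), a
#' 2-week acclimatization epoch, 4-week dosing epoch and 2-week recovery
#' epoch, terminal microscopic findings, and normally distributed clinical
#' chemistry.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical bundles.
#' @param studyid study identifier.
#' @param design TS SDESIGN value.
#' @param start_date ISO study start date (RFSTDTC for every animal).
#' @param species,strain,route study-wide DM/EX values.
#' @param sets data frame `setcd`, `set`, `tcntrl` (NA for treated), `n`.
#' @param epochs data frame `etcd`, `epoch`, `start_day`, `end_day`
#'   (half-open study-day ranges).
#' @param mi_plan data frame `specimen`, `finding`, `n_affected`,
#'   `severity`: findings planted in distinct control animals; every animal
#'   gets one record per specimen (UNREMARKABLE when unaffected).
#' @param mi_records optional explicit MI plan overriding `mi_plan`: data
#'   frame `subj` (1-based animal index), `specimen`, `finding`, `severity`.
#' @param lb_plan data frame `testcd`, `test`, `mu`, `sigma`, `units`,
#'   `spec`: one record per animal per test, drawn from Normal(mu, sigma).
#' @param mi_day,lb_day study day of the MI/LB records.
#' @param bw_days study days of body-weight records (8 by default).
#' @param age_days_at_start age in days at the reference start date
#'   (subject-level jitter of 0--6 days is added).
#' @param include_se,include_tcntrl,include_dm_species toggles that omit SE,
#'   the TCNTRL TX parameter, or DM SPECIES/STRAIN (forcing TS fallback), to
#'   exercise uncertain paths.
#' @return A `study_spec` list.
#' @export
study_spec <- function(seed = 1L,
                       studyid = "SEND-001",
                       design = "PARALLEL",
                       start_date = "2018-07-15",
                       species = "RAT",
                       strain = "SPRAGUE-DAWLEY",
                       route = "ORAL GAVAGE",
                       sets = data.frame(
                         setcd = c("VEH", "HD"),
                         set = c("Vehicle control", "High dose"),
                         tcntrl = c("VEHICLE CONTROL", NA),
                         n = c(10L, 10L),
                         stringsAsFactors = FALSE),
                       epochs = data.frame(
                         etcd = c("SCR", "TRT", "REC"),
                         epoch = c("SCREENING", "TREATMENT", "RECOVERY"),
                         start_day = c(-14L, 1L, 29L),
                         end_day = c(1L, 29L, 43L),
                         stringsAsFactors = FALSE),
                       mi_plan = data.frame(
                         specimen = c("LIVER", "LIVER"),
                         finding = c("NECROSIS", "INFLAMMATION"),
                         n_affected = c(2L, 3L),
                         severity = c("MINIMAL", "MILD"),
                         stringsAsFactors = FALSE),
                       mi_records = NULL,
                       lb_plan = data.frame(
                         testcd = c("ALT", "AST"),
                         test = c("Alanine Aminotransferase",
                                  "Aspartate Aminotransferase"),
                         mu = c(50, 80), sigma = c(5, 10),
                         units = c("U/L", "U/L"),
                         spec = c("SERUM", "SERUM"),
                         stringsAsFactors = FALSE),
                       mi_day = 28L,
                       lb_day = 28L,
                       bw_days = c(1L, 4L, 8L, 11L, 15L, 18L, 22L, 25L),
                       age_days_at_start = 56L,
                       include_se = TRUE,
                       include_tcntrl = TRUE,
                       include_dm_species = TRUE) {
  spec <- list(seed = as.integer(seed), studyid = studyid, design = design,
               start_date = start_date, species = species, strain = strain,
               route = route, sets = sets, epochs = epochs, mi_plan = mi_plan,
               mi_records = mi_records, lb_plan = lb_plan, mi_day = mi_day,
               lb_day = lb_day, bw_days = bw_days,
               age_days_at_start = age_days_at_start,
               include_se = include_se, include_tcntrl = include_tcntrl,
               include_dm_species = include_dm_species)
  class(spec) <- "study_spec"
  validate_study_spec(spec)
  spec
}

validate_study_spec <- function(spec) {
  s <- spec$sets
  if (any(s$n < 1L)) stop("study_spec: every trial set needs >= 1 animal")
  if (anyDuplicated(s$setcd)) stop("study_spec: duplicate SETCD")
  n_ctrl <- sum(s$n[!is.na(s$tcntrl)])
  if (!is.null(spec$mi_plan) && is.null(spec$mi_records)) {
    per_spec <- tapply(spec$mi_plan$n_affected, spec$mi_plan$specimen, sum)
    if (any(per_spec > n_ctrl)) {
      stop("study_spec: planted finding counts exceed control animals for ",
           "specimen(s): ",
           paste(names(per_spec)[per_spec > n_ctrl], collapse = ", "))
    }
  }
  if (!is.null(spec$mi_records)) {
    ntot <- sum(s$n)
    if (any(spec$mi_records$subj < 1L | spec$mi_records$subj > ntot)) {
      stop("study_spec: mi_records subject index out of range")
    }
  }
  if (any(spec$epochs$start_day >= spec$epochs$end_day)) {
    stop("study_spec: epoch start_day must precede end_day")
  }
  invisible(spec)
}

#' Generate one synthetic SEND study as a folder of XPT files
#'
#' Writes ts/tx/dm/ex/ds/se/bw/lb/mi XPT v5 files realizing the spec.
#' Identical seeds give byte-identical output. The ground truth (control
#' ids, per-subject attributes, planted finding counts, test distributions,
#' per-record phases) is derivable from the spec alone and is also
#' serialized as `ground_truth.json` beside the XPT files.
#'
#' @param spec a [study_spec()].
#' @param out_dir directory for the study folder (created, named after the
#'   study id).
#' @return List with `folder` and `truth` (the ground-truth list).
#' @export
make_study <- function(spec, out_dir) {
  validate_study_spec(spec)
  folder <- file.path(out_dir, spec$studyid)
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    sets <- spec$sets
    ntot <- sum(sets$n)
    setcd <- rep(sets$setcd, sets$n)
    usubjid <- sprintf("%s-%04d", spec$studyid, seq_len(ntot))
    sex <- unlist(lapply(sets$n, function(k) {
      rep_len(c("M", "F"), k)
    }))
    age_jitter <- sample(0:6, ntot, replace = TRUE)
    age_day1 <- spec$age_days_at_start + age_jitter
    rfstdtc <- rep(spec$start_date, ntot)
    brthdtc <- format(as.Date(spec$start_date) - age_day1, "%Y-%m-%d")
    is_control <- setcd %in% sets$setcd[!is.na(sets$tcntrl)]

    # TS
    ts_parms <- rbind(
      c("SPLANDAT", "Study Plan Date", spec$start_date),
      c("SDESIGN", "Study Design", spec$design),
      c("STSTDTC", "Study Start Date", spec$start_date),
      c("SPECIES", "Species", spec$species),
      c("STRAIN", "Strain/Substrain", spec$strain),
      c("ROUTE", "Route of Administration", spec$route))
    ts <- data.frame(STUDYID = spec$studyid, DOMAIN = "TS",
                     TSSEQ = seq_len(nrow(ts_parms)),
                     TSPARMCD = ts_parms[, 1], TSPARM = ts_parms[, 2],
                     TSVAL = ts_parms[, 3], stringsAsFactors = FALSE)

    # TX
    tx_rows <- list()
    for (i in seq_len(nrow(sets))) {
      seqn <- 1L
      if (!is.na(sets$tcntrl[i]) && spec$include_tcntrl) {
        tx_rows[[length(tx_rows) + 1L]] <- data.frame(
          STUDYID = spec$studyid, DOMAIN = "TX", SETCD = sets$setcd[i],
          SET = sets$set[i], TXSEQ = seqn, TXPARMCD = "TCNTRL",
          TXPARM = "Control Type", TXVAL = sets$tcntrl[i],
          stringsAsFactors = FALSE)
        seqn <- seqn + 1L
      }
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        STUDYID = spec$studyid, DOMAIN = "TX", SETCD = sets$setcd[i],
        SET = sets$set[i], TXSEQ = seqn, TXPARMCD = "GRPLBL",
        TXPARM = "Group Label", TXVAL = sets$set[i], stringsAsFactors = FALSE)
    }
    tx <- do.call(rbind, tx_rows)

    # DM
    dm <- data.frame(
      STUDYID = spec$studyid, DOMAIN = "DM", USUBJID = usubjid,
      SUBJID = sprintf("%04d", seq_len(ntot)), RFSTDTC = rfstdtc,
      RFENDTC = date_of_study_day(rfstdtc, max(spec$epochs$end_day) - 1L),
      BRTHDTC = brthdtc, AGE = age_day1, AGEU = "DAYS", SEX = sex,
      SPECIES = if (spec$include_dm_species) spec$species else NA_character_,
      STRAIN = if (spec$include_dm_species) spec$strain else NA_character_,
      ARMCD = setcd, ARM = sets$set[match(setcd, sets$setcd)], SETCD = setcd,
      stringsAsFactors = FALSE)

    # EX (one dosing record per animal over the treatment epoch)
    trt <- spec$epochs[grepl("TREAT", toupper(spec$epochs$epoch)), ][1, ]
    ex <- data.frame(
      STUDYID = spec$studyid, DOMAIN = "EX", USUBJID = usubjid, EXSEQ = 1L,
      EXTRT = ifelse(is_control, "VEHICLE", "TEST ARTICLE"),
      EXDOSE = ifelse(is_control, 0, 100), EXDOSU = "mg/kg/day",
      EXROUTE = spec$route,
      EXSTDTC = date_of_study_day(rfstdtc, trt$start_day),
      EXENDTC = date_of_study_day(rfstdtc, trt$end_day - 1L),
      EXSTDY = trt$start_day, EXENDY = trt$end_day - 1L,
      stringsAsFactors = FALSE)

    # DS
    last_day <- max(spec$epochs$end_day) - 1L
    ds <- data.frame(
      STUDYID = spec$studyid, DOMAIN = "DS", USUBJID = usubjid, DSSEQ = 1L,
      DSTERM = "TERMINAL SACRIFICE", DSDECOD = "TERMINAL SACRIFICE",
      DSSTDTC = date_of_study_day(rfstdtc, last_day), DSSTDY = last_day,
      stringsAsFactors = FALSE)

    # SE
    se <- NULL
    if (spec$include_se) {
      ep <- spec$epochs
      se <- do.call(rbind, lapply(seq_len(nrow(ep)), function(j) {
        data.frame(
          STUDYID = spec$studyid, DOMAIN = "SE", USUBJID = usubjid,
          SESEQ = j, ETCD = ep$etcd[j], ELEMENT = ep$epoch[j],
          SESTDTC = date_of_study_day(rfstdtc, ep$start_day[j]),
          SEENDTC = date_of_study_day(rfstdtc, ep$end_day[j]),
          EPOCH = ep$epoch[j], stringsAsFactors = FALSE)
      }))
      se <- se[order(se$USUBJID, se$SESEQ), ]
    }

    # BW (monotone growth plus noise)
    bw <- do.call(rbind, lapply(seq_along(spec$bw_days), function(j) {
      d <- spec$bw_days[j]
      w <- round(200 + 5 * (d - 1) + stats::rnorm(ntot, 0, 5), 1)
      data.frame(
        STUDYID = spec$studyid, DOMAIN = "BW", USUBJID = usubjid, BWSEQ = j,
        BWTESTCD = "BW", BWTEST = "Body Weight",
        BWORRES = format(w), BWORRESU = "g", BWSTRESC = format(w),
        BWSTRESN = w, BWSTRESU = "g",
        BWDTC = date_of_study_day(rfstdtc, d), BWDY = d,
        stringsAsFactors = FALSE)
    }))
    bw <- bw[order(bw$USUBJID, bw$BWSEQ), ]

    # LB
    lbp <- spec$lb_plan
    lb <- do.call(rbind, lapply(seq_len(nrow(lbp)), function(j) {
      v <- round(stats::rnorm(ntot, lbp$mu[j], lbp$sigma[j]), 2)
      data.frame(
        STUDYID = spec$studyid, DOMAIN = "LB", USUBJID = usubjid, LBSEQ = j,
        LBTESTCD = lbp$testcd[j], LBTEST = lbp$test[j],
        LBCAT = "CLINICAL CHEMISTRY", LBORRES = format(v),
        LBORRESU = lbp$units[j], LBSTRESC = format(v), LBSTRESN = v,
        LBSTRESU = lbp$units[j], LBSPEC = lbp$spec[j],
        LBDTC = date_of_study_day(rfstdtc, spec$lb_day), LBDY = spec$lb_day,
        stringsAsFactors = FALSE)
    }))
    lb <- lb[order(lb$USUBJID, lb$LBSEQ), ]

    # MI: explicit record plan, or sampled from mi_plan among controls
    if (!is.null(spec$mi_records)) {
      mr <- spec$mi_records
      planted <- data.frame(usubjid = usubjid[mr$subj],
                            specimen = mr$specimen, finding = mr$finding,
                            severity = mr$severity, stringsAsFactors = FALSE)
      specimens <- unique(mr$specimen)
    } else {
      specimens <- unique(spec$mi_plan$specimen)
      ctrl_ids <- usubjid[is_control]
      planted <- list()
      for (sp in specimens) {
        plan <- spec$mi_plan[spec$mi_plan$specimen == sp, , drop = FALSE]
        pool <- sample(ctrl_ids)  # distinct animals per specimen
        k <- 0L
        for (r in seq_len(nrow(plan))) {
          take <- pool[seq_len(plan$n_affected[r]) + k]
          k <- k + plan$n_affected[r]
          planted[[length(planted) + 1L]] <- data.frame(
            usubjid = take, specimen = sp, finding = plan$finding[r],
            severity = plan$severity[r], stringsAsFactors = FALSE)
        }
      }
      planted <- do.call(rbind, planted)
    }
    mi_rows <- list()
    for (sp in specimens) {
      aff <- planted[planted$specimen == sp, , drop = FALSE]
      i <- match(usubjid, aff$usubjid)
      mi_rows[[length(mi_rows) + 1L]] <- data.frame(
        STUDYID = spec$studyid, DOMAIN = "MI", USUBJID = usubjid,
        MISEQ = match(sp, specimens),
        MITESTCD = "MIEXAM", MITEST = "Microscopic Examination",
        MIORRES = ifelse(is.na(i), "UNREMARKABLE", aff$finding[i]),
        MISTRESC = ifelse(is.na(i), "UNREMARKABLE", aff$finding[i]),
        MISPEC = sp,
        MISEV = ifelse(is.na(i), NA_character_, aff$severity[i]),
        MIDTC = date_of_study_day(rfstdtc, spec$mi_day), MIDY = spec$mi_day,
        stringsAsFactors = FALSE)
    }
    mi <- do.call(rbind, mi_rows)
    mi <- mi[order(mi$USUBJID, mi$MISEQ), ]

    doms <- list(ts = ts, tx = tx, dm = dm, ex = ex, ds = ds, se = se,
                 bw = bw, lb = lb, mi = mi)
    man <- send_domain_manifest()
    for (nmf in names(doms)) {
      d <- doms[[nmf]]
      if (is.null(d)) next
      code <- toupper(nmf)
      labs <- man[man$domain == code, ]
      write_xpt(domain_table(code, d,
                             labels = stats::setNames(labs$label, labs$variable)),
                file.path(folder, paste0(nmf, ".xpt")))
    }

    mi_day_phase <- classify_epoch(
      spec$epochs$epoch[spec$mi_day >= spec$epochs$start_day &
                          spec$mi_day < spec$epochs$end_day][1])
    planted_ctrl <- planted[planted$usubjid %in% usubjid[is_control], ,
                            drop = FALSE]
    counts <- stats::aggregate(cnt ~ specimen + finding,
                               data = cbind(planted_ctrl, cnt = 1L), FUN = sum)
    truth <- list(
      studyid = spec$studyid,
      seed = spec$seed,
      design = spec$design,
      start_date = spec$start_date,
      control_usubjid = usubjid[is_control],
      subjects = data.frame(
        USUBJID = usubjid, SETCD = setcd, SEX = sex,
        SPECIES = spec$species, STRAIN = spec$strain, ROUTE = spec$route,
        AGE_DAYS_DAY1 = age_day1, BRTHDTC = brthdtc, RFSTDTC = rfstdtc,
        is_control = is_control, stringsAsFactors = FALSE),
      mi = list(
        counts_controls = counts,
        n_examined_controls = stats::setNames(
          rep(sum(is_control), length(specimens)), specimens),
        phase = if (spec$include_se) mi_day_phase else "Uncertain",
        day = spec$mi_day,
        affected = planted),
      lb = data.frame(testcd = lbp$testcd, mu = lbp$mu, sigma = lbp$sigma,
                      n_controls = sum(is_control), stringsAsFactors = FALSE),
      domains = names(doms)[!vapply(doms, is.null, logical(1))])
    jsonlite::write_json(truth, file.path(folder, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(folder = folder, truth = truth)
  })
}

#' Generate the default multi-study fixture root
#'
#' Three studies with distinct start dates and designs; one omits the SE
#' domain and one omits the TCNTRL trial-set parameter, to exercise the
#' uncertain paths of the filter chain.
#'
#' @param out_dir root directory (created).
#' @param seed base RNG seed.
#' @return List of per-study results from [make_study()].
#' @export
make_multi_study_root <- function(out_dir, seed = 101L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    study_spec(seed = seed, studyid = "SEND-001", design = "PARALLEL",
               start_date = "2016-03-01"),
    study_spec(seed = seed + 1L, studyid = "SEND-002", design = "PARALLEL",
               start_date = "2018-07-15", include_se = FALSE),
    study_spec(seed = seed + 2L, studyid = "SEND-003", design = "CROSSOVER",
               start_date = "2021-01-10", include_tcntrl = FALSE))
  lapply(specs, make_study, out_dir = out_dir)
}

#' Generate the 873-animal terminology-harmonization cohort
#'
#' A multi-study control cohort of exactly 873 animals, each with both
#' lung/bronchus and spleen examined microscopically. Planted lung/bronchus
#' records: 6 CELLULARITY, INCREASED + 48 ALVEOLAR MACROPHAGES, INCREASED +
#' 2 AGGREGATE; spleen: 21 CELLULARITY, INCREASED + 3 FOLLICLES, INCREASED —
#' one record per affected animal, on distinct animals. Harmonizing the
#' synonym terms onto CELLULARITY, INCREASED therefore raises the pooled
#' counts to 56 (lung/bronchus) and 24 (spleen).
#'
#' @param out_dir root directory for the study folders (created).
#' @param seed RNG seed controlling which animals carry the findings.
#' @return List with `folder` (the root), `studies` (per-study results) and
#'   `truth` (cohort-level planted counts).
#' @export
make_usecase2_fixture <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_per <- c(291L, 291L, 291L)
  total <- sum(n_per)
  plan <- data.frame(
    specimen = c(rep("LUNG/BRONCHUS", 3), rep("SPLEEN", 2)),
    finding = c("CELLULARITY, INCREASED", "ALVEOLAR MACROPHAGES, INCREASED",
                "AGGREGATE", "CELLULARITY, INCREASED", "FOLLICLES, INCREASED"),
    n = c(6L, 48L, 2L, 21L, 3L),
    severity = "MINIMAL",
    stringsAsFactors = FALSE)
  idx <- with_seed(seed, sample(total))
  k <- 0L
  assign_rows <- list()
  for (r in seq_len(nrow(plan))) {
    take <- idx[seq_len(plan$n[r]) + k]
    k <- k + plan$n[r]
    assign_rows[[r]] <- data.frame(subj = take, specimen = plan$specimen[r],
                                   finding = plan$finding[r],
                                   severity = plan$severity[r],
                                   stringsAsFactors = FALSE)
  }
  assigned <- do.call(rbind, assign_rows)
  starts <- c("2019-02-04", "2019-09-16", "2020-05-11")
  offsets <- c(0L, cumsum(n_per))
  studies <- vector("list", length(n_per))
  for (j in seq_along(n_per)) {
    in_study <- assigned$subj > offsets[j] & assigned$subj <= offsets[j + 1L]
    mr <- assigned[in_study, , drop = FALSE]
    mr$subj <- mr$subj - offsets[j]
    # ensure both specimens appear in every study even if no finding landed
    spec <- study_spec(
      seed = seed + j, studyid = sprintf("HC-%03d", j),
      start_date = starts[j],
      sets = data.frame(setcd = "CTL", set = "Vehicle control",
                        tcntrl = "VEHICLE CONTROL", n = n_per[j],
                        stringsAsFactors = FALSE),
      mi_records = rbind(
        mr,
        data.frame(subj = integer(0), specimen = character(0),
                   finding = character(0), severity = character(0))),
      bw_days = c(1L, 28L))
    spec$mi_records_specimens <- c("LUNG/BRONCHUS", "SPLEEN")
    studies[[j]] <- make_study_usecase2(spec, out_dir)
  }
  pre <- stats::aggregate(n ~ specimen + finding, data = plan, FUN = sum)
  post <- data.frame(
    specimen = c("LUNG/BRONCHUS", "SPLEEN"),
    finding = "CELLULARITY, INCREASED",
    n = c(56L, 24L), stringsAsFactors = FALSE)
  truth <- list(
    n_animals = total,
    pre_clean_counts = pre,
    post_clean_counts = post,
    n_examined = stats::setNames(c(total, total),
                                 c("LUNG/BRONCHUS", "SPLEEN")))
  list(folder = out_dir, studies = studies, truth = truth)
}

# make_study, but guaranteeing every specimen in `mi_records_specimens` is
# examined in every animal even when no planted finding fell in the study.
make_study_usecase2 <- function(spec, out_dir) {
  if (!is.null(spec$mi_records_specimens)) {
    have <- unique(spec$mi_records$specimen)
    missing <- setdiff(spec$mi_records_specimens, have)
    for (sp in missing) {
      # a zero-row plan entry cannot carry the specimen; plant an explicit
      # UNREMARKABLE record on animal 1 so the specimen column exists
      spec$mi_records <- rbind(
        spec$mi_records,
        data.frame(subj = 1L, specimen = sp, finding = "UNREMARKABLE",
                   severity = NA_character_, stringsAsFactors = FALSE))
    }
    # reorder so specimen MISEQ assignment is stable across studies
    spec$mi_records$specimen <- factor(spec$mi_records$specimen,
                                       levels = spec$mi_records_specimens)
    spec$mi_records <- spec$mi_records[order(spec$mi_records$specimen), ]
    spec$mi_records$specimen <- as.character(spec$mi_records$specimen)
  }
  make_study(spec, out_dir)
}

#' Write the packaged controlled-terminology fixture
#'
#' A small tab-delimited CT file covering the ten supported codelists with
#' at least three terms each, including the lung/spleen cellularity
#' mappings (ALVEOLAR MACROPHAGES, INCREASED; AGGREGATE; FOLLICLES,
#' INCREASED -> CELLULARITY, INCREASED). Output is deterministic.
#'
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
make_ct_fixture <- function(out_path) {
  rows <- list(
    c("Sex", "M", "MALE", "No"),
    c("Sex", "F", "FEMALE", "No"),
    c("Sex", "U", "UNKNOWN;UNDIFFERENTIATED", "No"),
    c("Species", "RAT", "RATTUS NORVEGICUS", "Yes"),
    c("Species", "MOUSE", "MUS MUSCULUS", "Yes"),
    c("Species", "DOG", "CANIS FAMILIARIS;CANINE", "Yes"),
    c("Strain/Substrain", "SPRAGUE-DAWLEY", "SD;CRL:CD(SD);SPRAGUE DAWLEY", "Yes"),
    c("Strain/Substrain", "WISTAR", "WISTAR HAN;CRL:WI(HAN)", "Yes"),
    c("Strain/Substrain", "BEAGLE", "CANINE BEAGLE", "Yes"),
    c("SEND Severity", "MINIMAL", "1 OF 5;GRADE 1", "No"),
    c("SEND Severity", "MILD", "2 OF 5;SLIGHT;GRADE 2", "No"),
    c("SEND Severity", "MODERATE", "3 OF 5;GRADE 3", "No"),
    c("Route of Administration Response", "ORAL GAVAGE", "PO GAVAGE;GAVAGE, ORAL", "Yes"),
    c("Route of Administration Response", "INTRAVENOUS", "IV;I.V.", "Yes"),
    c("Route of Administration Response", "SUBCUTANEOUS", "SC;S.C.", "Yes"),
    c("Standardized Disposition Term", "TERMINAL SACRIFICE", "SCHEDULED EUTHANASIA;SCHEDULED SACRIFICE", "Yes"),
    c("Standardized Disposition Term", "MORIBUND SACRIFICE", "EUTHANIZED MORIBUND", "Yes"),
    c("Standardized Disposition Term", "FOUND DEAD", "DIED;DEATH", "Yes"),
    c("Specimen", "LUNG/BRONCHUS", "LUNG WITH BRONCHUS;LUNG, BRONCHUS", "Yes"),
    c("Specimen", "SPLEEN", "SPLENIC TISSUE", "Yes"),
    c("Specimen", "LIVER", "HEPATIC TISSUE", "Yes"),
    c("Anatomical Location", "ALVEOLUS", "ALVEOLAR", "Yes"),
    c("Anatomical Location", "CORTEX", "CORTICAL", "Yes"),
    c("Anatomical Location", "MEDULLA", "MEDULLARY", "Yes"),
    c("Non-Neoplastic Finding Type", "CELLULARITY, INCREASED",
      "ALVEOLAR MACROPHAGES, INCREASED;AGGREGATE;FOLLICLES, INCREASED;INCREASED CELLULARITY", "Yes"),
    c("Non-Neoplastic Finding Type", "NECROSIS", "NECROTIC;NECROSIS, FOCAL", "Yes"),
    c("Non-Neoplastic Finding Type", "INFLAMMATION", "INFLAMMATION, CHRONIC;INFLAMMATORY INFILTRATE", "Yes"),
    c("Non-Neoplastic Finding Type", "UNREMARKABLE", "NORMAL;NO ABNORMALITIES DETECTED", "Yes"),
    c("SEND Control Type", "VEHICLE CONTROL", "VEHICLE;SALINE CONTROL", "Yes"),
    c("SEND Control Type", "UNTREATED CONTROL", "UNTREATED;NO TREATMENT", "Yes"),
    c("SEND Control Type", "SHAM CONTROL", "SHAM", "Yes"),
    c("SEND Control Type", "POSITIVE CONTROL", "POSITIVE", "Yes"))
  mat <- do.call(rbind, rows)
  df <- stats::setNames(data.frame(mat, stringsAsFactors = FALSE),
                        c("Codelist Name", "CDISC Submission Value",
                          "CDISC Synonym(s)", "Codelist Extensible (Yes/No)"))
  utils::write.table(df, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
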