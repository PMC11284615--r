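# -- helpers ------------------------------------------------------------------

norm_term <- function(x) toupper(trimws(x))

# Parse a possibly-partial ISO 8601 date (YYYY, YYYY-MM, YYYY-MM-DD, optional
# time part) into the interval of calendar dates it could denote.
parse_iso_partial <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T.*$", "", x)
  lo <- rep(as.Date(NA), length(x))
  hi <- lo
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  y <- grepl("^\\d{4}$", x)
  lo[full] <- as.Date(x[full])
  hi[full] <- lo[full]
  if (any(ym)) {
    lo[ym] <- as.Date(paste0(x[ym], "-01"))
    hi[ym] <- seq_next_month(lo[ym]) - 1L
  }
  if (any(y)) {
    lo[y] <- as.Date(paste0(x[y], "-01-01"))
    hi[y] <- as.Date(paste0(x[y], "-12-31"))
  }
  data.frame(lo = lo, hi = hi)
}

seq_next_month <- function(d) {
  # first day of the following month, vectorized
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  yr <- yr + (mo == 12L)
  mo <- ifelse(mo == 12L, 1L, mo + 1L)
  as.Date(sprintf("%04d-%02d-01", yr, mo))
}

iso_date <- function(x) {
  x <- sub("T.*$", "", as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok])
  out
}

add_uncertain <- function(old, msg) {
  ifelse(is.na(old) | old == "", msg, paste(old, msg, sep = "; "))
}

# Built-in SEX codelist so "Male"/"M" compare equal without a vocabulary.
SEX_CODELIST <- c("M" = "M", "MALE" = "M", "F" = "F", "FEMALE" = "F",
                  "U" = "U", "UNKNOWN" = "U", "INTERSEX" = "I", "I" = "I")

# Map values through a vocabulary codelist (when supplied), else through a
# built-in fallback, else pass through; always returns normalized terms.
map_terms <- function(values, codelist, vocab = NULL) {
  v <- norm_term(values)
  if (!is.null(vocab) && codelist %in% names(vocab$codelists)) {
    cl <- vocab$codelists[[codelist]]
    hit <- v %in% names(cl)
    v[hit] <- norm_term(unname(cl[v[hit]]))
    return(v)
  }
  if (codelist == "sex") {
    hit <- v %in% names(SEX_CODELIST)
    v[hit] <- unname(SEX_CODELIST[v[hit]])
  }
  v
}

ts_params <- function(db, studyids, parmcd) {
  if (!length(studyids)) {
    return(data.frame(STUDYID = character(0), TSVAL = character(0)))
  }
  sql <- sprintf(
    'SELECT STUDYID, TSVAL FROM TS WHERE UPPER(TSPARMCD) = ? AND STUDYID IN (%s)',
    paste(rep("?", length(studyids)), collapse = ","))
  DBI::dbGetQuery(db$con, sql, params = c(list(parmcd), as.list(studyids)))
}

empty_study_set <- function() {
  data.frame(STUDYID = character(0), SDESIGN = character(0),
             STSTDTC = character(0), UNCERTAIN_MSG = character(0),
             stringsAsFactors = FALSE)
}

base_study_set <- function(db) {
  ids <- db_studyids(db)
  if (!length(ids)) return(empty_study_set())
  sd <- ts_params(db, ids, "SDESIGN")
  st <- ts_params(db, ids, "STSTDTC")
  out <- data.frame(STUDYID = ids, stringsAsFactors = FALSE)
  out$SDESIGN <- sd$TSVAL[match(ids, sd$STUDYID)]
  out$STSTDTC <- st$TSVAL[match(ids, st$STUDYID)]
  out$UNCERTAIN_MSG <- NA_character_
  out
}

# -- study-level filters ------------------------------------------------------

#' Filter studies by study design (TS parameter SDESIGN)
#'
#' @param db a `send_db` handle.
#' @param design study design to keep (case-insensitive), or `NULL` for all.
#' @param prior a prior study set to refine, or `NULL` for all studies in the
#'   database.
#' @param incl_uncertain keep studies lacking an SDESIGN row, flagged in
#'   `UNCERTAIN_MSG`.
#' @return A study set: data frame with `STUDYID`, `SDESIGN`, `STSTDTC`,
#'   `UNCERTAIN_MSG`.
#' @export
get_studies_sdesign <- function(db, design = NULL, prior = NULL,
                                incl_uncertain = FALSE) {
  db_check_open(db)
  ss <- if (is.null(prior)) base_study_set(db) else prior
  if (is.null(design)) return(ss)
  have <- !is.na(ss$SDESIGN) & nzchar(trimws(ss$SDESIGN))
  keep <- have & norm_term(ss$SDESIGN) == norm_term(design)
  unc <- !have
  if (incl_uncertain) {
    ss$UNCERTAIN_MSG[unc] <- add_uncertain(ss$UNCERTAIN_MSG[unc], "SDESIGN missing")
    ss[keep | unc, , drop = FALSE]
  } else {
    ss[keep, , drop = FALSE]
  }
}

#' Filter studies by study start date (TS parameter STSTDTC)
#'
#' Dates may be partial ISO 8601 (`YYYY` or `YYYY-MM`); a partial study date
#' matches the interval if any completion of it does. The interval test is
#' inclusive on both ends; a `NULL` bound is open.
#'
#' @inheritParams get_studies_sdesign
#' @param from_date,to_date ISO 8601 bounds (possibly partial) or `NULL`.
#' @return A study set (see [get_studies_sdesign()]).
#' @export
get_studies_ststdtc <- function(db, from_date = NULL, to_date = NULL,
                                prior = NULL, incl_uncertain = FALSE) {
  db_check_open(db)
  ss <- if (is.null(prior)) base_study_set(db) else prior
  if (is.null(from_date) && is.null(to_date)) return(ss)
  from_lo <- if (is.null(from_date)) as.Date("0001-01-01") else parse_iso_partial(from_date)$lo
  to_hi <- if (is.null(to_date)) as.Date("9999-12-31") else parse_iso_partial(to_date)$hi
  if (is.na(from_lo) || is.na(to_hi)) stop("unparseable date bound")
  if (from_lo > to_hi) stop("invalid date range: from_date > to_date")
  iv <- parse_iso_partial(ss$STSTDTC)
  have <- !is.na(iv$lo)
  keep <- have & iv$hi >= from_lo & iv$lo <= to_hi
  unc <- !have
  if (incl_uncertain) {
    ss$UNCERTAIN_MSG[unc] <- add_uncertain(ss$UNCERTAIN_MSG[unc],
                                           "STSTDTC missing or unparseable")
    ss[keep | unc, , drop = FALSE]
  } else {
    ss[keep, , drop = FALSE]
  }
}

# -- subject-level filters ----------------------------------------------------

NEGATIVE_CONTROL_PATTERNS <- c("VEHICLE", "PLACEBO", "SHAM", "UNTREATED",
                               "NO TREATMENT", "NEGATIVE")

is_negative_control <- function(tcntrl) {
  v <- norm_term(tcntrl)
  has_neg <- Reduce(`|`, lapply(NEGATIVE_CONTROL_PATTERNS,
                                function(p) grepl(p, v, fixed = TRUE)))
  has_neg & !grepl("POSITIVE", v, fixed = TRUE)
}

empty_subject_set <- function() {
  data.frame(STUDYID = character(0), USUBJID = character(0),
             SETCD = character(0), TCNTRL = character(0), SEX = character(0),
             SPECIES = character(0), STRAIN = character(0),
             ROUTE = character(0), BRTHDTC = character(0),
             RFSTDTC = character(0), AGE = numeric(0), AGEU = character(0),
             UNCERTAIN_MSG = character(0), stringsAsFactors = FALSE)
}

dm_for_studies <- function(db, studyids) {
  if (!length(studyids)) return(NULL)
  sql <- sprintf('SELECT * FROM DM WHERE STUDYID IN (%s)',
                 paste(rep("?", length(studyids)), collapse = ","))
  DBI::dbGetQuery(db$con, sql, params = as.list(studyids))
}

#' Select negative-control subjects for a study set
#'
#' Trial sets (TX) whose TCNTRL parameter matches a negative-control pattern
#' (contains VEHICLE, PLACEBO, SHAM, UNTREATED, NO TREATMENT or NEGATIVE and
#' not POSITIVE, after vocabulary mapping) are selected; their subjects are
#' all DM rows with the set's SETCD. Sets with a missing or unrecognized
#' TCNTRL — and all subjects of studies without a TX table — are included
#' only with `incl_uncertain = TRUE`, flagged in `UNCERTAIN_MSG`. Sets with
#' an explicit positive-control TCNTRL are always excluded.
#'
#' @param db a `send_db` handle.
#' @param studies a study set from the study-level filters.
#' @param incl_uncertain include uncertain subjects, flagged.
#' @param vocab optional `send_vocab` used to map TCNTRL values through the
#'   SEND control type codelist before pattern matching.
#' @return A subject set: data frame with `STUDYID`, `USUBJID`, `SETCD`,
#'   `TCNTRL`, `SEX`, `SPECIES`, `STRAIN`, `ROUTE`, `BRTHDTC`, `RFSTDTC`,
#'   `AGE`, `AGEU`, `UNCERTAIN_MSG`.
#' @export
get_control_subj <- function(db, studies, incl_uncertain = FALSE, vocab = NULL) {
  db_check_open(db)
  ids <- studies$STUDYID
  if (!length(ids)) return(empty_subject_set())
  tx <- DBI::dbGetQuery(db$con, sprintf(
    'SELECT STUDYID, SETCD, TXPARMCD, TXVAL FROM TX WHERE STUDYID IN (%s)',
    paste(rep("?", length(ids)), collapse = ",")), params = as.list(ids))
  dm <- dm_for_studies(db, ids)
  if (is.null(dm) || nrow(dm) == 0L) return(empty_subject_set())
  tc <- tx[!is.na(tx$TXPARMCD) & norm_term(tx$TXPARMCD) == "TCNTRL", ,
           drop = FALSE]
  sets <- unique(tx[, c("STUDYID", "SETCD")])
  key <- function(s, c) paste(s, c, sep = "\r")
  tcv <- stats::setNames(tc$TXVAL, key(tc$STUDYID, tc$SETCD))
  studies_with_tx <- unique(tx$STUDYID)

  dm$TCNTRL <- unname(tcv[key(dm$STUDYID, dm$SETCD)])
  mapped <- map_terms(dm$TCNTRL, "send control type", vocab)
  has_tc <- !is.na(dm$TCNTRL) & nzchar(trimws(dm$TCNTRL))
  neg <- has_tc & is_negative_control(mapped)
  pos <- has_tc & grepl("POSITIVE", mapped, fixed = TRUE)
  no_tx <- !(dm$STUDYID %in% studies_with_tx)
  unc_missing <- (!has_tc | no_tx) & !pos
  unc_ambig <- has_tc & !neg & !pos & !no_tx

  msg <- rep(NA_character_, nrow(dm))
  msg[unc_missing & no_tx] <- "no TX trial sets for study"
  msg[unc_missing & !no_tx] <- "TCNTRL missing for trial set"
  msg[unc_ambig] <- "TCNTRL not a recognized negative control"

  keep <- neg | (incl_uncertain & (unc_missing | unc_ambig))
  out <- dm[keep, , drop = FALSE]
  msg <- msg[keep]

  res <- data.frame(
    STUDYID = out$STUDYID, USUBJID = out$USUBJID,
    SETCD = if ("SETCD" %in% names(out)) out$SETCD else NA_character_,
    TCNTRL = out$TCNTRL,
    SEX = if ("SEX" %in% names(out)) out$SEX else NA_character_,
    SPECIES = if ("SPECIES" %in% names(out)) out$SPECIES else NA_character_,
    STRAIN = if ("STRAIN" %in% names(out)) out$STRAIN else NA_character_,
    ROUTE = NA_character_,
    BRTHDTC = if ("BRTHDTC" %in% names(out)) out$BRTHDTC else NA_character_,
    RFSTDTC = if ("RFSTDTC" %in% names(out)) out$RFSTDTC else NA_character_,
    AGE = if ("AGE" %in% names(out)) out$AGE else NA_real_,
    AGEU = if ("AGEU" %in% names(out)) out$AGEU else NA_character_,
    UNCERTAIN_MSG = msg, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Filter subjects by sex
#'
#' Comparison is case-insensitive after mapping both sides through the sex
#' codelist (so `"Male"` and `"M"` compare equal). `sex = NULL` is the
#' identity.
#'
#' @param db a `send_db` handle.
#' @param subjects a subject set.
#' @param sex requested sex or `NULL`.
#' @param incl_uncertain keep subjects with missing SEX, flagged.
#' @param vocab optional `send_vocab` (sex codelist).
#' @return A subject set.
#' @export
get_subj_sex <- function(db, subjects, sex = NULL, incl_uncertain = FALSE,
                         vocab = NULL) {
  if (is.null(sex)) return(subjects)
  have <- !is.na(subjects$SEX) & nzchar(trimws(subjects$SEX))
  keep <- have & map_terms(subjects$SEX, "sex", vocab) ==
    map_terms(sex, "sex", vocab)
  unc <- !have
  if (incl_uncertain) {
    subjects$UNCERTAIN_MSG[unc] <- add_uncertain(subjects$UNCERTAIN_MSG[unc],
                                                 "SEX missing")
    subjects[keep | unc, , drop = FALSE]
  } else {
    subjects[keep, , drop = FALSE]
  }
}

tx_set_param <- function(db, studyids, parmcd) {
  if (!length(studyids)) {
    return(data.frame(STUDYID = character(0), SETCD = character(0),
                      TXVAL = character(0)))
  }
  DBI::dbGetQuery(db$con, sprintf(
    'SELECT STUDYID, SETCD, TXVAL FROM TX WHERE UPPER(TXPARMCD) = ? AND STUDYID IN (%s)',
    paste(rep("?", length(studyids)), collapse = ",")),
    params = c(list(parmcd), as.list(studyids)))
}

resolve_subject_attr <- function(db, subjects, dm_col, parmcd) {
  ids <- unique(subjects$STUDYID)
  val <- subjects[[dm_col]]
  val[!is.na(val) & !nzchar(trimws(val))] <- NA_character_
  need <- is.na(val)
  if (any(need)) {
    tx <- tx_set_param(db, ids, parmcd)
    if (nrow(tx)) {
      k <- paste(tx$STUDYID, tx$SETCD, sep = "\r")
      m <- stats::setNames(tx$TXVAL, k)
      got <- unname(m[paste(subjects$STUDYID, subjects$SETCD, sep = "\r")])
      val[need] <- got[need]
      need <- is.na(val)
    }
  }
  if (any(need)) {
    ts <- ts_params(db, ids, parmcd)
    if (nrow(ts)) {
      m <- stats::setNames(ts$TSVAL, ts$STUDYID)
      got <- unname(m[subjects$STUDYID])
      val[need] <- got[need]
    }
  }
  val
}

#' Filter subjects by species and strain
#'
#' Species and strain are resolved per subject with precedence
#' DM > trial-set TX parameter > TS parameter, then compared
#' case-insensitively after vocabulary mapping. A `NULL` criterion is the
#' identity on that axis. The resolved values are written back to the
#' `SPECIES`/`STRAIN` columns.
#'
#' @inheritParams get_subj_sex
#' @param species,strain requested values or `NULL`.
#' @return A subject set.
#' @export
get_subj_species_strain <- function(db, subjects, species = NULL,
                                    strain = NULL, incl_uncertain = FALSE,
                                    vocab = NULL) {
  db_check_open(db)
  if (!nrow(subjects)) return(subjects)
  subjects$SPECIES <- resolve_subject_attr(db, subjects, "SPECIES", "SPECIES")
  subjects$STRAIN <- resolve_subject_attr(db, subjects, "STRAIN", "STRAIN")
  keep <- rep(TRUE, nrow(subjects))
  unc <- rep(FALSE, nrow(subjects))
  if (!is.null(species)) {
    have <- !is.na(subjects$SPECIES)
    ok <- have & map_terms(subjects$SPECIES, "species", vocab) ==
      map_terms(species, "species", vocab)
    subjects$UNCERTAIN_MSG[!have] <- add_uncertain(subjects$UNCERTAIN_MSG[!have],
                                                   "SPECIES missing")
    keep <- keep & ok
    unc <- unc | !have
  }
  if (!is.null(strain)) {
    have <- !is.na(subjects$STRAIN)
    ok <- have & map_terms(subjects$STRAIN, "strain/substrain", vocab) ==
      map_terms(strain, "strain/substrain", vocab)
    subjects$UNCERTAIN_MSG[!have] <- add_uncertain(subjects$UNCERTAIN_MSG[!have],
                                                   "STRAIN missing")
    keep <- keep & ok
    unc <- unc | !have
  }
  if (incl_uncertain) {
    subjects[keep | unc, , drop = FALSE]
  } else {
    subjects[keep, , drop = FALSE]
  }
}

#' Filter subjects by route of administration
#'
#' Route is resolved per subject with precedence EX.EXROUTE (any dosing
#' record) > TS parameter ROUTE, compared case-insensitively after
#' vocabulary mapping. `route = NULL` is the identity. The resolved value is
#' written to the `ROUTE` column.
#'
#' @inheritParams get_subj_sex
#' @param route requested route or `NULL`.
#' @return A subject set.
#' @export
get_subj_route <- function(db, subjects, route = NULL, incl_uncertain = FALSE,
                           vocab = NULL) {
  db_check_open(db)
  if (!nrow(subjects)) return(subjects)
  ids <- unique(subjects$STUDYID)
  ex <- DBI::dbGetQuery(db$con, sprintf(
    'SELECT DISTINCT STUDYID, USUBJID, EXROUTE FROM EX WHERE EXROUTE IS NOT NULL AND STUDYID IN (%s)',
    paste(rep("?", length(ids)), collapse = ",")), params = as.list(ids))
  val <- rep(NA_character_, nrow(subjects))
  if (nrow(ex)) {
    ex <- ex[!duplicated(paste(ex$STUDYID, ex$USUBJID, sep = "\r")), ]
    m <- stats::setNames(ex$EXROUTE, paste(ex$STUDYID, ex$USUBJID, sep = "\r"))
    val <- unname(m[paste(subjects$STUDYID, subjects$USUBJID, sep = "\r")])
  }
  need <- is.na(val)
  if (any(need)) {
    ts <- ts_params(db, ids, "ROUTE")
    if (nrow(ts)) {
      m <- stats::setNames(ts$TSVAL, ts$STUDYID)
      val[need] <- unname(m[subjects$STUDYID])[need]
    }
  }
  subjects$ROUTE <- val
  if (is.null(route)) return(subjects)
  have <- !is.na(val)
  keep <- have & map_terms(val, "route of administration response", vocab) ==
    map_terms(route, "route of administration response", vocab)
  unc <- !have
  if (incl_uncertain) {
    subjects$UNCERTAIN_MSG[unc] <- add_uncertain(subjects$UNCERTAIN_MSG[unc],
                                                 "ROUTE missing")
    subjects[keep | unc, , drop = FALSE]
  } else {
    subjects[keep, , drop = FALSE]
  }
}

# -- findings extraction ------------------------------------------------------

#' Extract a findings domain for a subject set
#'
#' Returns all rows of the requested domain belonging to the subject set's
#' (STUDYID, USUBJID) pairs, with derived columns `AGEDAYS` and `PHASE`
#' initialized to `NA` (populate them with [get_findings_subj_age()] and
#' [get_findings_phase()]).
#'
#' @param db a `send_db` handle.
#' @param subjects a subject set.
#' @param domain findings domain code (e.g. `"MI"`, `"LB"`, `"BW"`).
#' @return A findings table (data frame with attribute `domain`).
#' @export
get_subj_data <- function(db, subjects, domain) {
  db_check_open(db)
  domain <- toupper(domain)
  tbl <- db_table_for_domain(domain)
  if (!tbl %in% DBI::dbListTables(db$con)) {
    stop("no such domain table in database: ", domain)
  }
  if (!"USUBJID" %in% DBI::dbListFields(db$con, tbl)) {
    stop("unsupported domain for subject-level extraction (no USUBJID): ", domain)
  }
  if (!nrow(subjects)) {
    cols <- DBI::dbListFields(db$con, tbl)
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else {
    ids <- unique(subjects$STUDYID)
    out <- DBI::dbGetQuery(db$con, sprintf(
      'SELECT * FROM "%s" WHERE STUDYID IN (%s)', tbl,
      paste(rep("?", length(ids)), collapse = ",")), params = as.list(ids))
    keep <- paste(out$STUDYID, out$USUBJID, sep = "\r") %in%
      paste(subjects$STUDYID, subjects$USUBJID, sep = "\r")
    out <- out[keep, , drop = FALSE]
  }
  out$AGEDAYS <- rep(NA_integer_, nrow(out))
  out$PHASE <- rep(NA_character_, nrow(out))
  out$UNCERTAIN_MSG <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  attr(out, "domain") <- domain
  out
}

findings_domain <- function(findings, default = NULL) {
  d <- attr(findings, "domain", exact = TRUE)
  if (is.null(d)) d <- default
  if (is.null(d)) stop("findings table has no domain attribute")
  toupper(d)
}

# -- age derivation -----------------------------------------------------------

AGEU_DAYS <- c(DAYS = 1, DAY = 1, WEEKS = 7, WEEK = 7,
               MONTHS = 30.4375, MONTH = 30.4375,
               YEARS = 365.25, YEAR = 365.25)

# SEND study-day convention: day 1 is the reference start day, there is no
# day 0; the offset in calendar days from RFSTDTC is DY-1 for DY >= 1 and DY
# for DY < 0.
study_day_offset <- function(dy) {
  if (any(!is.na(dy) & dy == 0)) stop("invalid study day 0 (SEND has no day 0)")
  ifelse(is.na(dy), NA_real_, ifelse(dy >= 1, dy - 1, dy))
}

#' Derive an animal's age in days at a finding
#'
#' Resolution order: (1) finding date and birth date -> calendar-day
#' difference; (2) birth date and reference start date -> age at reference
#' start plus the study-day offset; (3) DM AGE/AGEU converted to days
#' (DAYS x 1, WEEKS x 7, MONTHS x 30.4375, YEARS x 365.25, rounded) plus the
#' study-day offset; otherwise `NA`. The study-day offset comes from `dy`
#' (`--DY - 1` for days >= 1, `--DY` for negative days; day 0 is an error)
#' or, when `dy` is absent, from the calendar difference `dtc - rfstdtc`;
#' with neither, 0.
#'
#' @param brthdtc,rfstdtc,dtc ISO 8601 date strings (may be `NA`).
#' @param age,ageu DM age value and unit.
#' @param dy study day of the finding (`--DY`).
#' @return Integer vector of ages in whole days (`NA` when underivable;
#'   negative derivations are returned as `NA`).
#' @export
derive_age_days <- function(brthdtc, rfstdtc = NA, age = NA, ageu = NA,
                            dtc = NA, dy = NA) {
  n <- max(length(brthdtc), length(rfstdtc), length(age), length(ageu),
           length(dtc), length(dy))
  brth <- iso_date(rep_len(as.character(brthdtc), n))
  rfst <- iso_date(rep_len(as.character(rfstdtc), n))
  fdt <- iso_date(rep_len(as.character(dtc), n))
  age <- suppressWarnings(as.numeric(rep_len(age, n)))
  ageu <- norm_term(rep_len(as.character(ageu), n))
  dy <- suppressWarnings(as.numeric(rep_len(dy, n)))

  off <- study_day_offset(dy)
  dtc_off <- as.numeric(fdt - rfst)
  off[is.na(off)] <- dtc_off[is.na(off)]
  off[is.na(off)] <- 0

  out <- rep(NA_real_, n)
  r1 <- !is.na(fdt) & !is.na(brth)
  out[r1] <- as.numeric(fdt[r1] - brth[r1])
  r2 <- is.na(out) & !is.na(brth) & !is.na(rfst)
  out[r2] <- as.numeric(rfst[r2] - brth[r2]) + off[r2]
  conv <- unname(AGEU_DAYS[ageu])
  r3 <- is.na(out) & !is.na(age) & !is.na(conv)
  out[r3] <- round(age[r3] * conv[r3]) + off[r3]
  out <- round(out)
  out[!is.na(out) & out < 0] <- NA_real_
  as.integer(out)
}

#' Populate AGEDAYS and filter findings by animal age
#'
#' `AGEDAYS` is derived per row via [derive_age_days()]; rows are kept when
#' `min_days <= AGEDAYS <= max_days` (inclusive). Rows whose age cannot be
#' derived are kept only with `incl_uncertain = TRUE`, flagged.
#'
#' @param findings a findings table from [get_subj_data()].
#' @param subjects the subject set the findings came from.
#' @param min_days,max_days inclusive bounds in days, or `NULL` for open.
#' @param incl_uncertain keep unknown-age rows, flagged.
#' @return A findings table with `AGEDAYS` populated.
#' @export
get_findings_subj_age <- function(findings, subjects, min_days = NULL,
                                  max_days = NULL, incl_uncertain = FALSE) {
  if (!is.null(min_days) && !is.null(max_days) && min_days > max_days) {
    stop("invalid age range: min_days > max_days")
  }
  dom <- findings_domain(findings)
  dtc_col <- paste0(dom, "DTC")
  dy_col <- paste0(dom, "DY")
  k <- paste(findings$STUDYID, findings$USUBJID, sep = "\r")
  si <- match(k, paste(subjects$STUDYID, subjects$USUBJID, sep = "\r"))
  n <- nrow(findings)
  ad <- derive_age_days(
    brthdtc = subjects$BRTHDTC[si], rfstdtc = subjects$RFSTDTC[si],
    age = subjects$AGE[si], ageu = subjects$AGEU[si],
    dtc = if (dtc_col %in% names(findings)) findings[[dtc_col]] else rep(NA, n),
    dy = if (dy_col %in% names(findings)) findings[[dy_col]] else rep(NA, n))
  findings$AGEDAYS <- ad
  if (is.null(min_days) && is.null(max_days)) return(findings)
  lo <- if (is.null(min_days)) -Inf else min_days
  hi <- if (is.null(max_days)) Inf else max_days
  have <- !is.na(ad)
  keep <- have & ad >= lo & ad <= hi
  if (incl_uncertain) {
    findings$UNCERTAIN_MSG[!have] <- add_uncertain(findings$UNCERTAIN_MSG[!have],
                                                   "age unknown")
    out <- findings[keep | !have, , drop = FALSE]
  } else {
    out <- findings[keep, , drop = FALSE]
  }
  attr(out, "domain") <- dom
  rownames(out) <- NULL
  out
}

# -- phase classification -----------------------------------------------------

#' Classify an epoch label into a study phase
#'
#' Case-insensitive keyword rules, first match wins: screening keywords
#' (screen, pre-treat, pretreat, acclimat, baseline), then recovery keywords
#' (recovery, post-treat, posttreat, washout), then treatment keywords
#' (treat, dos, exposure); anything else is `"Uncertain"`. Ordering matters:
#' "PRETREATMENT" is Screening, not Treatment.
#'
#' @param epoch_label character vector of epoch labels.
#' @return Character vector: `"Screening"`, `"Treatment"`, `"Recovery"` or
#'   `"Uncertain"`.
#' @export
classify_epoch <- function(epoch_label) {
  v <- tolower(as.character(epoch_label))
  out <- rep("Uncertain", length(v))
  scr <- grepl("screen|pre-treat|pretreat|acclimat|baseline", v)
  rec <- !scr & grepl("recovery|post-treat|posttreat|washout", v)
  trt <- !scr & !rec & grepl("treat|dos|exposure", v)
  out[trt] <- "Treatment"
  out[rec] <- "Recovery"
  out[scr] <- "Screening"
  out[is.na(v)] <- "Uncertain"
  out
}

#' Populate PHASE and filter findings by study phase
#'
#' Each finding is located in its subject's SE epoch (half-open interval
#' `SESTDTC <= --DTC < SEENDTC`; a missing SEENDTC on the last epoch is
#' open-ended). When the finding has no date, its study day is compared
#' against epoch day bounds derived from the subject's RFSTDTC. The matched
#' epoch label is classified via [classify_epoch()]; findings without SE
#' data are `"Uncertain"` and kept only with `incl_uncertain = TRUE`.
#'
#' @param db a `send_db` handle.
#' @param findings a findings table.
#' @param phase requested phase (`"Screening"`, `"Treatment"`, `"Recovery"`)
#'   or `NULL` for the identity (PHASE still populated).
#' @param incl_uncertain keep `"Uncertain"` rows, flagged.
#' @return A findings table with `PHASE` populated.
#' @export
get_findings_phase <- function(db, findings, phase = NULL,
                               incl_uncertain = FALSE) {
  db_check_open(db)
  dom <- findings_domain(findings)
  n <- nrow(findings)
  ph <- rep("Uncertain", n)
  if (n > 0L) {
    ids <- unique(findings$STUDYID)
    qs <- paste(rep("?", length(ids)), collapse = ",")
    se <- DBI::dbGetQuery(db$con, sprintf(
      'SELECT STUDYID, USUBJID, EPOCH, ELEMENT, SESTDTC, SEENDTC FROM SE WHERE STUDYID IN (%s)',
      qs), params = as.list(ids))
    dm <- DBI::dbGetQuery(db$con, sprintf(
      'SELECT STUDYID, USUBJID, RFSTDTC FROM DM WHERE STUDYID IN (%s)', qs),
      params = as.list(ids))
    rfst <- stats::setNames(dm$RFSTDTC, paste(dm$STUDYID, dm$USUBJID, sep = "\r"))
    dtc_col <- paste0(dom, "DTC")
    dy_col <- paste0(dom, "DY")
    fdt <- if (dtc_col %in% names(findings)) iso_date(findings[[dtc_col]]) else rep(as.Date(NA), n)
    fdy <- if (dy_col %in% names(findings)) suppressWarnings(as.numeric(findings[[dy_col]])) else rep(NA_real_, n)
    se_key <- paste(se$STUDYID, se$USUBJID, sep = "\r")
    se_split <- split(seq_len(nrow(se)), se_key)
    f_key <- paste(findings$STUDYID, findings$USUBJID, sep = "\r")
    for (i in seq_len(n)) {
      rows <- se_split[[f_key[i]]]
      if (is.null(rows) || !length(rows)) next
      ep <- se[rows, , drop = FALSE]
      st <- iso_date(ep$SESTDTC)
      en <- iso_date(ep$SEENDTC)
      o <- order(st)
      ep <- ep[o, , drop = FALSE]; st <- st[o]; en <- en[o]
      lbl <- if (!all(is.na(ep$EPOCH))) ep$EPOCH else ep$ELEMENT
      hit <- NA_integer_
      if (!is.na(fdt[i])) {
        for (j in seq_along(st)) {
          lo_ok <- !is.na(st[j]) && fdt[i] >= st[j]
          hi_ok <- is.na(en[j]) || fdt[i] < en[j]
          if (lo_ok && hi_ok) { hit <- j; break }
        }
      } else if (!is.na(fdy[i])) {
        rf <- iso_date(rfst[f_key[i]])
        if (!is.na(rf)) {
          day_of <- function(d) ifelse(as.numeric(d - rf) >= 0,
                                       as.numeric(d - rf) + 1, as.numeric(d - rf))
          sd <- day_of(st); ed <- day_of(en)
          for (j in seq_along(sd)) {
            lo_ok <- !is.na(sd[j]) && fdy[i] >= sd[j]
            hi_ok <- is.na(ed[j]) || fdy[i] < ed[j]
            if (lo_ok && hi_ok) { hit <- j; break }
          }
        }
      }
      if (!is.na(hit)) ph[i] <- classify_epoch(lbl[hit])
    }
  }
  findings$PHASE <- ph
  if (is.null(phase)) return(findings)
  phase <- match.arg(phase, c("Screening", "Treatment", "Recovery", "Uncertain"))
  keep <- ph == phase
  unc <- ph == "Uncertain" & phase != "Uncertain"
  if (incl_uncertain) {
    findings$UNCERTAIN_MSG[unc] <- add_uncertain(findings$UNCERTAIN_MSG[unc],
                                                 "phase uncertain")
    out <- findings[keep | unc, , drop = FALSE]
  } else {
    out <- findings[keep, , drop = FALSE]
  }
  attr(out, "domain") <- dom
  rownames(out) <- NULL
  out
}
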