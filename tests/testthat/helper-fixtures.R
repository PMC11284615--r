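# Shared fixtures, built once per test run and cached in a session-level
# environment (everything is generated programmatically; nothing is stored).

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# Default three-study root: SEND-001 (2016, PARALLEL), SEND-002 (2018,
# PARALLEL, no SE), SEND-003 (2021, CROSSOVER, no TCNTRL).
fx_multi_root <- function() {
  fx_cached("multi_root", function() {
    root <- file.path(tempdir(), "sendhc-fx-multi")
    unlink(root, recursive = TRUE)
    studies <- make_multi_study_root(root, seed = 101L)
    list(root = root, studies = studies)
  })
}

# A populated database over the multi-study root (read-only for tests; tests
# that mutate must build their own copy with fx_fresh_db()).
fx_multi_db_path <- function() {
  fx_cached("multi_db", function() {
    fx <- fx_multi_root()
    dbp <- file.path(tempdir(), "sendhc-fx-multi.db")
    unlink(dbp)
    db <- init_environment(dbp, create = TRUE)
    on.exit(disconnect_db(db))
    create_schema(db)
    import_studies(db, fx$root)
    create_indexes(db)
    dbp
  })
}

fx_open_multi_db <- function() init_environment(fx_multi_db_path())

# Fresh disposable database populated from `root` (or empty when NULL).
fx_fresh_db <- function(root = NULL) {
  dbp <- tempfile(fileext = ".db")
  db <- init_environment(dbp, create = TRUE)
  create_schema(db)
  if (!is.null(root)) import_studies(db, root)
  db
}

# One default single study, cached.
fx_single_study <- function() {
  fx_cached("single_study", function() {
    out <- file.path(tempdir(), "sendhc-fx-single")
    unlink(out, recursive = TRUE)
    make_study(study_spec(seed = 7L, studyid = "SINGLE-01"), out)
  })
}

# The 873-animal harmonization cohort plus its cleaned copy and databases.
fx_usecase2 <- function() {
  fx_cached("usecase2", function() {
    root <- file.path(tempdir(), "sendhc-fx-uc2")
    unlink(root, recursive = TRUE)
    uc <- make_usecase2_fixture(root, seed = 1L)
    ct <- file.path(tempdir(), "sendhc-fx-ct.tsv")
    make_ct_fixture(ct)
    vocab <- gen_vocab(ct)
    cleaned <- file.path(tempdir(), "sendhc-fx-uc2-clean")
    unlink(cleaned, recursive = TRUE)
    for (sf in list.dirs(root, recursive = FALSE)) {
      standardize_file(sf, file.path(cleaned, basename(sf)), vocab)
    }
    build_db <- function(src, name) {
      dbp <- file.path(tempdir(), name)
      unlink(dbp)
      db <- init_environment(dbp, create = TRUE)
      on.exit(disconnect_db(db))
      create_schema(db)
      import_studies(db, src)
      dbp
    }
    list(root = root, cleaned = cleaned, ct = ct, vocab = vocab,
         truth = uc$truth,
         db_raw = build_db(root, "sendhc-fx-uc2-raw.db"),
         db_clean = build_db(cleaned, "sendhc-fx-uc2-clean.db"))
  })
}

# Incidence over controls on a database path, via the full filter chain.
fx_incidence <- function(db_path, vocab = NULL) {
  db <- init_environment(db_path)
  on.exit(disconnect_db(db))
  studies <- get_studies_sdesign(db)
  subj <- get_control_subj(db, studies, vocab = vocab)
  mi <- get_subj_data(db, subj, "MI")
  incidence_table(mi, subj, vocab = vocab)
}

# A small random domain table for round-trip property tests.
fx_random_table <- function(seed) {
  set.seed(seed)
  n <- sample(1:12, 1)
  k <- sample(2:6, 1)
  nm <- c("STUDYID", paste0("V", seq_len(k - 1)))
  cols <- list(rep("S1", n))
  for (j in seq_len(k - 1)) {
    cols[[j + 1]] <- if (runif(1) < 0.5) {
      v <- round(stats::rnorm(n, 100, 50), 4)
      v[runif(n) < 0.2] <- NA
      v
    } else {
      v <- replicate(n, paste(sample(c(LETTERS, " ", ","), sample(1:12, 1),
                                     replace = TRUE), collapse = ""))
      v <- sub(" +$", "", v)
      v[runif(n) < 0.2 | v == ""] <- NA
      v
    }
  }
  labs <- stats::setNames(paste("Label", nm), nm)
  domain_table("XX", stats::setNames(as.data.frame(cols,
                                                   stringsAsFactors = FALSE), nm),
               labels = labs)
}

# Independent calendar-arithmetic oracle for age derivation, written as a
# literal transcription of the resolution rules (scalar, if-chains).
oracle_age_days <- function(brthdtc, rfstdtc, age, ageu, dtc, dy) {
  to_date <- function(x) {
    if (is.na(x)) return(NA)
    tryCatch(as.Date(substr(x, 1, 10)), error = function(e) NA)
  }
  b <- to_date(brthdtc); r <- to_date(rfstdtc); d <- to_date(dtc)
  off <- if (!is.na(dy)) {
    if (dy >= 1) dy - 1 else dy
  } else if (!is.na(d) && !is.na(r)) {
    as.numeric(d - r)
  } else 0
  res <- if (!is.na(d) && !is.na(b)) {
    as.numeric(d - b)
  } else if (!is.na(b) && !is.na(r)) {
    as.numeric(r - b) + off
  } else if (!is.na(age) && !is.na(ageu)) {
    u <- c(DAYS = 1, WEEKS = 7, MONTHS = 30.4375, YEARS = 365.25)[toupper(ageu)]
    if (is.na(u)) return(NA_integer_)
    round(age * u) + off
  } else {
    return(NA_integer_)
  }
  res <- round(res)
  if (is.na(res) || res < 0) NA_integer_ else as.integer(res)
}

# Brute-force incidence oracle: loops over records, no grouping machinery.
oracle_incidence <- function(mi) {
  stat <- if ("MISTAT" %in% names(mi)) toupper(trimws(mi$MISTAT)) else
    rep(NA_character_, nrow(mi))
  ex <- is.na(stat) | stat != "NOT DONE"
  mi <- mi[ex, , drop = FALSE]
  out <- list()
  for (sp in sort(unique(toupper(trimws(mi$MISPEC))))) {
    rows <- mi[toupper(trimws(mi$MISPEC)) == sp, , drop = FALSE]
    n_exam <- length(unique(paste(rows$STUDYID, rows$USUBJID)))
    finds <- toupper(trimws(rows$MISTRESC))
    for (fd in sort(unique(finds[!is.na(finds) & finds != ""]))) {
      subj <- unique(paste(rows$STUDYID, rows$USUBJID)[!is.na(finds) & finds == fd])
      out[[length(out) + 1]] <- data.frame(
        SPECIMEN = sp, FINDING = fd, N_AFFECTED = length(subj),
        N_EXAMINED = n_exam,
        INCIDENCE_PCT = floor(100 * length(subj) / n_exam * 100 + 0.5) / 100,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

mk_mi <- function(df) {
  df$AGEDAYS <- rep(NA_integer_, nrow(df))
  df$PHASE <- rep(NA_character_, nrow(df))
  attr(df, "domain") <- "MI"
  df
}
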