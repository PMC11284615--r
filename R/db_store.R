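MANIFEST_VERSION <- "SEND-IG-3.1/sendhc-1"

#' The packaged SEND domain manifest
#'
#' One row per (domain, variable): the variable superset used by
#' [create_schema()] to lay out one SQLite table per SEND domain.
#'
#' @return data frame with columns `domain`, `variable`, `kind`, `label`.
#' @export
send_domain_manifest <- function() {
  path <- system.file("extdata", "send_domains.tsv", package = "sendhc",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

db_table_for_domain <- function(domain) {
  if (grepl("^SUPP", toupper(domain))) "SUPPQUAL" else toupper(domain)
}

#' Connect to (or create) a SEND SQLite database
#'
#' @param db_path path to the SQLite file.
#' @param create create the file if it does not exist.
#' @param log_path optional plain-text log; import/delete events are appended
#'   with timestamps.
#' @return A `send_db` handle.
#' @export
init_environment <- function(db_path, create = FALSE, log_path = NULL) {
  created_new <- FALSE
  if (!file.exists(db_path)) {
    if (!create) stop("database not found (create = FALSE): ", db_path)
    created_new <- TRUE
  }
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), db_path),
                  error = function(e) stop("cannot open database ", db_path, ": ",
                                           conditionMessage(e)))
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$db_path <- db_path
  h$created_new <- created_new
  h$open <- TRUE
  h$log_path <- log_path
  class(h) <- "send_db"
  h
}

db_check_open <- function(db) {
  if (!inherits(db, "send_db")) stop("not a send_db handle")
  if (!isTRUE(db$open)) stop("database handle is closed")
  invisible(db)
}

db_log <- function(db, msg) {
  if (!is.null(db$log_path)) {
    cat(sprintf("%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), msg),
        file = db$log_path, append = TRUE)
  }
  invisible(NULL)
}

#' @export
print.send_db <- function(x, ...) {
  cat(sprintf("<send_db %s (%s)>\n", x$db_path,
              if (isTRUE(x$open)) "open" else "closed"))
  invisible(x)
}

#' Disconnect from a SEND database
#'
#' The handle becomes unusable; a second disconnect is a no-op.
#' @param db a `send_db` handle.
#' @export
disconnect_db <- function(db) {
  if (!inherits(db, "send_db")) stop("not a send_db handle")
  if (isTRUE(db$open)) {
    DBI::dbDisconnect(db$con)
    db$open <- FALSE
  }
  invisible(NULL)
}

sql_type_for <- function(kind) ifelse(kind == "numeric", "REAL", "TEXT")

#' Create the SEND schema
#'
#' Creates one table per domain in the packaged SEND domain manifest plus a
#' `sendhc_meta` metadata table recording the manifest version. Fails if the
#' schema is already present (no partial rebuild).
#'
#' @param db a `send_db` handle.
#' @return Number of domain tables created.
#' @export
create_schema <- function(db) {
  db_check_open(db)
  man <- send_domain_manifest()
  existing <- DBI::dbListTables(db$con)
  if (any(unique(man$domain) %in% existing) || "sendhc_meta" %in% existing) {
    stop("SEND schema already initialized in ", db$db_path)
  }
  n <- 0L
  for (dom in unique(man$domain)) {
    vars <- man[man$domain == dom, ]
    cols <- paste(sprintf('"%s" %s', vars$variable, sql_type_for(vars$kind)),
                  collapse = ", ")
    DBI::dbExecute(db$con, sprintf('CREATE TABLE "%s" (%s)', dom, cols))
    n <- n + 1L
  }
  DBI::dbExecute(db$con, "CREATE TABLE sendhc_meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(db$con,
                 "INSERT INTO sendhc_meta (key, value) VALUES ('manifest_version', ?)",
                 params = list(MANIFEST_VERSION))
  db_log(db, sprintf("schema created: %d tables (%s)", n, MANIFEST_VERSION))
  n
}

db_has_schema <- function(db) {
  "sendhc_meta" %in% DBI::dbListTables(db$con)
}

db_studyids <- function(db) {
  ids <- character(0)
  for (t in intersect(c("DM", "TS"), DBI::dbListTables(db$con))) {
    ids <- union(ids, DBI::dbGetQuery(db$con, sprintf(
      'SELECT DISTINCT STUDYID FROM "%s" WHERE STUDYID IS NOT NULL', t))$STUDYID)
  }
  sort(ids)
}

# Align a domain_table's data to the SQLite table, adding unknown variables
# as new nullable columns (verbatim-load: nothing is dropped or transformed).
db_align_columns <- function(db, tbl_name, table) {
  existing <- DBI::dbListTables(db$con)
  if (!tbl_name %in% existing) {
    cols <- paste(sprintf('"%s" %s', table$variables$name,
                          sql_type_for(table$variables$kind)), collapse = ", ")
    DBI::dbExecute(db$con, sprintf('CREATE TABLE "%s" (%s)', tbl_name, cols))
  } else {
    have <- DBI::dbListFields(db$con, tbl_name)
    missing <- setdiff(table$variables$name, have)
    for (v in missing) {
      kind <- table$variables$kind[table$variables$name == v]
      DBI::dbExecute(db$con, sprintf('ALTER TABLE "%s" ADD COLUMN "%s" %s',
                                     tbl_name, v, sql_type_for(kind)))
    }
  }
  invisible(NULL)
}

#' Import one SEND study into the database
#'
#' Every record of every readable domain is inserted verbatim: no value
#' transformation, variables absent from the manifest are added as new
#' nullable columns, variables absent from the file are NULL. The whole
#' study is one transaction: any failure rolls back the study.
#'
#' @param db a `send_db` handle with schema.
#' @param folder study folder of XPT files.
#' @param replace replace an already-imported study with the same STUDYID.
#' @return The imported STUDYID, invisibly.
#' @export
import_one_study <- function(db, folder, replace = FALSE) {
  db_check_open(db)
  if (!db_has_schema(db)) stop("no SEND schema in database; run create_schema() first")
  bundle <- read_study_folder(folder)
  sid <- bundle$studyid
  already <- sid %in% db_studyids(db)
  if (already && !replace) {
    stop("study '", sid, "' already in database (replace = FALSE)")
  }
  DBI::dbWithTransaction(db$con, {
    if (already) delete_studies(db, sid)
    for (code in names(bundle$domains)) {
      tb <- bundle$domains[[code]]
      tbl_name <- db_table_for_domain(code)
      db_align_columns(db, tbl_name, tb)
      if (nrow(tb$data) == 0L) next
      cols <- DBI::dbListFields(db$con, tbl_name)
      out <- tb$data
      for (v in setdiff(cols, names(out))) out[[v]] <- NA
      out <- out[, cols, drop = FALSE]
      DBI::dbAppendTable(db$con, tbl_name, out)
    }
  })
  db_log(db, sprintf("imported study %s from %s (%d domains)", sid, folder,
                     length(bundle$domains)))
  invisible(sid)
}

#' Import every study under a root folder
#'
#' Every subdirectory (recursively, including the root itself) containing at
#' least one XPT file is attempted as one study; failures do not abort the
#' batch.
#'
#' @inheritParams import_one_study
#' @param root directory containing study folders.
#' @return An `import_report` data frame: `studyid`, `folder`, `status`
#'   (`ok`/`skipped`/`failed`), `message`, `n_rows` (total rows inserted).
#' @export
import_studies <- function(db, root, replace = FALSE) {
  db_check_open(db)
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- c(root, list.dirs(root, recursive = TRUE, full.names = TRUE))
  dirs <- unique(normalizePath(dirs))
  has_xpt <- vapply(dirs, function(d) {
    length(list.files(d, pattern = "\\.xpt$", ignore.case = TRUE)) > 0L
  }, logical(1))
  dirs <- dirs[has_xpt]
  rows <- lapply(dirs, function(d) {
    res <- tryCatch({
      pre <- db_total_rows(db)
      sid <- import_one_study(db, d, replace = replace)
      data.frame(studyid = sid, folder = d, status = "ok", message = "",
                 n_rows = db_total_rows(db) - pre, stringsAsFactors = FALSE)
    }, error = function(e) {
      msg <- conditionMessage(e)
      status <- if (grepl("already in database", msg)) "skipped" else "failed"
      data.frame(studyid = NA_character_, folder = d, status = status,
                 message = msg, n_rows = 0L, stringsAsFactors = FALSE)
    })
    res
  })
  report <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(studyid = character(0), folder = character(0),
               status = character(0), message = character(0),
               n_rows = integer(0), stringsAsFactors = FALSE)
  }
  class(report) <- c("import_report", class(report))
  db_log(db, sprintf("batch import from %s: %d ok, %d skipped, %d failed",
                     root, sum(report$status == "ok"),
                     sum(report$status == "skipped"),
                     sum(report$status == "failed")))
  report
}

db_total_rows <- function(db) {
  tabs <- setdiff(DBI::dbListTables(db$con), "sendhc_meta")
  sum(vapply(tabs, function(t) {
    DBI::dbGetQuery(db$con, sprintf('SELECT COUNT(*) AS n FROM "%s"', t))$n
  }, numeric(1)))
}

SUBJECT_LEVEL_DOMAINS <- c("DM", "EX", "DS", "SE", "BW", "LB", "MI", "SUPPQUAL")

#' Index the database
#'
#' Creates an index on STUDYID for every domain table and on
#' (STUDYID, USUBJID) for subject-level domains. Re-running is a no-op.
#'
#' @param db a `send_db` handle.
#' @return Number of indexes newly created.
#' @export
create_indexes <- function(db) {
  db_check_open(db)
  tabs <- setdiff(DBI::dbListTables(db$con), "sendhc_meta")
  pre <- DBI::dbGetQuery(db$con,
    "SELECT name FROM sqlite_master WHERE type = 'index'")$name
  n <- 0L
  for (t in tabs) {
    fields <- DBI::dbListFields(db$con, t)
    if (!"STUDYID" %in% fields) next
    idx <- sprintf("idx_%s_studyid", tolower(t))
    if (!idx %in% pre) {
      DBI::dbExecute(db$con, sprintf('CREATE INDEX "%s" ON "%s" (STUDYID)', idx, t))
      n <- n + 1L
    }
    if (t %in% SUBJECT_LEVEL_DOMAINS && "USUBJID" %in% fields) {
      idx2 <- sprintf("idx_%s_subj", tolower(t))
      if (!idx2 %in% pre) {
        DBI::dbExecute(db$con,
          sprintf('CREATE INDEX "%s" ON "%s" (STUDYID, USUBJID)', idx2, t))
        n <- n + 1L
      }
    }
  }
  n
}

#' Delete studies from the database
#'
#' @param db a `send_db` handle.
#' @param studyids character vector of STUDYID values.
#' @return Named numeric vector: rows deleted per study (0 for unknown ids).
#' @export
delete_studies <- function(db, studyids) {
  db_check_open(db)
  tabs <- setdiff(DBI::dbListTables(db$con), "sendhc_meta")
  counts <- stats::setNames(numeric(length(studyids)), studyids)
  for (sid in studyids) {
    for (t in tabs) {
      if (!"STUDYID" %in% DBI::dbListFields(db$con, t)) next
      counts[sid] <- counts[sid] + DBI::dbExecute(db$con,
        sprintf('DELETE FROM "%s" WHERE STUDYID = ?', t), params = list(sid))
    }
    db_log(db, sprintf("deleted study %s (%d rows)", sid, counts[sid]))
  }
  counts
}
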