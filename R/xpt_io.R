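# -- SAS XPT v5 header constants ---------------------------------------------

XPT_LIB_HEADER <- "HEADER RECORD*******LIBRARY HEADER RECORD!!!!!!!"
XPT_V8_MARKER <- "HEADER RECORD*******LIBV8"
XPT_MEMBER_HEADER <- "HEADER RECORD*******MEMBER  HEADER RECORD"

#' Construct a SEND domain table
#'
#' A `domain_table` is the in-memory form of one SEND domain: a plain
#' data frame of records plus per-variable metadata (label, kind, declared
#' length) mirroring what an XPT v5 member stores.
#'
#' @param domain 2--8 character domain code, e.g. `"DM"`, `"MI"`, `"SUPPMI"`.
#' @param data data frame of records; column names become variable names.
#' @param labels named character vector of variable labels (<= 40 chars);
#'   unnamed variables get their own name as label.
#' @param source_path optional path the table was read from.
#' @return An object of class `domain_table` with elements `domain`,
#'   `variables` (data frame: `name`, `label`, `kind`, `length`), `data`,
#'   and `source_path`.
#' @export
domain_table <- function(domain, data, labels = NULL, source_path = NA_character_) {
  stopifnot(is.character(domain), length(domain) == 1L, nzchar(domain))
  domain <- toupper(domain)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  nm <- names(data)
  bad <- nm[!grepl("^[A-Z][A-Z0-9_]{0,7}$", nm)]
  if (length(bad)) {
    stop("invalid XPT variable name(s): ", paste(bad, collapse = ", "),
         " (must match [A-Z][A-Z0-9_]*, <= 8 chars)")
  }
  if (anyDuplicated(nm)) stop("duplicate variable names in domain ", domain)
  lab <- vapply(nm, function(v) {
    l <- if (!is.null(labels) && v %in% names(labels)) labels[[v]] else v
    as.character(l)
  }, character(1))
  too_long <- nm[nchar(lab) > 40L]
  if (length(too_long)) {
    stop("variable label(s) exceed 40 characters: ", paste(too_long, collapse = ", "))
  }
  # SAS transport has no empty string: blank and missing coincide
  for (v in nm) {
    if (is.factor(data[[v]])) data[[v]] <- as.character(data[[v]])
    if (is.logical(data[[v]]) && all(is.na(data[[v]]))) data[[v]] <- as.character(data[[v]])
    if (is.character(data[[v]])) data[[v]][!is.na(data[[v]]) & data[[v]] == ""] <- NA_character_
  }
  kind <- ifelse(vapply(data, is.numeric, logical(1)), "numeric", "character")
  len <- vapply(seq_along(nm), function(i) {
    if (kind[i] == "numeric") return(8)
    x <- data[[i]]
    suppressWarnings(max(1, nchar(x[!is.na(x)], type = "bytes")))
  }, numeric(1))
  len[!is.finite(len)] <- 1
  len <- as.integer(len)
  if ("DOMAIN" %in% nm) {
    dv <- data[["DOMAIN"]]
    if (any(!is.na(dv) & toupper(dv) != domain)) {
      stop("DOMAIN variable values disagree with domain code ", domain)
    }
  }
  structure(
    list(domain = domain,
         variables = data.frame(name = nm, label = unname(lab), kind = kind,
                                length = len, stringsAsFactors = FALSE),
         data = data,
         source_path = source_path),
    class = "domain_table")
}

#' @export
print.domain_table <- function(x, ...) {
  cat(sprintf("<domain_table %s: %d records, %d variables>\n",
              x$domain, nrow(x$data), nrow(x$variables)))
  invisible(x)
}

#' @export
format.domain_table <- function(x, ...) {
  sprintf("<domain_table %s: %d x %d>", x$domain, nrow(x$data), nrow(x$variables))
}

xpt_header_check <- function(path) {
  hdr <- readBin(path, "raw", n = 80L)
  if (length(hdr) < 80L) {
    stop("malformed XPT header in '", path, "': file shorter than one 80-byte record (byte offset ",
         length(hdr), ")")
  }
  txt <- rawToChar(hdr)
  if (startsWith(txt, XPT_V8_MARKER)) {
    stop("unsupported XPT version in '", path,
         "': v8/v9 transport detected; only XPT v5 is supported")
  }
  expect <- XPT_LIB_HEADER
  got <- substr(txt, 1L, nchar(expect))
  if (got != expect) {
    diff <- which(utf8ToInt(got) != utf8ToInt(substr(expect, 1, nchar(got))))[1]
    if (is.na(diff)) diff <- 1L
    stop("malformed XPT header in '", path, "': library header mismatch at byte offset ",
         diff - 1L)
  }
  invisible(TRUE)
}

xpt_raw_text <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  raw[raw > as.raw(127) | raw == as.raw(0)] <- as.raw(32L)
  rawToChar(raw)
}

xpt_count_members <- function(path) {
  hits <- gregexpr(XPT_MEMBER_HEADER, xpt_raw_text(path), fixed = TRUE,
                   useBytes = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Read a SAS XPT v5 transport file as a domain table
#'
#' Records are returned in file order; numeric missing values become `NA`,
#' character values are right-trimmed of padding spaces (SAS transport cannot
#' distinguish a blank from a missing character value, so blank becomes `NA`).
#' Variable labels are preserved.
#'
#' @param path path to an `.xpt` file.
#' @param domain optional domain code override; defaults to the `DOMAIN`
#'   variable value when present, else the uppercased filename stem.
#' @return A [domain_table].
#' @export
read_xpt <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  xpt_header_check(path)
  if (xpt_count_members(path) == 0L) {
    stop("empty XPT library in '", path, "': zero datasets")
  }
  df <- haven::read_xpt(path)
  labels <- vapply(df, function(col) {
    l <- attr(col, "label", exact = TRUE)
    if (is.null(l)) NA_character_ else as.character(l)
  }, character(1))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (v in names(df)) {
    attributes(df[[v]]) <- NULL
    if (is.character(df[[v]])) {
      df[[v]] <- sub(" +$", "", df[[v]])
      if (any(grepl("[^\x01-\x7F]", df[[v]][!is.na(df[[v]])]))) {
        warning("non-ASCII bytes in variable ", v, " of ", path,
                " passed through unmodified")
      }
    }
  }
  labels <- labels[!is.na(labels)]
  dom <- domain
  if (is.null(dom)) {
    dom <- if ("DOMAIN" %in% names(df) && nrow(df) > 0 && !is.na(df$DOMAIN[1])) {
      toupper(df$DOMAIN[1])
    } else {
      toupper(tools::file_path_sans_ext(basename(path)))
    }
  }
  domain_table(dom, df, labels = labels, source_path = normalizePath(path))
}

# Pin the library/member creation and modification datetimes that SAS stamps
# into fixed header offsets, so identical inputs give byte-identical files.
pin_xpt_timestamps <- function(path, stamp = "01JAN20:00:00:00") {
  raw <- readBin(path, "raw", n = file.size(path))
  stopifnot(nchar(stamp) == 16L)
  sraw <- charToRaw(stamp)
  is_dt <- function(off) {  # 0-based offset of a 16-byte field
    txt <- tryCatch(rawToChar(raw[(off + 1):(off + 16)]), error = function(e) "")
    grepl("^[0-9]{2}[A-Z]{3}[0-9]{2}:[0-9]{2}:[0-9]{2}:[0-9]{2}$", txt)
  }
  put <- function(off) {
    if (is_dt(off)) raw[(off + 1):(off + 16)] <<- sraw
  }
  put(144L); put(160L)                        # library created / modified
  safe <- raw
  safe[safe > as.raw(127) | safe == as.raw(0)] <- as.raw(32L)
  txt <- rawToChar(safe)
  hits <- gregexpr(XPT_MEMBER_HEADER, txt, fixed = TRUE, useBytes = TRUE)[[1]]
  for (m in hits[hits > 0]) {
    put(m - 1L + 224L)  # member created
    put(m - 1L + 240L)  # member modified
  }
  writeBin(raw, path)
  invisible(path)
}

#' Write a domain table as a SAS XPT v5 transport file
#'
#' Validates variable names (<= 8 chars) and labels (<= 40 chars) before any
#' bytes are written. Declared character lengths are derived from the data
#' (auto-widened to the longest value, capped at 200 bytes). The emitted file
#' round-trips through [read_xpt()] exactly (records, variable order, labels,
#' kinds). Header timestamps are pinned so output is deterministic.
#'
#' @param table a [domain_table] (or a data frame, coerced with `domain`).
#' @param path output path.
#' @param domain domain code when `table` is a plain data frame.
#' @return `path`, invisibly.
#' @export
write_xpt <- function(table, path, domain = NULL) {
  if (!inherits(table, "domain_table")) {
    if (is.null(domain)) stop("domain code required when writing a plain data frame")
    table <- domain_table(domain, table)
  }
  nm <- table$variables$name
  bad_name <- nm[nchar(nm) > 8L]
  if (length(bad_name)) stop("variable name(s) exceed 8 characters: ",
                             paste(bad_name, collapse = ", "))
  bad_lab <- nm[nchar(table$variables$label) > 40L]
  if (length(bad_lab)) stop("variable label(s) exceed 40 characters: ",
                            paste(bad_lab, collapse = ", "))
  df <- table$data
  for (i in seq_along(nm)) {
    v <- nm[i]
    if (is.character(df[[v]])) {
      over <- !is.na(df[[v]]) & nchar(df[[v]], type = "bytes") > 200L
      if (any(over)) {
        warning("character values in ", v, " truncated to the 200-byte XPT cap")
        df[[v]][over] <- substr(df[[v]][over], 1L, 200L)
      }
      if (any(grepl("[^\x01-\x7F]", df[[v]][!is.na(df[[v]])]))) {
        warning("non-ASCII bytes in variable ", v, " passed through unmodified")
      }
    }
    attr(df[[v]], "label") <- table$variables$label[i]
  }
  dsname <- table$domain
  haven::write_xpt(df, path, version = 5, name = dsname)
  pin_xpt_timestamps(path)
  invisible(path)
}

#' Read a folder of XPT files as one SEND study bundle
#'
#' Every `*.xpt` file (case-insensitive extension) becomes one domain table,
#' keyed by its domain code: the `DOMAIN` variable value when present, else
#' the uppercased filename stem. Split datasets sharing a domain code (e.g.
#' `lb1.xpt`/`lb2.xpt`) are concatenated. The study identifier is resolved
#' from DM, else TS, and must be consistent across all domains.
#'
#' @param folder directory containing a single study's XPT files.
#' @return A `study_bundle`: list with `studyid`, `folder`, and `domains`
#'   (named list of [domain_table]s).
#' @export
read_study_folder <- function(folder) {
  if (!dir.exists(folder)) stop("no such directory: ", folder)
  files <- list.files(folder, pattern = "\\.xpt$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files))]
  if (!length(files)) stop("empty study: no XPT files in ", folder)
  domains <- list()
  for (f in files) {
    tb <- read_xpt(f)
    code <- tb$domain
    if (!is.null(domains[[code]])) {
      merged <- rbind(domains[[code]]$data, tb$data)
      lb <- stats::setNames(domains[[code]]$variables$label, domains[[code]]$variables$name)
      domains[[code]] <- domain_table(code, merged, labels = lb,
                                      source_path = domains[[code]]$source_path)
    } else {
      domains[[code]] <- tb
    }
  }
  ids <- lapply(names(domains), function(code) {
    d <- domains[[code]]$data
    if ("STUDYID" %in% names(d)) unique(d$STUDYID[!is.na(d$STUDYID)]) else character(0)
  })
  names(ids) <- names(domains)
  multi <- names(ids)[vapply(ids, length, integer(1)) > 1L]
  if (length(multi)) {
    stop("inconsistent STUDYID within domain(s): ", paste(multi, collapse = ", "))
  }
  flat <- unlist(ids)
  if (length(unique(flat)) > 1L) {
    off <- names(ids)[vapply(ids, function(x) length(x) == 1L, logical(1))]
    stop("conflicting STUDYID values across domains [",
         paste(unique(flat), collapse = " vs "), "] in: ",
         paste(off, collapse = ", "))
  }
  studyid <- NA_character_
  if (!is.null(domains$DM) && "STUDYID" %in% names(domains$DM$data)) {
    v <- domains$DM$data$STUDYID
    studyid <- v[!is.na(v)][1]
  }
  if (is.na(studyid) && !is.null(domains$TS) && "STUDYID" %in% names(domains$TS$data)) {
    v <- domains$TS$data$STUDYID
    studyid <- v[!is.na(v)][1]
  }
  if (is.na(studyid) && length(flat)) studyid <- flat[[1]]
  if (is.na(studyid)) stop("cannot resolve STUDYID from DM or TS in ", folder)
  structure(list(studyid = studyid,
                 folder = normalizePath(folder),
                 domains = domains),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle %s: %d domains [%s]>\n", x$studyid,
              length(x$domains), paste(names(x$domains), collapse = ", ")))
  invisible(x)
}
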