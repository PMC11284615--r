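SUPPORTED_CODELISTS <- c(
  "sex", "strain/substrain", "species", "send severity",
  "route of administration response", "standardized disposition term",
  "specimen", "anatomical location", "non-neoplastic finding type",
  "send control type")

codelist_key <- function(name) {
  k <- tolower(trimws(name))
  k <- sub("\\s*\\(.*\\)$", "", k)
  k
}

# Tolerant tab-delimited CT reader: accepts both the minimal column contract
# (codelist name / submission value / synonyms / extensible) and the headers
# of the published CDISC CT export ("Codelist Name", "CDISC Submission
# Value", "CDISC Synonym(s)", "Codelist Extensible (Yes/No)").
read_ct_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = character(0))
  find_col <- function(patterns, required = TRUE) {
    nm <- tolower(names(df))
    for (p in patterns) {
      i <- which(grepl(p, nm))
      if (length(i)) return(names(df)[i[1]])
    }
    if (required) stop("CT file ", path, " lacks a column matching: ",
                       paste(patterns, collapse = " | "))
    NULL
  }
  cl <- find_col(c("codelist name", "^codelist$", "code list"))
  sv <- find_col(c("submission value", "^preferred", "preferred term"))
  sy <- find_col(c("synonym"))
  ex <- find_col(c("extensible"), required = FALSE)
  data.frame(
    codelist = df[[cl]],
    submission_value = df[[sv]],
    synonyms = df[[sy]],
    extensible = if (is.null(ex)) "" else df[[ex]],
    stringsAsFactors = FALSE)
}

#' Build a terminology vocabulary from tab-delimited CT files
#'
#' Each input file maps controlled-terminology synonyms to preferred
#' submission values. Synonyms (semicolon-separated) and submission values
#' are uppercased and trimmed; every preferred value also maps to itself.
#' `extra_files` (user extensible-term mappings, same format) are merged
#' after the CT files and override on conflict with a warning; a synonym
#' mapped to two different preferred values within the same layer is a hard
#' error. Rows for codelists outside the ten supported lists are skipped
#' with a warning. The vocabulary is written as JSON when `json_out` is
#' given.
#'
#' @param ct_files character vector of tab-delimited CT file paths.
#' @param extra_files optional extensible-term files, same format.
#' @param json_out optional path for the JSON vocabulary.
#' @return A `send_vocab`: list with `codelists` (codelist-key -> named
#'   character vector synonym -> preferred), `extensible`, `provenance`.
#' @export
gen_vocab <- function(ct_files, extra_files = character(0), json_out = NULL) {
  build_layer <- function(files, label) {
    maps <- stats::setNames(vector("list", length(SUPPORTED_CODELISTS)),
                            SUPPORTED_CODELISTS)
    ext <- stats::setNames(rep(NA, length(SUPPORTED_CODELISTS)),
                           SUPPORTED_CODELISTS)
    for (f in files) {
      ct <- read_ct_file(f)
      keys <- codelist_key(ct$codelist)
      unknown <- unique(ct$codelist[!keys %in% SUPPORTED_CODELISTS])
      if (length(unknown)) {
        warning("skipping unsupported codelist(s) in ", basename(f), ": ",
                paste(unknown, collapse = ", "))
      }
      ct <- ct[keys %in% SUPPORTED_CODELISTS, , drop = FALSE]
      keys <- keys[keys %in% SUPPORTED_CODELISTS]
      for (i in seq_len(nrow(ct))) {
        k <- keys[i]
        pref <- norm_term(ct$submission_value[i])
        if (!nzchar(pref)) next
        syns <- unlist(strsplit(ct$synonyms[i], ";", fixed = TRUE))
        syns <- norm_term(syns)
        syns <- syns[nzchar(syns)]
        entries <- stats::setNames(rep(pref, length(syns) + 1L), c(pref, syns))
        cur <- maps[[k]]
        clash <- intersect(names(entries), names(cur))
        bad <- clash[cur[clash] != entries[clash]]
        if (length(bad)) {
          stop("conflicting synonym mapping(s) in ", label, " codelist '", k,
               "': ", paste(sprintf("%s -> {%s, %s}", bad, cur[bad],
                                    entries[bad]), collapse = "; "))
        }
        maps[[k]] <- c(cur[setdiff(names(cur), names(entries))], entries)
        flag <- norm_term(ct$extensible[i])
        if (nzchar(flag)) ext[[k]] <- flag %in% c("YES", "Y", "TRUE", "1")
      }
    }
    list(maps = maps, ext = ext)
  }
  base <- build_layer(ct_files, "CT")
  vocab <- base$maps
  ext <- base$ext
  if (length(extra_files)) {
    extra <- build_layer(extra_files, "extra")
    for (k in SUPPORTED_CODELISTS) {
      add <- extra$maps[[k]]
      if (is.null(add)) next
      cur <- vocab[[k]]
      over <- intersect(names(add), names(cur))
      over <- over[cur[over] != add[over]]
      if (length(over)) {
        warning("extensible mapping(s) override CT in codelist '", k, "': ",
                paste(sprintf("%s -> %s (was %s)", over, add[over],
                              cur[over]), collapse = "; "))
      }
      vocab[[k]] <- c(cur[setdiff(names(cur), names(add))], add)
      if (!is.na(extra$ext[[k]])) ext[[k]] <- extra$ext[[k]]
    }
  }
  vocab <- vocab[!vapply(vocab, is.null, logical(1))]
  vocab <- lapply(vocab, function(m) m[order(names(m))])
  obj <- structure(
    list(codelists = vocab,
         extensible = as.list(ext[names(vocab)]),
         provenance = basename(c(ct_files, extra_files))),
    class = "send_vocab")
  if (!is.null(json_out)) write_vocab(obj, json_out)
  obj
}

#' @export
print.send_vocab <- function(x, ...) {
  cat(sprintf("<send_vocab: %d codelists, %d mappings>\n",
              length(x$codelists), sum(lengths(x$codelists))))
  invisible(x)
}

#' Write a vocabulary as JSON
#'
#' Top-level object keyed by codelist; values are flat synonym -> preferred
#' objects. A `_meta` object holds provenance and extensible flags. Keys are
#' ordered for diffability.
#'
#' @param vocab a `send_vocab`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  body <- lapply(vocab$codelists, as.list)
  body <- body[order(names(body))]
  body[["_meta"]] <- list(
    provenance = vocab$provenance,
    extensible = vocab$extensible[order(names(vocab$extensible))])
  jsonlite::write_json(body, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a JSON vocabulary
#'
#' @param path JSON file written by [write_vocab()] / [gen_vocab()].
#' @return A `send_vocab`.
#' @export
load_vocab <- function(path) {
  obj <- jsonlite::read_json(path)
  meta <- obj[["_meta"]]
  obj[["_meta"]] <- NULL
  codelists <- lapply(obj, function(m) unlist(m))
  structure(
    list(codelists = codelists,
         extensible = if (is.null(meta$extensible)) list() else meta$extensible,
         provenance = unlist(meta$provenance)),
    class = "send_vocab")
}

#' Map one value through a vocabulary codelist
#'
#' Lookup is on the uppercased, trimmed value; a miss returns the input
#' unchanged with `hit = FALSE`. Preferred values hit via their identity
#' rows.
#'
#' @param value character vector of values.
#' @param codelist_key one of the supported codelist keys.
#' @param vocab a `send_vocab`.
#' @return List with `value` (mapped) and `hit` (logical), both vectorized.
#' @export
apply_map <- function(value, codelist_key, vocab) {
  if (!codelist_key %in% SUPPORTED_CODELISTS) {
    stop("unknown codelist key: ", codelist_key)
  }
  cl <- vocab$codelists[[codelist_key]]
  v <- as.character(value)
  key <- norm_term(v)
  hit <- !is.na(key) & nzchar(key) & key %in% names(cl)
  out <- v
  out[hit] <- unname(cl[key[hit]])
  list(value = out, hit = hit)
}

#' Default variable-to-codelist bindings
#'
#' Which SEND variables are harmonized against which codelist. For TX and TS
#' the binding is conditional: only parameter-value rows whose `--PARMCD`
#' equals `param` are mapped.
#'
#' @return Data frame with columns `domain`, `variable`, `param`, `codelist`.
#' @export
default_bindings <- function() {
  b <- rbind(
    c("DM", "SEX", NA, "sex"),
    c("DM", "STRAIN", NA, "strain/substrain"),
    c("DM", "SPECIES", NA, "species"),
    c("MI", "MISPEC", NA, "specimen"),
    c("MI", "MIANTREG", NA, "anatomical location"),
    c("MI", "MISTRESC", NA, "non-neoplastic finding type"),
    c("MI", "MISEV", NA, "send severity"),
    c("EX", "EXROUTE", NA, "route of administration response"),
    c("DS", "DSDECOD", NA, "standardized disposition term"),
    c("TX", "TXVAL", "TCNTRL", "send control type"),
    c("TS", "TSVAL", "SPECIES", "species"))
  stats::setNames(data.frame(b, stringsAsFactors = FALSE),
                  c("domain", "variable", "param", "codelist"))
}

#' Rewrite a folder of SEND XPT files with harmonized terminology
#'
#' Every XPT file in `in_dir` is rewritten to `out_dir` under the same
#' filename. For each bound variable, each value is uppercased and trimmed
#' for lookup: on a hit the value is replaced by the preferred term, on a
#' miss the original value is preserved verbatim and tallied as unmapped.
#' Unbound variables are untouched. Because preferred values map to
#' themselves, running the operation on its own output changes nothing.
#' A clean report CSV (`clean_report.csv`) is written beside the outputs.
#'
#' @param in_dir folder of XPT files to clean.
#' @param out_dir output folder (must differ from `in_dir`; created if
#'   needed).
#' @param vocab a `send_vocab` or the path to a JSON vocabulary.
#' @param bindings variable bindings, default [default_bindings()].
#' @return A `clean_report` data frame: `file`, `variable`, `original`,
#'   `mapped`, `n` (records changed), with attributes `totals` (changed
#'   records per file), `unmapped` (distinct unmapped values per codelist)
#'   and `failed` (files that could not be read).
#' @export
standardize_file <- function(in_dir, out_dir, vocab,
                             bindings = default_bindings()) {
  if (!dir.exists(in_dir)) stop("no such directory: ", in_dir)
  if (normalizePath(in_dir, mustWork = TRUE) ==
      suppressWarnings(normalizePath(out_dir, mustWork = FALSE))) {
    stop("out_dir must differ from in_dir (no in-place overwrite)")
  }
  if (is.character(vocab)) vocab <- load_vocab(vocab)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(in_dir, pattern = "\\.xpt$", ignore.case = TRUE,
                      full.names = TRUE)
  entries <- list()
  totals <- stats::setNames(integer(length(files)), basename(files))
  unmapped <- list()
  failed <- character(0)
  for (f in files) {
    tb <- tryCatch(read_xpt(f), error = function(e) e)
    if (inherits(tb, "error")) {
      warning("skipping unreadable XPT ", basename(f), ": ",
              conditionMessage(tb))
      failed <- c(failed, basename(f))
      next
    }
    bnd <- bindings[bindings$domain == tb$domain, , drop = FALSE]
    changed_rows <- rep(FALSE, nrow(tb$data))
    for (i in seq_len(nrow(bnd))) {
      v <- bnd$variable[i]
      if (!v %in% names(tb$data)) next
      scope <- rep(TRUE, nrow(tb$data))
      if (!is.na(bnd$param[i])) {
        pc <- paste0(tb$domain, "PARMCD")
        if (!pc %in% names(tb$data)) next
        scope <- !is.na(tb$data[[pc]]) & norm_term(tb$data[[pc]]) == bnd$param[i]
      }
      vals <- tb$data[[v]]
      idx <- which(scope & !is.na(vals))
      if (!length(idx)) next
      m <- apply_map(vals[idx], bnd$codelist[i], vocab)
      new <- ifelse(m$hit, m$value, vals[idx])
      diff <- new != vals[idx]
      if (any(diff)) {
        pairs <- data.frame(original = vals[idx][diff], mapped = new[diff],
                            stringsAsFactors = FALSE)
        agg <- stats::aggregate(cnt ~ original + mapped,
                                data = cbind(pairs, cnt = 1L), FUN = sum)
        agg <- data.frame(file = basename(f), variable = v, agg,
                          stringsAsFactors = FALSE)
        names(agg)[names(agg) == "cnt"] <- "n"
        entries[[length(entries) + 1L]] <- agg
        totals[basename(f)] <- totals[basename(f)] + sum(diff)
        tb$data[[v]][idx] <- new
        changed_rows[idx][diff] <- TRUE
      }
      misses <- unique(norm_term(vals[idx][!m$hit]))
      if (length(misses)) {
        unmapped[[bnd$codelist[i]]] <- union(unmapped[[bnd$codelist[i]]], misses)
      }
    }
    out_tb <- domain_table(tb$domain, tb$data,
                           labels = stats::setNames(tb$variables$label,
                                                    tb$variables$name))
    write_xpt(out_tb, file.path(out_dir, basename(f)))
  }
  report <- if (length(entries)) {
    do.call(rbind, entries)
  } else {
    data.frame(file = character(0), variable = character(0),
               original = character(0), mapped = character(0),
               n = integer(0), stringsAsFactors = FALSE)
  }
  rownames(report) <- NULL
  attr(report, "totals") <- totals
  attr(report, "unmapped") <- unmapped
  attr(report, "failed") <- failed
  class(report) <- c("clean_report", class(report))
  utils::write.csv(report, file.path(out_dir, "clean_report.csv"),
                   row.names = FALSE)
  report
}
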