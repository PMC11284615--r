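# Round half away from zero at `digits` decimals; R's round() is banker's
# rounding, which would print 2.745 -> 2.74 where the dashboard convention
# is 2.75.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Background incidence table for microscopic findings
#'
#' The denominator for a specimen is the number of distinct subjects with at
#' least one MI record for that specimen whose MISTAT is not "NOT DONE"
#' (i.e. animals in which the tissue was actually examined). The numerator
#' for a (specimen, finding) is the number of distinct subjects with at
#' least one matching record. Specimens and findings are uppercased and,
#' when a vocabulary is supplied, mapped through the specimen and
#' non-neoplastic finding type codelists first, so synonymous terms pool by
#' distinct subject.
#'
#' @param findings an MI findings table from [get_subj_data()].
#' @param subjects the subject set the findings came from (used only for
#'   validation; the denominator is examined animals per specimen).
#' @param group_by_severity additionally key rows by MISEV.
#' @param vocab optional `send_vocab` for term harmonization at query time.
#' @return Data frame with columns `SPECIMEN`, `FINDING`, (`SEVERITY`,)
#'   `N_AFFECTED`, `N_EXAMINED`, `INCIDENCE_PCT` (percent, half-up at 2
#'   decimals), sorted by specimen then descending incidence.
#' @export
incidence_table <- function(findings, subjects = NULL,
                            group_by_severity = FALSE, vocab = NULL) {
  dom <- findings_domain(findings, default = "MI")
  if (dom != "MI") stop("incidence_table expects MI findings, got ", dom)
  need <- c("STUDYID", "USUBJID", "MISPEC", "MISTRESC")
  miss <- setdiff(need, names(findings))
  if (length(miss)) stop("MI findings lack variable(s): ", paste(miss, collapse = ", "))
  f <- findings
  stat <- if ("MISTAT" %in% names(f)) norm_term(f$MISTAT) else rep(NA_character_, nrow(f))
  examined <- is.na(stat) | stat != "NOT DONE"
  f <- f[examined, , drop = FALSE]
  spec <- map_terms(f$MISPEC, "specimen", vocab)
  find <- map_terms(f$MISTRESC, "non-neoplastic finding type", vocab)
  subj <- paste(f$STUDYID, f$USUBJID, sep = "\r")
  ok_spec <- !is.na(spec) & nzchar(spec)
  denom <- tapply(subj[ok_spec], spec[ok_spec],
                  function(s) length(unique(s)))
  has_find <- ok_spec & !is.na(find) & nzchar(find)
  if (group_by_severity) {
    sev <- if ("MISEV" %in% names(f)) norm_term(f$MISEV) else rep(NA_character_, nrow(f))
    sev[is.na(sev)] <- ""
    keydf <- data.frame(SPECIMEN = spec[has_find], FINDING = find[has_find],
                        SEVERITY = sev[has_find], subj = subj[has_find],
                        stringsAsFactors = FALSE)
    grp <- c("SPECIMEN", "FINDING", "SEVERITY")
  } else {
    keydf <- data.frame(SPECIMEN = spec[has_find], FINDING = find[has_find],
                        subj = subj[has_find], stringsAsFactors = FALSE)
    grp <- c("SPECIMEN", "FINDING")
  }
  if (!nrow(keydf)) {
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = length(grp) + 3)),
                           c(grp, "N_AFFECTED", "N_EXAMINED", "INCIDENCE_PCT"))
    return(out)
  }
  agg <- stats::aggregate(subj ~ ., data = keydf,
                          FUN = function(s) length(unique(s)))
  names(agg)[names(agg) == "subj"] <- "N_AFFECTED"
  agg$N_EXAMINED <- as.integer(denom[agg$SPECIMEN])
  agg$N_AFFECTED <- as.integer(agg$N_AFFECTED)
  agg$INCIDENCE_PCT <- round_half_up(100 * agg$N_AFFECTED / agg$N_EXAMINED, 2L)
  agg <- agg[order(agg$SPECIMEN, -agg$INCIDENCE_PCT, agg$FINDING), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Reference ranges for quantitative domains (LB, BW)
#'
#' Groups numeric standardized results (`--STRESN`) by test code, specimen
#' and unit (and sex when requested; sex is joined from the subject set) and
#' reports n, arithmetic mean and sample standard deviation (n-1
#' denominator; `NA` for a single observation). Rows without a numeric
#' standardized result are excluded from computation and counted in the
#' `n_excluded` attribute. Mixed units within a test split into separate
#' rows, never pooled.
#'
#' @param findings an LB or BW findings table.
#' @param subjects the subject set (supplies SEX for `group_by_sex`).
#' @param group_by_sex additionally key rows by subject sex.
#' @return Data frame with columns `TESTCD`, `TEST`, `SPEC`, `UNITS`,
#'   `SEX`, `N`, `MEAN`, `SD`, with attribute `n_excluded`.
#' @export
reference_ranges <- function(findings, subjects = NULL, group_by_sex = FALSE) {
  dom <- findings_domain(findings)
  if (!dom %in% c("LB", "BW")) {
    stop("reference_ranges expects LB or BW findings, got ", dom)
  }
  col <- function(suffix) paste0(dom, suffix)
  val <- suppressWarnings(as.numeric(findings[[col("STRESN")]]))
  ok <- !is.na(val)
  n_excluded <- sum(!ok)
  g <- data.frame(
    TESTCD = norm_term(findings[[col("TESTCD")]]),
    TEST = if (col("TEST") %in% names(findings)) as.character(findings[[col("TEST")]]) else NA_character_,
    SPEC = if (dom == "LB" && "LBSPEC" %in% names(findings)) norm_term(findings$LBSPEC) else NA_character_,
    UNITS = if (col("STRESU") %in% names(findings)) norm_term(findings[[col("STRESU")]]) else NA_character_,
    stringsAsFactors = FALSE)
  if (group_by_sex) {
    if (is.null(subjects)) stop("group_by_sex = TRUE requires the subject set")
    si <- match(paste(findings$STUDYID, findings$USUBJID, sep = "\r"),
                paste(subjects$STUDYID, subjects$USUBJID, sep = "\r"))
    g$SEX <- map_terms(subjects$SEX[si], "sex", NULL)
  } else {
    g$SEX <- NA_character_
  }
  g <- g[ok, , drop = FALSE]
  val <- val[ok]
  if (!nrow(g)) {
    out <- data.frame(TESTCD = character(0), TEST = character(0),
                      SPEC = character(0), UNITS = character(0),
                      SEX = character(0), N = integer(0), MEAN = numeric(0),
                      SD = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  blank_na <- function(x) ifelse(is.na(x), "", x)
  key <- paste(blank_na(g$TESTCD), blank_na(g$TEST), blank_na(g$SPEC),
               blank_na(g$UNITS), blank_na(g$SEX), sep = "\r")
  idx <- split(seq_along(val), key)
  rows <- lapply(idx, function(ii) {
    r <- g[ii[1], , drop = FALSE]
    r$N <- length(ii)
    r$MEAN <- mean(val[ii])
    r$SD <- if (length(ii) > 1L) stats::sd(val[ii]) else NA_real_
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$TESTCD, out$SPEC, out$UNITS, out$SEX), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Export an aggregate or findings table as CSV
#'
#' RFC 4180 CSV with a header row; percentage columns are serialized with
#' two decimals, everything else at full precision.
#'
#' @param rows a data frame (e.g. from [incidence_table()]).
#' @param path output file path.
#' @param format only `"csv"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(rows, path, format = c("csv")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (v in names(rows)) {
    if (grepl("_PCT$", v) && is.numeric(rows[[v]])) {
      rows[[v]] <- sprintf("%.2f", rows[[v]])
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, na = "")
  invisible(path)
}
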