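write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("Codelist Name\tCDISC Submission Value\tCDISC Synonym(s)\tCodelist Extensible (Yes/No)",
               lines), path)
  path
}

test_that("gen_vocab builds all ten codelists with identity rows", {
  ct <- withr::local_tempfile(fileext = ".tsv")
  make_ct_fixture(ct)
  v <- gen_vocab(ct)
  expect_s3_class(v, "send_vocab")
  expect_setequal(names(v$codelists), sendhc:::SUPPORTED_CODELISTS)
  nn <- v$codelists[["non-neoplastic finding type"]]
  # the lung/spleen cellularity mappings are present
  expect_identical(unname(nn[["ALVEOLAR MACROPHAGES, INCREASED"]]),
                   "CELLULARITY, INCREASED")
  expect_identical(unname(nn[["AGGREGATE"]]), "CELLULARITY, INCREASED")
  expect_identical(unname(nn[["FOLLICLES, INCREASED"]]), "CELLULARITY, INCREASED")
  # every preferred value maps to itself
  for (cl in v$codelists) expect_true(all(cl[unique(cl)] == unique(cl)))

  # JSON round trip preserves the mappings
  jf <- withr::local_tempfile(fileext = ".json")
  write_vocab(v, jf)
  v2 <- load_vocab(jf)
  expect_identical(
    v2$codelists[["non-neoplastic finding type"]][order(names(nn))],
    nn[order(names(nn))])
})

test_that("gen_vocab skips unknown codelists, rejects intra-layer conflicts,
          and lets extras override with a warning", {
  base <- write_tsv_fixture(c(
    "Sex\tM\tMALE\tNo",
    "Nonsense List\tX\tY\tNo"))
  expect_warning(v <- gen_vocab(base), "unsupported codelist")
  expect_false(is.null(v$codelists$sex))

  clash <- write_tsv_fixture(c(
    "Sex\tM\tUNCLEAR\tNo",
    "Sex\tF\tUNCLEAR\tNo"))
  expect_error(gen_vocab(clash), "conflicting synonym")

  extra <- write_tsv_fixture(
    "Non-Neoplastic Finding Type\tCELLULARITY, INCREASED\tAGGREGATE\tYes")
  ct <- write_tsv_fixture(
    "Non-Neoplastic Finding Type\tAGGREGATE\t\tYes")
  expect_warning(v2 <- gen_vocab(ct, extra_files = extra), "override")
  expect_identical(
    unname(v2$codelists[["non-neoplastic finding type"]][["AGGREGATE"]]),
    "CELLULARITY, INCREASED")

  # empty extras leave the CT content untouched
  v3 <- gen_vocab(write_tsv_fixture("Sex\tM\tMALE\tNo"))
  expect_identical(unname(v3$codelists$sex[["MALE"]]), "M")
  expect_equal(length(v3$codelists$sex), 2L)
})

test_that("apply_map hits after uppercase/trim and misses verbatim", {
  fx <- fx_usecase2()
  m <- apply_map(c("vehicle control", "  SALINE CONTROL ", "mystery brew", ""),
                 "send control type", fx$vocab)
  expect_identical(m$value[1], "VEHICLE CONTROL")
  expect_identical(m$value[2], "VEHICLE CONTROL")
  expect_identical(m$value[3], "mystery brew")  # miss preserved verbatim
  expect_identical(m$value[4], "")
  expect_identical(m$hit, c(TRUE, TRUE, FALSE, FALSE))
  # identity row hits
  id <- apply_map("CELLULARITY, INCREASED", "non-neoplastic finding type",
                  fx$vocab)
  expect_true(id$hit)
  expect_identical(id$value, "CELLULARITY, INCREASED")
  expect_error(apply_map("x", "no such list", fx$vocab), "unknown codelist")
})

test_that("standardize_file rewrites bound variables and reports changes", {
  fx <- fx_usecase2()
  # report completeness: per-file totals equal a brute-force record diff
  for (study in list.dirs(fx$root, recursive = FALSE)[1]) {
    out <- file.path(withr::local_tempdir(), "clean")
    rep <- standardize_file(study, out, fx$vocab)
    for (f in list.files(study, pattern = "\\.xpt$")) {
      pre <- read_xpt(file.path(study, f))$data
      post <- read_xpt(file.path(out, f))$data
      expect_identical(dim(pre), dim(post))
      changed <- sum(vapply(names(pre), function(v) {
        sum(!is.na(pre[[v]]) & !is.na(post[[v]]) & pre[[v]] != post[[v]])
      }, numeric(1)))
      expect_equal(unname(attr(rep, "totals")[f]), changed, info = f)
    }
    expect_true(file.exists(file.path(out, "clean_report.csv")))
    # unbound variables byte-identical: MIORRES keeps the verbatim term
    pre_mi <- read_xpt(file.path(study, "mi.xpt"))$data
    post_mi <- read_xpt(file.path(out, "mi.xpt"))$data
    expect_identical(pre_mi$MIORRES, post_mi$MIORRES)
    expect_identical(pre_mi$USUBJID, post_mi$USUBJID)
  }
})

test_that("standardize_file is idempotent and refuses in-place overwrite", {
  fx <- fx_usecase2()
  study <- list.dirs(fx$root, recursive = FALSE)[1]
  out1 <- file.path(withr::local_tempdir(), "pass1")
  out2 <- file.path(withr::local_tempdir(), "pass2")
  standardize_file(study, out1, fx$vocab)
  rep2 <- standardize_file(out1, out2, fx$vocab)
  expect_equal(nrow(rep2), 0L)  # second pass changes nothing
  for (f in list.files(out1, pattern = "\\.xpt$")) {
    expect_identical(read_xpt(file.path(out1, f))$data,
                     read_xpt(file.path(out2, f))$data, info = f)
  }
  expect_error(standardize_file(study, study, fx$vocab), "in-place")
})

test_that("an identity vocabulary leaves files record-identical", {
  study <- fx_single_study()$folder
  v <- gen_vocab(write_tsv_fixture("Sex\tNO-MATCH-EVER\t\tNo"))
  out <- file.path(withr::local_tempdir(), "ident")
  rep <- standardize_file(study, out, v)
  expect_equal(nrow(rep), 0L)
  for (f in list.files(study, pattern = "\\.xpt$")) {
    expect_identical(read_xpt(file.path(study, f))$data,
                     read_xpt(file.path(out, f))$data, info = f)
  }
})

test_that("TX control-type values are cleaned only on TCNTRL parameter rows", {
  d <- withr::local_tempdir()
  tx <- domain_table("TX", data.frame(
    STUDYID = "S", DOMAIN = "TX", SETCD = c("A", "A"), SET = "set",
    TXSEQ = 1:2, TXPARMCD = c("TCNTRL", "GRPLBL"),
    TXPARM = c("Control Type", "Group Label"),
    TXVAL = c("vehicle", "vehicle"), stringsAsFactors = FALSE))
  write_xpt(tx, file.path(d, "tx.xpt"))
  fx <- fx_usecase2()
  out <- file.path(withr::local_tempdir(), "txclean")
  standardize_file(d, out, fx$vocab)
  post <- read_xpt(file.path(out, "tx.xpt"))$data
  expect_identical(post$TXVAL[post$TXPARMCD == "TCNTRL"], "VEHICLE CONTROL")
  expect_identical(post$TXVAL[post$TXPARMCD == "GRPLBL"], "vehicle")
})
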