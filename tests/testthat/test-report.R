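# Orchestration, report aggregation, filtering and the CLI.

test_that("a clean neutral achiral record yields no issues", {
  iss <- validate_record(ethanol_record())
  expect_length(iss, 0L)
})

test_that("query atoms yield both the atom error and the InChI failure", {
  rec <- parse_molfile(make_fixture("query_atom")$molfile)
  codes <- chemcheck:::.codes_of(validate_record(rec))
  expect_true(all(c("query_atom", "inchi_generation_failed") %in% codes))
})

test_that("issues carry their record index and summary counts distinct records", {
  vs <- validated_suite()
  rep <- vs$report
  for (i in seq_along(rep$entries)) {
    for (iss in rep$entries[[i]]$issues) {
      expect_equal(iss$record_index, rep$entries[[i]]$record_index)
    }
  }
  # summary[code] equals the number of entries whose issues contain code
  for (code in names(rep$summary)) {
    n <- sum(vapply(rep$entries, function(e)
      code %in% chemcheck:::.codes_of(e$issues), logical(1)))
    expect_equal(unname(rep$summary[[code]]), n, label = code)
  }
})

test_that("exactly the three severity levels ever appear", {
  vs <- validated_suite()
  sev <- unique(unlist(lapply(vs$report$entries, function(e)
    vapply(e$issues, function(i) i$severity, character(1)))))
  expect_setequal(sev, c("Error", "Warning", "Information"))
})

test_that("filtering retains entries matching both filters and is non-destructive", {
  vs <- validated_suite()
  rep <- vs$report
  errs <- filter_report(rep, severities = "Error")
  expect_true(all(vapply(errs$entries, function(e)
    any(vapply(e$issues, function(i) i$severity == "Error", logical(1))),
    logical(1))))
  expect_length(rep$entries, length(vs$suite)) # original untouched

  # empty filters: identity
  same <- filter_report(rep)
  expect_length(same$entries, length(rep$entries))

  # filtering by one code returns exactly the records the summary counts
  by_code <- filter_report(rep, codes = "relative_stereo")
  expect_length(by_code$entries, unname(rep$summary[["relative_stereo"]]))

  expect_error(filter_report(rep, severities = "Fatal"), "unknown severities")
  expect_error(filter_report(rep, codes = "no_such_code"),
               "unknown issue codes")
})

test_that("reports serialize deterministically", {
  recs <- list(parse_molfile(make_fixture("contains_enol")$molfile, 1L),
               parse_molfile(make_fixture("net_charge_nonzero")$molfile, 2L))
  j1 <- report_to_json(build_report(recs))
  j2 <- report_to_json(build_report(recs))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("standardization is opt-in and reprotonates in the report", {
  rec <- parse_molfile(
    make_fixture("strongest_acid_not_ionized_first")$molfile)
  plain <- build_report(list(rec))
  expect_true("strongest_acid_not_ionized_first" %in% names(plain$summary))
  fixed <- build_report(list(rec), chemcheck_options(standardize = TRUE))
  expect_false("strongest_acid_not_ionized_first" %in% names(fixed$summary))
  expect_true(fixed$entries[[1]]$standardized)
})

test_that("the CLI validates, filters, exports and signals unreadable input", {
  dir <- tempfile("cli")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  recs <- list(parse_molfile(make_fixture("bad_valence")$molfile, 1L),
               ethanol_record())
  recs[[1]]$sdf_fields <- c(DB_ID = "A1")
  recs[[2]]$sdf_fields <- c(DB_ID = "A2")
  sdf <- file.path(dir, "in.sdf")
  write_sdf(recs, sdf)
  out <- file.path(dir, "report.json")
  exp_sdf <- file.path(dir, "errors.sdf")
  status <- run_cli(c("validate", sdf, "--map", "DB_ID=REGID",
                      "--out", out,
                      "--filter-severity", "Error",
                      "--export", exp_sdf))
  expect_equal(status, 0L)
  j <- jsonlite::read_json(out)
  expect_length(j$records, 1L)
  expect_equal(j$records[[1]]$regid, "A1")
  expect_length(parse_sdf(exp_sdf), 1L)

  expect_equal(run_cli(c("validate", file.path(dir, "missing.sdf"))), 2L)
  expect_equal(run_cli(c("frobnicate")), 1L)
  expect_equal(run_cli(c("validate", sdf, "--bogus-flag", "x")), 1L)
})

test_that("the CLI reads gzip-compressed SDF transparently", {
  dir <- tempfile("cligz")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  sdf_gz <- file.path(dir, "in.sdf.gz")
  con <- gzfile(sdf_gz, "wt")
  writeLines(write_sdf(list(ethanol_record())), con)
  close(con)
  out <- file.path(dir, "r.json")
  expect_equal(run_cli(c("validate", sdf_gz, "--out", out)), 0L)
  expect_length(jsonlite::read_json(out)$records, 1L)
})
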