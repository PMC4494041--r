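# Connection-table reading and writing.

test_that("a minimal well-formed molfile parses into the expected record", {
  rec <- ethanol_record()
  parsed <- parse_molfile(write_molfile(rec))
  expect_equal(nrow(parsed$atoms), 3L)
  expect_equal(nrow(parsed$bonds), 2L)
  expect_false(parsed$chiral_flag)
  expect_false(parsed$has_3d)
  expect_equal(parsed$atoms$symbol, c("C", "C", "O"))
  expect_equal(parsed$bonds$order, c("single", "single"))
})

test_that("query atom symbols are flagged, not rejected", {
  rec <- parse_molfile(make_fixture("query_atom")$molfile)
  expect_true(rec$atoms$is_query[1])
  expect_false(any(rec$atoms$is_query[-1]))
})

test_that("M  CHG property lines supersede atom-block charge codes", {
  # atom-block charge code 0 but an M CHG line setting atom 1 to -1
  mol <- paste(
    "", "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "M  CHG  1   1  -1",
    "M  END", sep = "\n")
  rec <- parse_molfile(mol)
  expect_equal(rec$atoms$charge, c(-1L, 0L))

  # atom-block code present but M CHG resets everything it does not list
  mol2 <- sub("O   0  0", "O   0  3", mol) # code 3 = +1 in the atom block
  rec2 <- parse_molfile(sub("M  CHG  1   1  -1", "M  CHG  1   2   1", mol2))
  expect_equal(rec2$atoms$charge, c(0L, 1L))
})

test_that("V3000 and structurally corrupt blocks raise parse errors", {
  expect_error(parse_molfile("x\n\n\n  0  0  0  0  0  0  0  0  0  0 V3000"),
               class = "chemcheck_parse_error")
  expect_error(parse_molfile("x\n\n\n  z bad counts"),
               class = "chemcheck_parse_error")
  good <- write_molfile(ethanol_record())
  truncated <- paste(head(strsplit(good, "\n")[[1]], 6), collapse = "\n")
  expect_error(parse_molfile(truncated), class = "chemcheck_parse_error")
})

test_that("SDF parsing maps fields and isolates corrupt records", {
  r1 <- ethanol_record()
  r1$sdf_fields <- c(DATABASE_ID = "DB1", Extra = "x")
  r2 <- ethanol_record()
  r2$sdf_fields <- c(DATABASE_ID = "DB2")
  sdf <- write_sdf(list(r1, r2))
  recs <- parse_sdf(strsplit(sdf, "\n")[[1]],
                    map = field_map(DATABASE_ID = "REGID"))
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$mapped$REGID, "DB1")
  expect_equal(recs[[2]]$mapped$REGID, "DB2")
  expect_equal(recs[[1]]$sdf_fields[["Extra"]], "x")
  expect_equal(vapply(recs, `[[`, integer(1), "source_index"), 1:2)

  # empty field map: nothing mapped, fields still captured
  recs0 <- parse_sdf(strsplit(sdf, "\n")[[1]])
  expect_null(recs0[[1]]$mapped$REGID)
  expect_equal(recs0[[1]]$sdf_fields[["DATABASE_ID"]], "DB1")

  # corrupt middle record must not suppress its neighbors
  blocks <- strsplit(sdf, "\n")[[1]]
  corrupt <- c(blocks[seq_len(which(blocks == "$$$$")[1])],
               "broken", "", "", "  x bad", "$$$$",
               blocks[(which(blocks == "$$$$")[1] + 1):length(blocks)])
  recs3 <- parse_sdf(corrupt, map = field_map(DATABASE_ID = "REGID"))
  expect_length(recs3, 3L)
  expect_null(recs3[[1]]$parse_error)
  expect_false(is.null(recs3[[2]]$parse_error))
  expect_null(recs3[[3]]$parse_error)
  expect_equal(recs3[[3]]$mapped$REGID, "DB2")
})

test_that("field maps reject duplicate or unknown reserved bindings", {
  expect_error(field_map(A = "REGID", B = "REGID"), "more than once")
  expect_error(field_map(A = "NOPE"), "targets must be")
  expect_error(chemcheck:::parse_field_map_specs("X=bad"), "--map")
})

test_that("write/parse round-trips every fixture on all connection-table fields", {
  vs <- validated_suite()
  for (code in setdiff(names(vs$suite), "parse_error")) {
    r1 <- parse_molfile(vs$suite[[code]]$molfile)
    r2 <- parse_molfile(write_molfile(r1))
    expect_identical(r1$atoms, r2$atoms, label = paste("atoms of", code))
    expect_identical(r1$bonds, r2$bonds, label = paste("bonds of", code))
    expect_identical(r1$chiral_flag, r2$chiral_flag)
    expect_identical(r1$has_3d, r2$has_3d, label = paste("has_3d of", code))
  }
})

test_that("SDF round-trip preserves wedges, charges and data fields", {
  rec <- parse_molfile(make_fixture("relative_stereo")$molfile)
  rec$sdf_fields <- c(NOTE = "two\nlines", ID = "r1")
  back <- parse_sdf(strsplit(write_sdf(list(rec)), "\n")[[1]])[[1]]
  expect_identical(back$bonds$wedge, rec$bonds$wedge)
  expect_identical(back$sdf_fields[["NOTE"]], "two\nlines")
  expect_identical(back$chiral_flag, rec$chiral_flag)
})

test_that("writing zero records yields an empty stream", {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  expect_equal(write_sdf(list(), tmp), 0L)
  expect_length(parse_sdf(tmp), 0L)
})

test_that("SMILES parsing produces coordinate-free records and classed errors", {
  eth <- parse_smiles("CCO")
  expect_equal(nrow(eth$atoms), 3L)
  expect_false(eth$has_3d)
  expect_true(all(eth$atoms$x == 0 & eth$atoms$y == 0 & eth$atoms$z == 0))
  benzene <- parse_smiles("C1=CC=CC=C1")
  expect_equal(nrow(benzene$atoms), 6L)
  expect_setequal(unique(benzene$bonds$order), c("single", "double"))
  expect_error(parse_smiles("C("), class = "chemcheck_invalid_smiles")
})
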