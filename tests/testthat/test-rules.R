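# SMARTS abbreviation expansion and the dictionary rule engine.

test_that("abbreviations expand to the published element classes", {
  hal <- expand_abbreviations("{Hal}")
  expect_equal(hal, "[#9,#17,#35,#53]") # F, Cl, Br, I
  pn <- expand_abbreviations("{Pn}")
  expect_equal(pn, "[#15,#33,#51]") # P, As, Sb
  expect_equal(expand_abbreviations("c1ccccc1"), "c1ccccc1")
  # idempotent
  expect_equal(expand_abbreviations(hal), hal)
  expect_error(expand_abbreviations("{NoSuchClass}"),
               "unknown SMARTS abbreviation")
  # the metal class excludes carbon, hydrogen and the non-metal list
  m <- expand_abbreviations("{M}")
  expect_false(grepl("(?<![0-9])#1(?![0-9])", m, perl = TRUE)) # no H
  expect_false(grepl("(?<![0-9])#6(?![0-9])", m, perl = TRUE)) # no C
  expect_true(grepl("#11", m))  # Na
  # V6 metals are exactly Cr, Mo, W, Mn, Pt
  expect_equal(expand_abbreviations("{M_V6}"), "[#24,#42,#74,#25,#78]")
  # charged class carries the charge on every alternative
  expect_equal(expand_abbreviations("{M_+1}"),
               gsub("(#[0-9]+)", "\\1+", expand_abbreviations("{M}")))
})

test_that("rule XML loads with severities, combinators and error reporting", {
  rs <- load_ruleset_xml(
    '<rules><Warning name="w" message="phenol"><test name="SMARTStest" param="[OH]c"/></Warning></rules>')
  expect_length(rs$rules, 1L)
  expect_equal(rs$rules$w$severity, "Warning")
  expect_equal(rs$rules$w$combinator, "single")
  expect_length(load_ruleset_xml("<rules></rules>")$rules, 0L)
  expect_error(
    load_ruleset_xml('<rules><Warning message="m"><test name="RegexTest" param="x"/></Warning></rules>'),
    "only SMARTS tests are supported")
  expect_error(
    load_ruleset_xml('<rules><Error name="bad" message="m"><test name="SMARTStest" param="[[["/></Error></rules>'),
    "invalid SMARTS")
})

test_that("default rules fire on their canonical triggers and not on benzene", {
  vs <- validated_suite()
  rep <- vs$report
  i_frag <- which(names(vs$suite) == "fragment_small_molecule")
  expect_true("fragment_small_molecule" %in% entry_codes(rep, i_frag))
  i_enol <- which(names(vs$suite) == "contains_enol")
  expect_true("contains_enol" %in% entry_codes(rep, i_enol))
  benzene <- make_ring_record(rep("C", 6), order = "aromatic")
  expect_length(evaluate_rules(benzene, default_ruleset()), 0L)
})

test_that("an OR rule fires iff at least one of its tests fires alone", {
  tests <- c("[OX2H]", "[F]", "[NX3]")
  or_xml <- sprintf(
    '<rules><Warning name="or_rule" message="or"><or>%s</or></Warning></rules>',
    paste(sprintf('<test name="SMARTStest" param="%s"/>', tests),
          collapse = ""))
  or_rs <- load_ruleset_xml(or_xml)
  single_rs <- lapply(tests, function(p) load_ruleset_xml(sprintf(
    '<rules><Warning name="s" message="s"><test name="SMARTStest" param="%s"/></Warning></rules>', p)))
  mols <- list(parse_smiles("CCO"), parse_smiles("CCF"),
               parse_smiles("CCCC"), parse_smiles("NCC(O)CF"))
  for (mol in mols) {
    fired_or <- length(evaluate_rules(mol, or_rs)) > 0
    fired_any <- any(vapply(single_rs, function(rs)
      length(evaluate_rules(mol, rs)) > 0, logical(1)))
    expect_identical(fired_or, fired_any)
  }
})

test_that("an AND rule needs all of its tests", {
  and_rs <- load_ruleset_xml(
    '<rules><Error name="and_rule" message="and"><and><test name="SMARTStest" param="[OX2H]"/><test name="SMARTStest" param="C=C"/></and></Error></rules>')
  expect_length(evaluate_rules(parse_smiles("CCO"), and_rs), 0L)
  expect_length(evaluate_rules(parse_smiles("C=CC"), and_rs), 0L)
  fired <- evaluate_rules(parse_smiles("C=CCO"), and_rs)
  expect_length(fired, 1L)
  expect_equal(fired[[1]]$code, "and_rule")
  expect_equal(fired[[1]]$severity, "Error")
})

test_that("rule evaluation is deterministic", {
  rec <- parse_molfile(make_fixture("contains_enol")$molfile)
  i1 <- issues_df(evaluate_rules(rec, default_ruleset()))
  i2 <- issues_df(evaluate_rules(rec, default_ruleset()))
  expect_identical(i1, i2)
})

test_that("a multiply-firing rule yields one issue with all locants", {
  two_waters <- new_molrec(
    atoms_df(c("O", "O"), c(0, 3), c(0, 0)),
    bonds_df(integer(), integer()))
  iss <- evaluate_rules(two_waters, default_ruleset())
  frag <- iss[vapply(iss, function(x) x$code, character(1)) ==
                "fragment_small_molecule"]
  expect_length(frag, 1L)
  expect_setequal(frag[[1]]$atoms, c(1L, 2L))
})
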