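# Competitive ionization: table loading, state assignment, violation
# detection and reprotonation, including brute-force optimality on random
# polyprotic molecules.

test_that("the shipped table reproduces the published ranking", {
  groups <- default_acid_groups()
  expect_length(groups, 33L)
  ranks <- vapply(groups, `[[`, integer(1), "rank")
  expect_equal(ranks, seq(10L, 330L, by = 10L))
  expect_equal(groups[[1]]$name, "OSO3H")
  expect_equal(groups[[1]]$acid, "OS(=O)(=O)[O;H]")
  co2h <- groups[[which(ranks == 70L)]]
  expect_equal(co2h$name, "CO2H")
  expect_equal(co2h$base, "C(=O)[O-]")
  arom_oh <- groups[[which(ranks == 170L)]]
  expect_equal(arom_oh$acid, "c[OH]")
})

test_that("acid-group XML schema violations are load errors", {
  expect_error(load_acid_groups(
    '<acidgroups><acidgroup name="X" rank="10" acid="[OH]" base="[O-]" acid2base="[OH:1]>>[O-:1]"/></acidgroups>'),
    "missing attribute")
  expect_error(load_acid_groups(
    '<acidgroups><acidgroup rank="0" acid="a" base="b" acid2base="x" base2acid="y"/></acidgroups>'),
    "non-positive rank")
  expect_error(load_acid_groups("<acidgroups></acidgroups>"),
               "no <acidgroup> elements")
})

test_that("ionization states are assigned with rank-based overlap resolution", {
  benzoic <- parse_smiles("OC(=O)c1ccccc1")
  st <- assign_ionization_state(benzoic)
  acid_matches <- st$matches[st$matches$form == "acid" &
                               st$matches$rank == 70L, ]
  expect_equal(nrow(acid_matches), 1L)
  expect_equal(acid_matches$name, "CO2H")

  phenolate <- parse_smiles("[O-]c1ccccc1")
  st2 <- assign_ionization_state(phenolate)
  base_m <- st2$matches[st2$matches$form == "base", ]
  expect_equal(base_m$name, "Arom-OH")
  expect_equal(base_m$rank, 170L)

  methane <- parse_smiles("C")
  st3 <- assign_ionization_state(methane)
  # no ionizable group: at most the generic C-H acids, never a base form
  expect_false(any(st3$matches$form == "base"))

  # retained matches have pairwise disjoint atom sets
  st4 <- assign_ionization_state(
    parse_molfile(make_fixture("strongest_acid_not_ionized_first")$molfile))
  all_atoms <- unlist(st4$matches$atoms)
  expect_equal(anyDuplicated(all_atoms), 0L)
})

test_that("a weaker acid ionized before a stronger one is flagged", {
  wrong <- parse_molfile(
    make_fixture("strongest_acid_not_ionized_first")$molfile)
  iss <- check_competitive_ionization(assign_ionization_state(wrong))
  expect_equal(iss$code, "strongest_acid_not_ionized_first")
  expect_equal(iss$severity, "Information")

  # the correct depiction: carboxylate ionized, phenol neutral
  right <- parse_smiles("[O-]C(=O)c1ccc(O)cc1")
  expect_null(check_competitive_ionization(assign_ionization_state(right)))

  neutral <- parse_smiles("OC(=O)c1ccc(O)cc1")
  expect_null(check_competitive_ionization(assign_ionization_state(neutral)))
})

test_that("reprotonation reaches the canonical state and conserves matter", {
  rec <- parse_molfile(
    make_fixture("strongest_acid_not_ionized_first")$molfile)
  before_charge <- net_charge(rec)
  before_formula <- molecular_formula(rec)
  res <- reprotonate_to_canonical(rec)
  expect_true(res$changed)
  expect_length(res$issues, 0L)
  expect_equal(net_charge(res$record), before_charge)
  expect_equal(molecular_formula(res$record), before_formula)
  # fixpoint: the violation is gone and a second pass changes nothing
  expect_null(check_competitive_ionization(
    assign_ionization_state(res$record)))
  res2 <- reprotonate_to_canonical(res$record)
  expect_false(res2$changed)
  expect_identical(res2$record$atoms, res$record$atoms)
})

test_that("a fully ionized polyacid is already canonical", {
  dianion <- parse_smiles("[O-]C(=O)CCC(=O)[O-]")
  expect_null(check_competitive_ionization(
    assign_ionization_state(dianion)))
  res <- reprotonate_to_canonical(dianion)
  expect_false(res$changed)
})

test_that("random polyprotic molecules reprotonate to the brute-force optimum", {
  set.seed(42)
  lib <- c("sulfo", "carboxyl", "thiol", "hydroxyl")
  for (trial in seq_len(12)) {
    n <- sample(2:4, 1)
    groups <- sample(lib, n, replace = TRUE)
    k <- sample(seq_len(n), 1) # number of removed protons
    ionized <- seq_len(n) %in% sample(seq_len(n), k)
    rec <- make_polyprotic(groups, ionized)
    res <- reprotonate_to_canonical(rec)
    st <- assign_ionization_state(res$record)
    got <- sort(st$matches$rank[st$matches$form == "base"])
    ranks <- vapply(groups, group_rank, integer(1))
    optimum <- unname(sort(sort(ranks)[seq_len(k)]))
    expect_equal(got, optimum,
                 label = paste("trial", trial, ":",
                               paste(groups, collapse = "+"), "k =", k))
    expect_equal(net_charge(res$record), -k)
    expect_equal(molecular_formula(res$record), molecular_formula(rec))
    expect_null(check_competitive_ionization(st))
  }
})

test_that("equal ranks never violate each other", {
  two_acids <- make_polyprotic(c("carboxyl", "carboxyl"),
                               c(TRUE, FALSE))
  expect_null(check_competitive_ionization(
    assign_ionization_state(two_acids)))
})
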