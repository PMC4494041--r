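# Stereocenter perception, the wedge geometry battery and the
# undefined-stereo classifier.

chfclbr <- function(wedge_to_f = "none", chiral = TRUE) {
  rec <- new_molrec(
    atoms_df(c("C", "F", "Cl", "Br"), c(0, 1, -0.5, -0.5),
             c(0, 0, 0.87, -0.87)),
    bonds_df(c(1, 1, 1), c(2, 3, 4),
             wedge = c(wedge_to_f, "none", "none")),
    chiral_flag = chiral)
  rec
}

test_that("potential and defined stereocenters are perceived", {
  bare <- chfclbr()
  sc <- find_stereocenters(bare)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$atom, 1L)
  expect_false(sc$defined)

  wedged <- chfclbr("up")
  sc2 <- find_stereocenters(wedged)
  expect_true(sc2$defined)

  expect_equal(nrow(find_stereocenters(ethanol_record())), 0L)
})

test_that("symmetry analysis agrees with an independent perception", {
  # oracle: RDKit chiral-center detection on the same molblocks
  cases <- list(
    list(rec = chfclbr(), n = 1L),
    list(rec = ethanol_record(), n = 0L),
    list(rec = parse_molfile(make_fixture("undefined_stereo_mixtures")$molfile),
         n = 2L),
    list(rec = parse_molfile(make_fixture("stereobond_in_ring")$molfile),
         n = 1L)
  )
  for (cs in cases) {
    res <- chemcheck:::chem_backend(list(list(
      op = "stereocenters", molblock = write_molfile(cs$rec))))[[1]]
    expect_true(isTRUE(res$ok))
    expect_equal(length(res$centers), cs$n)
    ours <- find_stereocenters(cs$rec)
    expect_equal(nrow(ours), cs$n)
    if (cs$n > 0) {
      expect_setequal(ours$atom,
                      vapply(res$centers, function(x) x$atom, integer(1)))
    }
  }
})

test_that("the wedge battery flags each depiction error", {
  fx <- function(code) parse_molfile(make_fixture(code)$molfile)
  codes <- function(rec) chemcheck:::.codes_of(validate_wedges(rec))
  expect_true("wedge_on_non_stereocenter" %in%
                codes(fx("wedge_on_non_stereocenter")))
  expect_true("wedge_points_at_stereocenter" %in%
                codes(fx("wedge_points_at_stereocenter")))
  expect_true("stereo_bond_direction_nonsense" %in%
                codes(fx("stereo_bond_direction_nonsense")))
  expect_true("two_same_wedges_at_center" %in%
                codes(fx("two_same_wedges_at_center")))
  expect_true("up_and_down_at_center" %in%
                codes(fx("up_and_down_at_center")))
  expect_true("stereo_bond_angle_too_small" %in%
                codes(fx("stereo_bond_angle_too_small")))
  expect_true("implicit_h_near_stereocenter" %in%
                codes(fx("implicit_h_near_stereocenter")))
})

test_that("the wedge battery never fires without wedge bonds", {
  vs <- validated_suite()
  for (code in setdiff(names(vs$suite), "parse_error")) {
    rec <- parse_molfile(vs$suite[[code]]$molfile)
    if (!any(rec$bonds$wedge %in% c("up", "down"))) {
      expect_length(validate_wedges(rec), 0L)
    }
  }
})

test_that("same-type wedges are judged by adjacency, mixed by opposition", {
  center <- function(a2_deg, w1, w2) {
    new_molrec(
      atoms_df(c("C", "F", "Cl", "Br", "C"),
               c(0, 1, cos(a2_deg * pi / 180), -0.5, -1),
               c(0, 0, sin(a2_deg * pi / 180), -0.87, 0.5)),
      bonds_df(rep(1, 4), 2:5, wedge = c(w1, w2, "none", "none")),
      chiral_flag = TRUE)
  }
  # two up wedges nearly opposite: no finding (trans depiction is legal)
  expect_length(validate_wedges(center(170, "up", "up")), 0L)
  # up + down adjacent: only the small-angle warning can apply, not here
  expect_length(validate_wedges(center(60, "up", "down")), 0L)
  # and the error cases
  expect_equal(chemcheck:::.codes_of(validate_wedges(center(60, "up", "up"))),
               "two_same_wedges_at_center")
  expect_equal(chemcheck:::.codes_of(validate_wedges(center(170, "up", "down"))),
               "up_and_down_at_center")
})

test_that("the small-angle severity is configurable", {
  rec <- parse_molfile(make_fixture("stereo_bond_angle_too_small")$molfile)
  default <- validate_wedges(rec)
  expect_equal(default[[1]]$severity, "Warning")
  strict <- validate_wedges(rec,
                            chemcheck_options(angle_rule_severity = "Error"))
  expect_equal(strict[[1]]$severity, "Error")
})

test_that("undefined-stereo categories follow the (defined, undefined) counts", {
  fx <- function(code) parse_molfile(make_fixture(code)$molfile)
  expect_equal(categorize_undefined_stereo(fx("undefined_stereo_epimers"))$code,
               "undefined_stereo_epimers")
  expect_equal(
    categorize_undefined_stereo(fx("undefined_stereo_partial_mixtures"))$code,
    "undefined_stereo_partial_mixtures")
  expect_equal(
    categorize_undefined_stereo(fx("undefined_stereo_enantiomers"))$code,
    "undefined_stereo_enantiomers")
  expect_equal(categorize_undefined_stereo(fx("undefined_stereo_mixtures"))$code,
               "undefined_stereo_mixtures")
  # fully defined: no category
  expect_null(categorize_undefined_stereo(chfclbr("up")))
  # the four categories are distinct
  cats <- vapply(c("undefined_stereo_epimers",
                   "undefined_stereo_partial_mixtures",
                   "undefined_stereo_enantiomers",
                   "undefined_stereo_mixtures"),
                 function(code) categorize_undefined_stereo(fx(code))$code,
                 character(1))
  expect_length(unique(cats), 4L)
})

test_that("an either-type stereo bond marks a center unknown, not defined", {
  rec <- chfclbr()
  rec$bonds$wedge[1] <- "either_sp3"
  sc <- find_stereocenters(rec)
  expect_true(sc$marked_unknown)
  expect_false(sc$defined)
  expect_equal(categorize_undefined_stereo(rec)$code,
               "undefined_stereo_enantiomers")
})

test_that("relative-stereo, cross-bond, ring and 3D flags", {
  rel <- parse_molfile(make_fixture("relative_stereo")$molfile)
  expect_true("relative_stereo" %in%
                chemcheck:::.codes_of(check_relative_and_cross(rel)))
  flagged <- rel
  flagged$chiral_flag <- TRUE
  expect_false("relative_stereo" %in%
                 chemcheck:::.codes_of(check_relative_and_cross(flagged)))
  cross <- parse_molfile(make_fixture("unknown_double_bond_stereo")$molfile)
  expect_true("unknown_double_bond_stereo" %in%
                chemcheck:::.codes_of(check_relative_and_cross(cross)))
  ring <- parse_molfile(make_fixture("stereobond_in_ring")$molfile)
  expect_true("stereobond_in_ring" %in%
                chemcheck:::.codes_of(check_relative_and_cross(ring)))
  three_d <- parse_molfile(make_fixture("contains_3d")$molfile)
  expect_true("contains_3d" %in%
                chemcheck:::.codes_of(check_relative_and_cross(three_d)))
  # 3D records skip wedge perception entirely
  expect_equal(nrow(find_stereocenters(three_d)), 0L)
})
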