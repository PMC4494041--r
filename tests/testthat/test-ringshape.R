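# Ring-walking signatures, the eight shape classes and the carbohydrate
# depiction flags.

rotate_str <- function(s, k) {
  n <- nchar(s); k <- k %% n
  if (k == 0) s else paste0(substr(s, k + 1, n), substr(s, 1, k))
}
complement_str <- function(s) chartr("LR", "RL", s)
all_signatures <- apply(expand.grid(rep(list(c("L", "R")), 6)), 1,
                        paste, collapse = "")

test_that("turn signatures from coordinates", {
  hexagon <- hexagon_coords()
  sig <- ring_signature(hexagon)
  expect_true(sig %in% c("LLLLLL", "RRRRRR")) # convex = homotropous
  expect_equal(canonical_shape(sig), "homotropous")
  # reversed walk direction gives the complementary homotropous string
  expect_equal(ring_signature(hexagon[6:1, ]), complement_str(sig))
  # chair template
  chair_sig <- ring_signature(chemcheck:::.chair_coords)
  expect_equal(canonical_shape(chair_sig), "chair")
  # three collinear points: undefined
  degenerate <- hexagon
  degenerate[2, ] <- (degenerate[1, ] + degenerate[3, ]) / 2
  expect_true(is.na(ring_signature(degenerate)))
})

test_that("named classes match the published signature table", {
  expect_equal(canonical_shape("LRRLRR"), "chair")
  expect_equal(canonical_shape("RLLRLL"), "chair")
  expect_equal(canonical_shape("LRLLRR"), "boat")
  expect_equal(canonical_shape("RLRRLL"), "boat")
  expect_equal(canonical_shape("LLLRRR"), "twist_boat")
  expect_equal(canonical_shape("RRLLLR"), "twist_boat")
  expect_equal(canonical_shape("LRRRRR"), "half_chair")
  expect_equal(canonical_shape("RLLLLL"), "half_chair")
  expect_equal(canonical_shape("LLLLLL"), "homotropous")
  expect_equal(canonical_shape("RRRRRR"), "homotropous")
  expect_equal(canonical_shape("RLRLRL"), canonical_shape("LRLRLR"))
  expect_error(canonical_shape("LRLRLX"), "six-character")
})

test_that("enumeration yields eight classes partitioning all 64 strings", {
  enum <- enumerate_shape_classes()
  expect_equal(enum$count, 8L)
  expect_length(enum$classes, 64L)
  expect_setequal(names(enum$classes), all_signatures)
  expect_setequal(unique(unname(enum$classes)),
                  names(enum$representatives))
})

test_that("shape is invariant under rotation, complement and mirroring", {
  for (s in all_signatures) {
    base <- canonical_shape(s)
    for (k in 1:5) expect_equal(canonical_shape(rotate_str(s, k)), base)
    expect_equal(canonical_shape(complement_str(s)), base)
  }
  # mirroring coordinates complements every turn
  set.seed(11)
  for (rep_i in 1:5) {
    coords <- hexagon_coords() + matrix(runif(12, -0.2, 0.2), 6, 2)
    sig <- ring_signature(coords)
    if (is.na(sig)) next
    mirrored <- coords
    mirrored[, 1] <- -mirrored[, 1]
    expect_equal(ring_signature(mirrored), complement_str(sig))
    # starting node must not matter
    for (k in 1:5) {
      shifted <- coords[c((k + 1):6, 1:k), , drop = FALSE]
      expect_equal(canonical_shape(ring_signature(shifted)),
                   canonical_shape(sig))
    }
  }
})

test_that("ring classification flags perspective pyranose depictions", {
  thp <- parse_molfile(make_fixture("perspective_ring_depiction")$molfile)
  res <- classify_rings(thp)
  expect_equal(nrow(res$rings), 1L)
  expect_equal(res$rings$shape, "chair")
  expect_equal(chemcheck:::.codes_of(res$issues),
               "perspective_ring_depiction")

  benzene <- make_ring_record(rep("C", 6), order = "single")
  res2 <- classify_rings(benzene)
  expect_equal(res2$rings$shape, "homotropous")
  expect_length(res2$issues, 0L)

  # an all-carbon chair is not a pyranose candidate
  chair6 <- new_molrec(
    atoms_df(rep("C", 6), chemcheck:::.chair_coords[, 1],
             chemcheck:::.chair_coords[, 2]),
    bonds_df(1:6, c(2:6, 1)))
  expect_length(classify_rings(chair6)$issues, 0L)
})

test_that("the Haworth heuristic needs long horizontal edges and vertical bonds", {
  hw <- parse_molfile(make_fixture("haworth_projection")$molfile)
  expect_true("haworth_projection" %in%
                chemcheck:::.codes_of(classify_rings(hw)$issues))
  # same ring without the vertical substituents: no flag
  ring_only <- subset_rec <- hw
  keep <- seq_len(6)
  ring_only <- chemcheck:::subset_record(hw, keep)
  expect_length(classify_rings(ring_only)$issues, 0L)
})

test_that("fused six-rings are excluded from shape classification", {
  hx1 <- hexagon_coords()
  atoms <- atoms_df(rep("C", 10),
                    c(hx1[, 1], 1.74, 2.61, 2.61, 1.74),
                    c(hx1[, 2], -1, -0.5, 0.5, 1))
  bonds <- bonds_df(
    c(1, 2, 3, 4, 5, 6, 3, 7, 8, 9, 10),
    c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 2))
  decalin <- new_molrec(atoms, bonds)
  expect_equal(nrow(classify_rings(decalin)$rings), 0L)
})

test_that("L-pyranose detection flips under mirroring", {
  l_form <- parse_molfile(make_fixture("contains_l_pyranose")$molfile)
  expect_equal(detect_l_pyranose(l_form)$code, "contains_l_pyranose")
  d_form <- l_form
  d_form$atoms$x <- -d_form$atoms$x
  expect_null(detect_l_pyranose(d_form))
  # the configuration oracle agrees: mirroring flips the CIP label at the
  # reference carbon
  lab <- function(rec) {
    res <- chemcheck:::chem_backend(list(list(
      op = "stereocenters", molblock = write_molfile(rec))))[[1]]
    labs <- vapply(res$centers, function(x) x$label, character(1))
    atoms <- vapply(res$centers, function(x) x$atom, integer(1))
    labs[atoms == 6L]
  }
  expect_equal(lab(l_form), "S")
  expect_equal(lab(d_form), "R")
  # no pyranose candidate: nothing to flag
  cyclohexane <- new_molrec(
    atoms_df(rep("C", 6), hexagon_coords()[, 1], hexagon_coords()[, 2]),
    bonds_df(1:6, c(2:6, 1)))
  expect_null(detect_l_pyranose(cyclohexane))
})
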