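# Programmatic fixtures: one minimal V2000 record per issue class.  These
# are the package's test surface — no external datasets are needed.  Each
# fixture is emitted as molfile text (not as a pre-built record) so the
# parser and every downstream check are exercised end to end.

.A <- function(symbol, x, y, z = 0, charge = 0L, radical = 0L) {
  data.frame(symbol = symbol, x = x, y = y, z = z,
             charge = as.integer(charge), radical = as.integer(radical),
             stringsAsFactors = FALSE)
}

.B <- function(begin, end, order = "single", wedge = "none") {
  data.frame(begin = as.integer(begin), end = as.integer(end),
             order = order, wedge = wedge, stringsAsFactors = FALSE)
}

.fx <- function(atoms, bonds, expected, chiral = TRUE, fields = NULL,
                description = "") {
  list(atoms = do.call(rbind, atoms), bonds = do.call(rbind, bonds),
       chiral = chiral, expected = expected, fields = fields,
       description = description)
}

.hexagon <- function(r = 1, phase = 90) {
  ang <- (phase - 60 * (0:5)) * pi / 180
  cbind(x = r * cos(ang), y = r * sin(ang))
}

# chair-template hexagon: closed equilateral polygon whose walk makes the
# turn pattern LRRLRR (left at two antipodal nodes), i.e. the chair class
.chair_coords <- local({
  ext <- c(30, -105, -105, 30, -105, -105) # signed exterior angles, sum -360
  heading <- cumsum(c(0, ext[-6])) * pi / 180
  x <- cumsum(c(0, cos(heading)))[1:6]
  y <- cumsum(c(0, sin(heading)))[1:6]
  cbind(x = x, y = y)
})

.ethanol_fx <- function(expected, fields = NULL) {
  .fx(list(.A("C", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0)),
      list(.B(1, 2), .B(2, 3)),
      expected = expected, fields = fields,
      description = "ethanol")
}

.benzene_atoms <- function(dx = 0, dy = 0) {
  hx <- .hexagon()
  lapply(seq_len(6), function(i) .A("C", hx[i, 1] + dx, hx[i, 2] + dy))
}

.benzene_bonds <- function(offset = 0) {
  lapply(seq_len(6), function(i) {
    .B(offset + i, offset + (i %% 6) + 1,
       order = if (i %% 2 == 1) "double" else "single")
  })
}

.fixture_definitions <- function() {
  defs <- list()

  defs$query_atom <- .fx(
    list(.A("A", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0)),
    list(.B(1, 2), .B(2, 3)),
    expected = c("query_atom", "inchi_generation_failed"),
    description = "ethanol backbone with query atom 'A'")
  defs$inchi_generation_failed <- defs$query_atom

  defs$query_bond <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0)),
    list(.B(1, 2, order = "query"), .B(2, 3)),
    expected = c("query_bond", "inchi_generation_failed"),
    description = "ethanol with an 'any' (type 8) bond")

  # aromatic imidazole without an explicit ring NH: two H placements kekulize
  pent <- cbind(x = cos((90 - 72 * (0:4)) * pi / 180),
                y = sin((90 - 72 * (0:4)) * pi / 180))
  defs$dearomatization_not_unique <- .fx(
    lapply(seq_len(5), function(i)
      .A(c("C", "N", "C", "N", "C")[i], pent[i, 1], pent[i, 2])),
    lapply(seq_len(5), function(i)
      .B(i, (i %% 5) + 1, order = "aromatic")),
    expected = c("dearomatization_not_unique", "inchi_generation_failed"),
    description = "imidazole drawn fully aromatic, no NH")

  defs$dearomatization_failed <- .fx(
    lapply(seq_len(5), function(i) .A("C", pent[i, 1], pent[i, 2])),
    lapply(seq_len(5), function(i)
      .B(i, (i %% 5) + 1, order = "aromatic")),
    expected = c("dearomatization_failed", "inchi_generation_failed"),
    description = "neutral all-carbon five-ring drawn aromatic")

  penta <- cbind(x = cos(2 * pi * (0:4) / 5 + pi / 2),
                 y = sin(2 * pi * (0:4) / 5 + pi / 2))
  defs$bad_valence <- .fx(
    c(list(.A("C", 0, 0)),
      lapply(seq_len(5), function(i) .A("F", penta[i, 1], penta[i, 2]))),
    lapply(seq_len(5), function(i) .B(1, i + 1)),
    expected = "bad_valence",
    description = "carbon with five bonds")

  defs$unusual_valence <- .fx(
    list(.A("C", 0, 0), .A("N", 1, 0), .A("O", 2, 0.8), .A("O", 2, -0.8)),
    list(.B(1, 2), .B(2, 3, "double"), .B(2, 4, "double")),
    expected = "unusual_valence",
    description = "nitromethane drawn with pentavalent nitrogen N(=O)=O")

  defs$wedge_on_non_stereocenter <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0.5), .A("C", 2, 0)),
    list(.B(2, 1, wedge = "up"), .B(2, 3)),
    expected = "wedge_on_non_stereocenter",
    description = "propane with an up-wedge from its CH2")

  defs$wedge_points_at_stereocenter <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", -0.5, 0.87),
         .A("Br", -0.5, -0.87)),
    list(.B(2, 1, wedge = "up"), .B(1, 3), .B(1, 4)),
    expected = c("wedge_points_at_stereocenter",
                 "undefined_stereo_enantiomers"),
    description = "bromochlorofluoromethane, wedge narrow end at fluorine")

  defs$stereo_bond_direction_nonsense <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0), .A("C", 1.5, 0.87),
         .A("C", 2.5, 0.87), .A("Br", 1, -1), .A("Cl", 1.5, 1.87)),
    list(.B(1, 2), .B(2, 3, wedge = "up"), .B(3, 4), .B(2, 5), .B(3, 6)),
    expected = c("stereo_bond_direction_nonsense",
                 "undefined_stereo_mixtures"),
    description = "wedge joining two stereocenters")

  ang10 <- c(cos(10 * pi / 180), sin(10 * pi / 180))
  defs$stereo_bond_angle_too_small <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", ang10[1], ang10[2]),
         .A("Br", -0.5, -0.87), .A("C", -0.5, 0.87)),
    list(.B(1, 2, wedge = "up"), .B(1, 3, wedge = "down"),
         .B(1, 4), .B(1, 5)),
    expected = "stereo_bond_angle_too_small",
    description = "two stereo bonds 10 degrees apart")

  ang60 <- c(cos(60 * pi / 180), sin(60 * pi / 180))
  defs$two_same_wedges_at_center <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", ang60[1], ang60[2]),
         .A("Br", -0.5, -0.87), .A("C", -1, 0.3)),
    list(.B(1, 2, wedge = "up"), .B(1, 3, wedge = "up"),
         .B(1, 4), .B(1, 5)),
    expected = c("two_same_wedges_at_center",
                 "undefined_stereo_enantiomers"),
    description = "two up-wedges 60 degrees apart at one center")

  ang170 <- c(cos(170 * pi / 180), sin(170 * pi / 180))
  defs$up_and_down_at_center <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", ang170[1], ang170[2]),
         .A("Br", -0.2, -1), .A("C", 0.5, 0.87)),
    list(.B(1, 2, wedge = "up"), .B(1, 3, wedge = "down"),
         .B(1, 4), .B(1, 5)),
    expected = c("up_and_down_at_center", "undefined_stereo_enantiomers"),
    description = "up and down wedges 170 degrees apart at one center")

  dirs <- rbind(c(cos(10 * pi / 180), sin(10 * pi / 180)),
                c(cos(80 * pi / 180), sin(80 * pi / 180)),
                c(cos(150 * pi / 180), sin(150 * pi / 180)))
  defs$implicit_h_near_stereocenter <- .fx(
    list(.A("C", 0, 0), .A("F", dirs[1, 1], dirs[1, 2]),
         .A("Cl", dirs[2, 1], dirs[2, 2]), .A("C", dirs[3, 1], dirs[3, 2])),
    list(.B(1, 2, wedge = "up"), .B(1, 3), .B(1, 4)),
    expected = c("implicit_h_near_stereocenter",
                 "undefined_stereo_enantiomers"),
    description = "stereocenter with all three explicit bonds in one half-plane")

  chain5 <- function(subs) {
    atoms <- list(.A("C", 0, 0), .A("C", 1, 0.3), .A("C", 2, 0),
                  .A("C", 3, 0.3), .A("C", 4, 0))
    bonds <- list(.B(1, 2), .B(2, 3), .B(3, 4), .B(4, 5))
    for (s in subs) {
      atoms <- c(atoms, list(.A(s$sym, s$x, s$y)))
      bonds <- c(bonds, list(.B(s$on, length(atoms), wedge = s$wedge)))
    }
    list(atoms = atoms, bonds = bonds)
  }

  ep <- chain5(list(list(sym = "Cl", x = 1, y = 1.3, on = 2, wedge = "up"),
                    list(sym = "Br", x = 2, y = -1, on = 3,
                         wedge = "none")))
  defs$undefined_stereo_epimers <- .fx(
    ep$atoms, ep$bonds,
    expected = "undefined_stereo_epimers",
    description = "one defined, one bare stereocenter")

  pm <- chain5(list(list(sym = "Cl", x = 1, y = 1.3, on = 2, wedge = "up"),
                    list(sym = "Br", x = 2, y = -1, on = 3, wedge = "none"),
                    list(sym = "F", x = 3, y = 1.3, on = 4,
                         wedge = "none")))
  defs$undefined_stereo_partial_mixtures <- .fx(
    pm$atoms, pm$bonds,
    expected = "undefined_stereo_partial_mixtures",
    description = "one defined, two bare stereocenters")

  defs$undefined_stereo_enantiomers <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", -0.5, 0.87),
         .A("Br", -0.5, -0.87)),
    list(.B(1, 2), .B(1, 3), .B(1, 4)),
    expected = "undefined_stereo_enantiomers",
    description = "bromochlorofluoromethane without wedges")

  mx <- chain5(list(list(sym = "Cl", x = 1, y = 1.3, on = 2,
                         wedge = "none"),
                    list(sym = "Br", x = 2, y = -1, on = 3,
                         wedge = "none")))
  defs$undefined_stereo_mixtures <- .fx(
    mx$atoms, mx$bonds,
    expected = "undefined_stereo_mixtures",
    description = "two bare stereocenters")

  defs$relative_stereo <- .fx(
    list(.A("C", 0, 0), .A("F", 1, 0), .A("Cl", -0.5, 0.87),
         .A("Br", -0.5, -0.87)),
    list(.B(1, 2, wedge = "up"), .B(1, 3), .B(1, 4)),
    chiral = FALSE,
    expected = "relative_stereo",
    description = "wedged stereocenter without the chiral flag")

  defs$unknown_double_bond_stereo <- .fx(
    list(.A("C", 0, 0.5), .A("C", 1, 0), .A("C", 2, 0.5), .A("C", 3, 0)),
    list(.B(1, 2), .B(2, 3, "double", wedge = "cross_double"), .B(3, 4)),
    expected = "unknown_double_bond_stereo",
    description = "2-butene with a crossed double bond")

  hx <- .hexagon()
  ring_atoms <- lapply(seq_len(6), function(i) .A("C", hx[i, 1], hx[i, 2]))
  defs$stereobond_in_ring <- .fx(
    c(ring_atoms,
      list(.A("Cl", 0, 2),                        # on C1 (top)
           .A("C", 1.74, 1.5), .A("C", 2.6, 0.5))), # gem-dimethyl on C2
    c(lapply(seq_len(6), function(i) {
        .B(i, (i %% 6) + 1,
           wedge = if (i == 1) "up" else "none")   # ring bond C1-C2 wedged
      }),
      list(.B(1, 7), .B(2, 8), .B(2, 9))),
    expected = "stereobond_in_ring",
    description = "1-chloro-2,2-dimethylcyclohexane with a wedged ring bond")

  defs$contains_3d <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0, z = 0.5)),
    list(.B(1, 2), .B(2, 3)),
    expected = "contains_3d",
    description = "ethanol with one non-zero z coordinate")

  defs$fragment_small_molecule <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0), .A("O", 1, 1.5),
         .A("O", 5, 0)),
    list(.B(1, 2), .B(2, 3), .B(2, 4, "double")),
    expected = "fragment_small_molecule",
    description = "acetic acid plus a lone water fragment")

  defs$multiple_radicals <- .fx(
    list(.A("C", 0, 0, radical = 1L), .A("C", 1, 0, radical = 1L)),
    list(.B(1, 2)),
    expected = "multiple_radicals",
    description = "1,2-ethanediyl biradical")

  defs$net_charge_nonzero <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0.5), .A("O", 2, 0, charge = -1L),
         .A("O", 1, 1.5)),
    list(.B(1, 2), .B(2, 3), .B(2, 4, "double")),
    expected = "net_charge_nonzero",
    description = "acetate anion")

  defs$adjacent_like_charges <- .fx(
    list(.A("N", 0, 0, charge = 1L), .A("N", 1, 0, charge = 1L)),
    list(.B(1, 2)),
    expected = c("adjacent_like_charges", "net_charge_nonzero"),
    description = "hydrazinium dication")

  defs$metal_nonmetal_bond <- .fx(
    list(.A("Na", 0, 0), .A("Cl", 1, 0)),
    list(.B(1, 2)),
    expected = "metal_nonmetal_bond",
    description = "sodium chloride drawn covalent")

  defs$metal_nitrogen_bond <- .fx(
    list(.A("Na", 0, 0), .A("N", 1, 0)),
    list(.B(1, 2)),
    expected = c("metal_nitrogen_bond", "metal_nonmetal_bond"),
    description = "sodium amide drawn covalent")

  defs$metal_oxygen_bond <- .fx(
    list(.A("Na", 0, 0), .A("O", 1, 0)),
    list(.B(1, 2)),
    expected = c("metal_oxygen_bond", "metal_nonmetal_bond"),
    description = "sodium hydroxide drawn covalent")

  defs$contains_enol <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0), .A("O", 1.5, 0.87),
         .A("C", 1.5, -0.87)),
    list(.B(1, 2, "double"), .B(2, 3), .B(2, 4)),
    expected = "contains_enol",
    description = "propen-2-ol")

  tet <- cbind(x = cos((90 - 72 * (0:4)) * pi / 180),
               y = sin((90 - 72 * (0:4)) * pi / 180))
  defs$non_1h_tetrazole <- .fx(
    c(lapply(seq_len(5), function(i)
        .A(c("C", "N", "N", "N", "N")[i], tet[i, 1], tet[i, 2])),
      list(.A("C", 0, 2))),
    list(.B(1, 2, "double"), .B(2, 3), .B(3, 4), .B(4, 5, "double"),
         .B(5, 1), .B(1, 6)),
    expected = "non_1h_tetrazole",
    description = "5-methyl-2H-tetrazole (ring H on N2, not N1)")

  defs$iminol_tautomer <- .fx(
    list(.A("C", 0, 0), .A("C", 1, 0), .A("O", 1.5, 0.87),
         .A("N", 1.5, -0.87)),
    list(.B(1, 2), .B(2, 3), .B(2, 4, "double")),
    expected = "iminol_tautomer",
    description = "acetamide drawn as its iminol tautomer N=C-OH")

  defs$azide_drawn_hypervalent <- .fx(
    list(.A("C", 0, 0), .A("N", 1, 0), .A("N", 2, 0), .A("N", 3, 0)),
    list(.B(1, 2), .B(2, 3, "double"), .B(3, 4, "triple")),
    expected = c("azide_drawn_hypervalent", "unusual_valence"),
    description = "methyl azide drawn as N#N=N")

  defs$free_carbon_monoxide <- .fx(
    list(.A("C", 0, 0, charge = -1L), .A("O", 1, 0, charge = 1L)),
    list(.B(1, 2, "triple")),
    expected = "free_carbon_monoxide",
    description = "carbon monoxide")

  # 4-hydroxybenzoic acid drawn with neutral COOH and ionized phenolate
  hb <- .hexagon()
  defs$strongest_acid_not_ionized_first <- .fx(
    c(lapply(seq_len(6), function(i) .A("C", hb[i, 1], hb[i, 2])),
      list(.A("C", 0, 2), .A("O", -0.87, 2.5), .A("O", 0.87, 2.5),
           .A("O", 0, -2, charge = -1L))),
    c(.benzene_bonds(),
      list(.B(1, 7), .B(7, 8, "double"), .B(7, 9), .B(4, 10))),
    expected = c("strongest_acid_not_ionized_first", "net_charge_nonzero"),
    description = "4-hydroxybenzoate drawn as neutral COOH plus phenolate")

  ch <- .chair_coords
  defs$perspective_ring_depiction <- .fx(
    lapply(seq_len(6), function(i)
      .A(c("O", "C", "C", "C", "C", "C")[i], ch[i, 1], ch[i, 2])),
    lapply(seq_len(6), function(i) .B(i, (i %% 6) + 1)),
    expected = "perspective_ring_depiction",
    description = "tetrahydropyran drawn as a chair")

  # Haworth template: flattened hexagon, long horizontal top/bottom edges,
  # vertical exocyclic oxygens
  hw <- cbind(x = c(0.0, 0.6, 2.0, 2.6, 2.0, 0.6),
              y = c(0.0, -0.45, -0.45, 0.0, 0.45, 0.45))
  defs$haworth_projection <- .fx(
    c(lapply(seq_len(6), function(i)
        .A(c("C", "C", "C", "O", "C", "C")[i], hw[i, 1], hw[i, 2])),
      list(.A("O", 0.6, -1.45), .A("O", 2.0, -1.45), .A("O", 0.6, 1.45))),
    c(lapply(seq_len(6), function(i) .B(i, (i %% 6) + 1)),
      list(.B(2, 7), .B(3, 8), .B(6, 9))),
    expected = c("haworth_projection", "undefined_stereo_mixtures"),
    description = "monosaccharide drawn as a Haworth projection")

  # L-pyranose: hexopyranose on a regular hexagon, CH2OH wedge at the
  # reference carbon with L-series geometry
  lp <- .hexagon()
  lp_syms <- c("O", "C", "C", "C", "C", "C") # ring O at top, C5 at index 6
  defs$contains_l_pyranose <- .fx(
    c(lapply(seq_len(6), function(i) .A(lp_syms[i], lp[i, 1], lp[i, 2])),
      list(.A("O", 1.74, 1.0),   # OH on C1 (atom 2)
           .A("O", 1.74, -1.0),  # OH on C2 (atom 3)
           .A("O", 0, -2),       # OH on C3 (atom 4)
           .A("O", -1.74, -1.0), # OH on C4 (atom 5)
           .A("C", -1.74, 1.0),  # C6 on C5 (atom 6)
           .A("O", -1.74, 2.0))),
    c(lapply(seq_len(6), function(i) .B(i, (i %% 6) + 1)),
      list(.B(2, 7), .B(3, 8), .B(4, 9), .B(5, 10),
           .B(6, 11, wedge = "down"), .B(11, 12))),
    expected = c("contains_l_pyranose",
                 "undefined_stereo_partial_mixtures"),
    description = "hexopyranose with L-series reference carbon")

  defs$smiles_mismatch <- .ethanol_fx(
    expected = "smiles_mismatch", fields = c(SMILES = "CCN"))
  defs$smiles_invalid <- .ethanol_fx(
    expected = "smiles_invalid", fields = c(SMILES = "C("))
  defs$inchi_mismatch <- .ethanol_fx(
    expected = "inchi_mismatch",
    fields = c(InChI = "InChI=1S/CH4O/c1-2/h2H,1H3"))
  defs$inchi_nonstandard <- .ethanol_fx(
    expected = "inchi_nonstandard",
    fields = c(InChI = "InChI=1/C2H6O/c1-2-3/h3H,2H2,1H3"))

  two_benzenes <- c(.benzene_atoms(), .benzene_atoms(dx = 4))
  defs$only_duplicate_molecules <- .fx(
    two_benzenes,
    c(.benzene_bonds(0), .benzene_bonds(6)),
    expected = c("duplicate_molecules", "only_duplicate_molecules"),
    description = "two benzene fragments")

  defs$duplicate_molecules <- .fx(
    c(two_benzenes,
      list(.A("C", 8, 0), .A("C", 9, 0.5), .A("O", 10, 0))),
    c(.benzene_bonds(0), .benzene_bonds(6),
      list(.B(13, 14), .B(14, 15))),
    expected = "duplicate_molecules",
    description = "two benzenes plus ethanol")

  defs
}

.render_fixture <- function(def, code, seed) {
  atoms <- def$atoms
  if (seed != 0L && nrow(atoms)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed + sum(utf8ToInt(code)))
    atoms$x <- atoms$x + stats::runif(nrow(atoms), -0.003, 0.003)
    atoms$y <- atoms$y + stats::runif(nrow(atoms), -0.003, 0.003)
  }
  rec <- new_molrec(atoms, def$bonds, chiral_flag = def$chiral,
                    name = code)
  write_molfile(rec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate one validation fixture
#'
#' Emits a minimal molfile whose validation yields the expected issue codes,
#' including `code` itself.  The seed only jitters coordinates benignly
#' (never enough to cross a geometric threshold).
#'
#' @param code a known issue code (see [issue_registry()]).
#' @param seed integer jitter seed; 0 = no jitter.
#' @return list with `code`, `molfile` (text), `expected` (character vector
#'   of codes), `sdf_fields` (named character or `NULL`), `description`.
#' @examples
#' fx <- make_fixture("contains_3d")
#' cat(fx$expected)
#' @export
make_fixture <- function(code, seed = 0L) {
  if (identical(code, "parse_error")) {
    return(list(code = code,
                molfile = "broken record\n\n\n  x bad counts line",
                expected = "parse_error", sdf_fields = NULL,
                description = "corrupt counts line"))
  }
  defs <- .fixture_definitions()
  def <- defs[[code]]
  if (is.null(def)) {
    stop("no fixture for code '", code, "'; known codes: ",
         paste(sort(c(names(defs), "parse_error")), collapse = ", "))
  }
  list(code = code,
       molfile = .render_fixture(def, code, as.integer(seed)),
       expected = def$expected,
       sdf_fields = def$fields,
       description = def$description)
}

#' The full fixture suite
#'
#' One fixture per issue code that a well-formed input can trigger
#' deliberately (all registry codes with `fixture = TRUE`).
#'
#' @param seed jitter seed passed to [make_fixture()].
#' @return named list of fixtures, one per code.
#' @export
fixture_suite <- function(seed = 0L) {
  codes <- issue_registry()
  codes <- codes$code[codes$fixture]
  out <- lapply(codes, make_fixture, seed = seed)
  names(out) <- codes
  out
}

#' Parse a fixture into a record, applying its mapped fields
#' @param fixture result of [make_fixture()].
#' @param source_index record number to stamp.
#' @return a `molrec` (a parse-failure stub for the corrupt fixture).
#' @export
fixture_record <- function(fixture, source_index = 1L) {
  rec <- tryCatch(
    parse_molfile(fixture$molfile, source_index = source_index),
    error = function(e) failed_molrec(conditionMessage(e), source_index))
  if (!is.null(fixture$sdf_fields)) {
    rec$sdf_fields <- fixture$sdf_fields
    for (fld in intersect(names(fixture$sdf_fields),
                          c("REGID", "SMILES", "InChI"))) {
      rec$mapped[[fld]] <- unname(fixture$sdf_fields[[fld]])
    }
  }
  rec
}
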