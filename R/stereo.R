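# Wedge/hash stereochemistry validation on 2D depictions.
#
# Potential tetrahedral stereocenters are found by symmetry-aware
# substituent-distinctness analysis: Morgan-style iterative refinement of
# atom equivalence classes, then a center is "potential" when its four
# substituents (implicit hydrogen included) fall in four different classes.
# Wedge geometry is then judged with plain 2D trigonometry; every angular
# threshold lives in chemcheck_options().

#' Atom symmetry classes by iterative refinement
#'
#' Starts from (element, charge, radical, degree, bond-order sum, implicit
#' hydrogens) and refines each class with the sorted multiset of
#' (bond order, neighbor class) until the partition stabilizes.  Atoms in
#' different classes are guaranteed non-equivalent; for the molecule sizes
#' this package validates the converse holds in practice and is
#' cross-checked against an independent perception in the test suite.
#'
#' @param record a `molrec`.
#' @return integer vector of class ids, one per atom.
#' @export
atom_symmetry_classes <- function(record) {
  n <- nrow(record$atoms)
  if (!n) return(integer())
  nb <- neighbor_list(record)
  h_imp <- implicit_h_counts(record)
  ord_num <- .bond_order_num(record$bonds$order)
  ord_num[is.na(ord_num)] <- 0.5
  bond_ord <- matrix(0, n, n)
  for (k in seq_len(nrow(record$bonds))) {
    b <- record$bonds$begin[k]; e <- record$bonds$end[k]
    bond_ord[b, e] <- ord_num[k]; bond_ord[e, b] <- ord_num[k]
  }
  key <- paste(record$atoms$symbol, record$atoms$charge,
               record$atoms$radical,
               vapply(nb, length, integer(1)),
               round(explicit_valence(record), 1), h_imp)
  cls <- as.integer(factor(key))
  repeat {
    new_key <- vapply(seq_len(n), function(i) {
      nbr <- nb[[i]]
      if (!length(nbr)) return(paste(cls[i], "|"))
      paste(cls[i], "|",
            paste(sort(paste0(bond_ord[i, nbr], ":", cls[nbr])),
                  collapse = ","))
    }, character(1))
    new_cls <- as.integer(factor(new_key))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }
  cls
}

# Candidate elements for tetrahedral stereocenters.
.stereo_elements <- c("C", "Si", "N", "P", "As", "Ge", "B")

.potential_centers <- function(record) {
  n <- nrow(record$atoms)
  if (!n || !nrow(record$bonds)) return(integer())
  cls <- atom_symmetry_classes(record)
  nb <- neighbor_list(record)
  h_imp <- implicit_h_counts(record)
  all_single <- vapply(seq_len(n), function(i) {
    rows <- record$bonds$begin == i | record$bonds$end == i
    all(record$bonds$order[rows] == "single")
  }, logical(1))
  out <- integer()
  for (i in seq_len(n)) {
    if (record$atoms$is_query[i]) next
    if (!record$atoms$symbol[i] %in% .stereo_elements) next
    d <- length(nb[[i]])
    if (!(d == 4L || (d == 3L && h_imp[i] == 1L))) next
    if (d + h_imp[i] != 4L) next
    if (!all_single[i]) next
    if (anyDuplicated(cls[nb[[i]]])) next
    out <- c(out, i)
  }
  out
}

.bond_angle_deg <- function(v1, v2) {
  cosv <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

# Directions (degrees, 0..360) of bonds at atom i.
.bond_directions <- function(record, i, bond_rows) {
  vapply(bond_rows, function(k) {
    other <- if (record$bonds$begin[k] == i) record$bonds$end[k]
             else record$bonds$begin[k]
    dx <- record$atoms$x[other] - record$atoms$x[i]
    dy <- record$atoms$y[other] - record$atoms$y[i]
    (atan2(dy, dx) * 180 / pi) %% 360
  }, numeric(1))
}

#' Validate wedge/hash bond geometry
#'
#' Runs the stereo-bond battery on a 2D record: wedges on non-stereocenters,
#' wedges pointing the wrong way, nonsensical directions (both ends
#' stereocenters), two like wedges in adjacent positions, an up and a down
#' wedge in near-opposite positions, stereo bonds at too small an angle, and
#' ambiguous implicit-hydrogen placement (stereocenter whose three explicit
#' bonds all lie in one half-plane).  3D records are skipped (they carry a
#' `contains_3d` flag instead).
#'
#' @param record a `molrec`.
#' @param config a [chemcheck_options()] list.
#' @return list of `chem_issue`.
#' @export
validate_wedges <- function(record, config = chemcheck_options()) {
  out <- list()
  wedge_rows <- which(record$bonds$wedge %in% c("up", "down"))
  if (!length(wedge_rows) || record$has_3d) return(out)
  pot <- .potential_centers(record)

  # per-bond direction sanity
  for (k in wedge_rows) {
    b <- record$bonds$begin[k]
    e <- record$bonds$end[k]
    pb <- b %in% pot
    pe <- e %in% pot
    if (pb && pe) {
      out <- c(out, list(issue("stereo_bond_direction_nonsense",
                               atoms = c(b, e), bonds = k)))
    } else if (!pb && pe) {
      out <- c(out, list(issue("wedge_points_at_stereocenter",
                               atoms = c(b, e), bonds = k)))
    } else if (!pb && !pe) {
      out <- c(out, list(issue("wedge_on_non_stereocenter",
                               atoms = b, bonds = k)))
    }
  }

  # per-center pair geometry
  for (ctr in pot) {
    rows <- wedge_rows[record$bonds$begin[wedge_rows] == ctr]
    if (length(rows) >= 2L) {
      dirs <- .bond_directions(record, ctr, rows)
      types <- record$bonds$wedge[rows]
      for (a in seq_along(rows)[-length(rows)]) {
        for (b in seq((a + 1), length(rows))) {
          ang <- abs(dirs[a] - dirs[b])
          ang <- min(ang, 360 - ang)
          if (ang < config$stereo_min_angle) {
            out <- c(out, list(issue("stereo_bond_angle_too_small",
                                     atoms = ctr, bonds = rows[c(a, b)],
                                     severity = config$angle_rule_severity)))
          }
          same <- types[a] == types[b]
          if (same && ang < config$stereo_opposite_angle) {
            out <- c(out, list(issue("two_same_wedges_at_center",
                                     atoms = ctr, bonds = rows[c(a, b)])))
          }
          if (!same && ang >= config$stereo_opposite_angle) {
            out <- c(out, list(issue("up_and_down_at_center",
                                     atoms = ctr, bonds = rows[c(a, b)])))
          }
        }
      }
    }
    # implicit-H ambiguity: three explicit bonds in one half-plane
    all_rows <- which(record$bonds$begin == ctr | record$bonds$end == ctr)
    if (length(all_rows) == 3L && length(rows) >= 1L) {
      dirs <- sort(.bond_directions(record, ctr, all_rows))
      gaps <- diff(c(dirs, dirs[1] + 360))
      if (max(gaps) > 180 + 1e-9) {
        out <- c(out, list(issue("implicit_h_near_stereocenter",
                                 atoms = ctr)))
      }
    }
  }
  out
}

#' Locate potential, defined and unknown-marked stereocenters
#'
#' A center is *potential* when its four substituents are in four distinct
#' symmetry classes; *defined* when at least one up/down wedge has its
#' narrow end at the center and the wedge geometry passes
#' [validate_wedges()] there; *marked unknown* when an either-type stereo
#' bond touches it.
#'
#' @param record a `molrec` (2D; for 3D records no centers are perceived).
#' @param config a [chemcheck_options()] list.
#' @return data frame with columns `atom`, `potential`, `defined`,
#'   `marked_unknown`.
#' @export
find_stereocenters <- function(record, config = chemcheck_options()) {
  empty <- data.frame(atom = integer(), potential = logical(),
                      defined = logical(), marked_unknown = logical())
  if (record$has_3d || !nrow(record$atoms)) return(empty)
  pot <- .potential_centers(record)
  if (!length(pot)) return(empty)
  geom_issues <- validate_wedges(record, config)
  error_atoms <- unique(unlist(lapply(
    geom_issues[vapply(geom_issues, function(i) i$severity == "Error",
                       logical(1))],
    function(i) i$atoms)))
  unknown_rows <- which(record$bonds$wedge == "either_sp3")
  unknown_atoms <- unique(c(record$bonds$begin[unknown_rows],
                            record$bonds$end[unknown_rows]))
  wedge_rows <- which(record$bonds$wedge %in% c("up", "down"))
  res <- data.frame(atom = pot, potential = TRUE, defined = FALSE,
                    marked_unknown = pot %in% unknown_atoms)
  for (j in seq_along(pot)) {
    ctr <- pot[j]
    has_wedge <- any(record$bonds$begin[wedge_rows] == ctr)
    res$defined[j] <- has_wedge && !(ctr %in% error_atoms) &&
      !res$marked_unknown[j]
  }
  res
}

#' Categorize undefined stereochemistry
#'
#' With `d` defined and `u` undefined-or-unknown potential centers:
#' `d>=1, u==1` epimers; `d>=1, u>=2` partially undefined mixtures;
#' `d==0, u==1` enantiomers; `d==0, u>=2` completely undefined mixtures;
#' `u==0` nothing.
#'
#' @param record a `molrec`.
#' @param config a [chemcheck_options()] list.
#' @return A single `chem_issue` (Information) or `NULL`.
#' @export
categorize_undefined_stereo <- function(record,
                                        config = chemcheck_options()) {
  centers <- find_stereocenters(record, config)
  if (!nrow(centers)) return(NULL)
  d <- sum(centers$defined)
  u <- sum(!centers$defined)
  if (u == 0L) return(NULL)
  code <- if (d >= 1L && u == 1L) "undefined_stereo_epimers"
          else if (d >= 1L) "undefined_stereo_partial_mixtures"
          else if (u == 1L) "undefined_stereo_enantiomers"
          else "undefined_stereo_mixtures"
  issue(code, atoms = centers$atom[!centers$defined])
}

#' Bond-in-ring flags
#'
#' A bond lies in a ring iff its endpoints stay connected after the bond is
#' removed.
#' @keywords internal
bonds_in_ring <- function(record) {
  nb_all <- neighbor_list(record)
  vapply(seq_len(nrow(record$bonds)), function(k) {
    b <- record$bonds$begin[k]; e <- record$bonds$end[k]
    # BFS from b to e avoiding bond k
    seen <- rep(FALSE, nrow(record$atoms))
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      rows <- which((record$bonds$begin == v | record$bonds$end == v))
      rows <- setdiff(rows, k)
      for (r in rows) {
        w <- if (record$bonds$begin[r] == v) record$bonds$end[r]
             else record$bonds$begin[r]
        if (w == e) return(TRUE)
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Relative-stereo, cross-bond, ring-stereo-bond and 3D flags
#'
#' @param record a `molrec`.
#' @param config a [chemcheck_options()] list.
#' @return list of `chem_issue`: Warning `relative_stereo` (wedges present
#'   but no chiral flag), Information `unknown_double_bond_stereo` (crossed
#'   double bond), Information `stereobond_in_ring`, Information
#'   `contains_3d`.
#' @export
check_relative_and_cross <- function(record, config = chemcheck_options()) {
  out <- list()
  wedge_rows <- which(record$bonds$wedge %in% c("up", "down"))
  if (length(wedge_rows) && !record$chiral_flag) {
    out <- c(out, list(issue("relative_stereo", bonds = wedge_rows)))
  }
  cross <- which(record$bonds$wedge == "cross_double")
  if (length(cross)) {
    out <- c(out, list(issue("unknown_double_bond_stereo", bonds = cross,
                             atoms = unique(c(record$bonds$begin[cross],
                                              record$bonds$end[cross])))))
  }
  stereo_rows <- which(record$bonds$wedge %in%
                         c("up", "down", "either_sp3"))
  if (length(stereo_rows)) {
    in_ring <- bonds_in_ring(record)
    ring_stereo <- stereo_rows[in_ring[stereo_rows]]
    if (length(ring_stereo)) {
      out <- c(out, list(issue("stereobond_in_ring", bonds = ring_stereo)))
    }
  }
  if (record$has_3d) {
    out <- c(out, list(issue("contains_3d")))
  }
  out
}
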