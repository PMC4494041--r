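# Ring-walking turn signatures for six-membered rings.  Walking the 2D
# depiction of a hexagon and recording a left (L) or right (R) turn at every
# node gives a six-character signature; signatures equivalent under cyclic
# rotation (choice of start node) and letterwise complement (walk direction
# or mirroring) form eight shape classes, some with common names (chair,
# boat, twist-boat, half-chair, homotropous).  Perspective (non-convex)
# pyranose depictions defeat identifier algorithms that expect flat rings,
# and a mirrored ring silently turns a D-sugar into its L-enantiomer.

.ringshape_state <- new.env(parent = emptyenv())

.rotate_string <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

.complement_string <- function(s) {
  chartr("LR", "RL", s)
}

.orbit_of <- function(s) {
  out <- character()
  for (k in 0:(nchar(s) - 1)) {
    r <- .rotate_string(s, k)
    out <- c(out, r, .complement_string(r))
  }
  sort(unique(out))
}

# shape-class representatives; every six-character L/R string falls in the
# orbit of exactly one of these under rotation + complement
.shape_reps <- c(
  chair = "LRRLRR",
  boat = "LRLLRR",
  twist_boat = "LLLRRR",
  half_chair = "LRRRRR",
  homotropous = "LLLLLL",
  unnamed_LRLRLR = "LRLRLR",
  unnamed_LRLRRR = "LRLRRR",
  unnamed_LLLLRR = "LLLLRR"
)

.shape_table <- function() {
  if (!is.null(.ringshape_state$table)) return(.ringshape_state$table)
  tab <- character()
  for (nm in names(.shape_reps)) {
    orbit <- .orbit_of(.shape_reps[[nm]])
    tab[orbit] <- nm
  }
  stopifnot(length(tab) == 64L)
  .ringshape_state$table <- tab
  tab
}

#' Turn signature of a hexagon walk
#'
#' The turn at node i is the sign of the planar cross product of the edges
#' (i-1 -> i) and (i -> i+1): positive = left (L), negative = right (R).  A
#' cross product within `tol` (relative to the edge lengths) of zero means
#' three near-collinear nodes: the depiction is degenerate and the signature
#' undefined (`NA`).
#'
#' @param coords 6x2 numeric matrix of ring-node coordinates in walk order.
#' @param tol relative collinearity tolerance.
#' @return A six-character string over L/R, or `NA_character_`.
#' @examples
#' hexagon <- cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6))
#' ring_signature(hexagon)
#' @export
ring_signature <- function(coords, tol = 1e-3) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 6L, ncol(coords) >= 2L)
  turns <- character(6)
  for (i in seq_len(6)) {
    p_prev <- coords[(i - 2) %% 6 + 1, 1:2]
    p_cur <- coords[i, 1:2]
    p_next <- coords[i %% 6 + 1, 1:2]
    u <- p_cur - p_prev
    v <- p_next - p_cur
    lu <- sqrt(sum(u^2))
    lv <- sqrt(sum(v^2))
    if (lu == 0 || lv == 0) return(NA_character_)
    cross <- u[1] * v[2] - u[2] * v[1]
    if (abs(cross) <= tol * lu * lv) return(NA_character_)
    turns[i] <- if (cross > 0) "L" else "R"
  }
  paste(turns, collapse = "")
}

#' Canonical shape class of a turn signature
#'
#' Two signatures are equivalent when one is a cyclic rotation and/or the
#' letterwise L/R complement of the other; the 64 possible signatures fall
#' into eight classes.
#'
#' @param turns six-character string over L/R.
#' @return shape name, one of `"chair"`, `"boat"`, `"twist_boat"`,
#'   `"half_chair"`, `"homotropous"`, `"unnamed_LRLRLR"`,
#'   `"unnamed_LRLRRR"`, `"unnamed_LLLLRR"` (the three classes the
#'   published shape table leaves unnamed, labelled by their
#'   lexicographically smallest members).
#' @examples
#' canonical_shape("LRRLRR")
#' @export
canonical_shape <- function(turns) {
  if (!is.character(turns) || length(turns) != 1L || nchar(turns) != 6L ||
      grepl("[^LR]", turns)) {
    stop("turns must be a six-character string over {L, R}")
  }
  unname(.shape_table()[[turns]])
}

#' Enumerate all hexagon shape classes
#'
#' Brute force over the 64 possible L/R signatures, grouped under the
#' rotation + complement equivalence.
#'
#' @return list with `count`, `representatives` (named character vector,
#'   one per class) and `classes` (named character vector over all 64
#'   strings).
#' @export
enumerate_shape_classes <- function() {
  strings <- apply(expand.grid(rep(list(c("L", "R")), 6)), 1, paste,
                   collapse = "")
  strings <- sort(strings)
  assigned <- character()
  reps <- character()
  for (s in strings) {
    if (s %in% names(assigned)) next
    orbit <- .orbit_of(s)
    rep_name <- canonical_shape(s)
    reps[rep_name] <- min(orbit)
    assigned[orbit] <- rep_name
  }
  list(count = length(reps), representatives = reps, classes = assigned)
}

# ---- ring perception -------------------------------------------------------

# All simple cycles of length 3..max_len, as lists of atom indices in walk
# order.  Each cycle is reported once (minimal start vertex, fixed
# direction).
.simple_cycles <- function(record, max_len = 8L) {
  nb <- neighbor_list(record)
  n <- nrow(record$atoms)
  cycles <- list()
  path <- integer()
  dfs <- function(start, v) {
    path[[length(path) + 1L]] <<- v
    for (w in nb[[v]]) {
      if (w == start && length(path) >= 3L) {
        if (path[2] < path[length(path)]) { # one direction only
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (w > start && !(w %in% path) && length(path) < max_len) {
        dfs(start, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s, s)
  cycles
}

.cycle_bonds <- function(record, cycle) {
  vapply(seq_along(cycle), function(i) {
    a <- cycle[i]
    b <- cycle[i %% length(cycle) + 1]
    which((record$bonds$begin == a & record$bonds$end == b) |
            (record$bonds$begin == b & record$bonds$end == a))[1]
  }, integer(1))
}

#' Unfused six-membered rings of a record
#'
#' A six-ring is unfused when none of its bonds belongs to any other ring
#' (cycles up to length 8 are considered).
#' @keywords internal
unfused_six_rings <- function(record) {
  cycles <- .simple_cycles(record)
  lens <- vapply(cycles, length, integer(1))
  six <- cycles[lens == 6L]
  if (!length(six)) return(list())
  bond_sets <- lapply(cycles, .cycle_bonds, record = record)
  six_idx <- which(lens == 6L)
  keep <- vapply(seq_along(six_idx), function(j) {
    mine <- bond_sets[[six_idx[j]]]
    others <- unlist(bond_sets[-six_idx[j]])
    !any(mine %in% others)
  }, logical(1))
  six[keep]
}

.is_pyranose_candidate <- function(record, ring) {
  syms <- record$atoms$symbol[ring]
  sum(syms == "O") == 1L && sum(syms == "C") == 5L
}

#' Classify the unfused six-membered rings of a record
#'
#' Each unfused six-ring gets its turn signature (when defined) and shape
#' class.  A non-homotropous (non-convex) pyranose-candidate ring — exactly
#' one ring oxygen — is flagged `perspective_ring_depiction`: chair/boat
#' "perspective" drawings are what identifier algorithms cannot cope with.
#' A homotropous pyranose-candidate hexagon with two long near-horizontal
#' edges and at least two near-vertical exocyclic bonds is flagged as a
#' Haworth projection.
#'
#' @param record a `molrec` (2D).
#' @param config a [chemcheck_options()] list.
#' @return list with `rings` (data frame: `turns`, `shape`, plus list
#'   column `atoms`) and `issues`.
#' @export
classify_rings <- function(record, config = chemcheck_options()) {
  rings <- unfused_six_rings(record)
  if (!length(rings) || record$has_3d) {
    out <- data.frame(turns = character(), shape = character(),
                      stringsAsFactors = FALSE)
    out$atoms <- list()
    return(list(rings = out, issues = list()))
  }
  all_turns <- character(length(rings))
  all_shapes <- character(length(rings))
  issues <- list()
  for (j in seq_along(rings)) {
    ring <- rings[[j]]
    coords <- cbind(record$atoms$x[ring], record$atoms$y[ring])
    turns <- ring_signature(coords, tol = config$collinear_tol)
    shape <- if (is.na(turns)) NA_character_ else canonical_shape(turns)
    all_turns[j] <- turns
    all_shapes[j] <- shape
    if (!.is_pyranose_candidate(record, ring) || is.na(turns)) next
    if (shape != "homotropous") {
      issues <- c(issues, list(issue("perspective_ring_depiction",
                                     atoms = ring,
                                     note = paste("shape:", shape))))
    } else if (.looks_like_haworth(record, ring, config)) {
      issues <- c(issues, list(issue("haworth_projection", atoms = ring)))
    }
  }
  out <- data.frame(turns = all_turns, shape = all_shapes,
                    stringsAsFactors = FALSE)
  out$atoms <- rings
  list(rings = out, issues = issues)
}

.looks_like_haworth <- function(record, ring, config) {
  coords <- cbind(record$atoms$x[ring], record$atoms$y[ring])
  nxt <- c(seq_along(ring)[-1], 1L)
  edges <- coords[nxt, , drop = FALSE] - coords
  lens <- sqrt(rowSums(edges^2))
  if (any(lens == 0)) return(FALSE)
  angles <- abs(atan2(edges[, 2], edges[, 1]) * 180 / pi)
  to_horizontal <- pmin(angles, abs(180 - angles))
  long <- lens >= config$haworth_edge_ratio * min(lens)
  if (sum(long & to_horizontal <= config$haworth_axis_angle) < 2L) {
    return(FALSE)
  }
  # near-vertical exocyclic bonds from ring atoms
  n_vert <- 0L
  for (i in seq_along(ring)) {
    a <- ring[i]
    rows <- which(record$bonds$begin == a | record$bonds$end == a)
    for (k in rows) {
      other <- if (record$bonds$begin[k] == a) record$bonds$end[k]
               else record$bonds$begin[k]
      if (other %in% ring) next
      dx <- record$atoms$x[other] - record$atoms$x[a]
      dy <- record$atoms$y[other] - record$atoms$y[a]
      ang <- abs(atan2(dy, dx) * 180 / pi)
      to_vertical <- abs(90 - ang)
      if (to_vertical <= config$haworth_axis_angle) n_vert <- n_vert + 1L
    }
  }
  n_vert >= 2L
}

#' Detect an L-series pyranose depiction
#'
#' For each pyranose candidate (unfused six-ring with one ring oxygen and at
#' least three exocyclic oxygens on ring carbons) the configuration
#' reference carbon is the ring carbon adjacent to the ring oxygen that
#' bears an exocyclic carbon substituent (C5 of an aldohexopyranose).  Its
#' configuration is read from the wedge geometry with the fixed priority
#' order ring-O > ring-C > exocyclic-C > implicit-H; the sense
#' corresponding to the L series (S at the reference carbon for common
#' sugars) — usually the result of an inadvertently mirrored ring — is
#' flagged.  Rings whose reference carbon carries no interpretable wedge are
#' not flagged.
#'
#' @param record a `molrec` (2D).
#' @param config a [chemcheck_options()] list.
#' @return A single Information `chem_issue` or `NULL`.
#' @export
detect_l_pyranose <- function(record, config = chemcheck_options()) {
  if (record$has_3d) return(NULL)
  rings <- unfused_six_rings(record)
  nb <- neighbor_list(record)
  for (ring in rings) {
    if (!.is_pyranose_candidate(record, ring)) next
    ring_c <- ring[record$atoms$symbol[ring] == "C"]
    exo_o <- sum(vapply(ring_c, function(a) {
      any(record$atoms$symbol[setdiff(nb[[a]], ring)] == "O")
    }, logical(1)))
    if (exo_o < 3L) next
    ring_o <- ring[record$atoms$symbol[ring] == "O"]
    ref_candidates <- intersect(nb[[ring_o]], ring_c)
    for (ref in ref_candidates) {
      exo_c <- setdiff(nb[[ref]], ring)
      exo_c <- exo_c[record$atoms$symbol[exo_c] == "C"]
      if (!length(exo_c)) next
      sign <- .reference_carbon_parity(record, ref, ring_o,
                                       setdiff(intersect(nb[[ref]], ring),
                                               ring_o)[1],
                                       exo_c[1])
      if (is.na(sign)) next
      # det < 0 = R (D series) with this priority order; det > 0 = L
      if (sign > 0) {
        return(issue("contains_l_pyranose", atoms = c(ref, ring)))
      }
    }
  }
  NULL
}

# Signed volume of the priority-ordered substituent frame at a ring
# reference carbon: rows (v_O - v_H, v_ringC - v_H, v_exoC - v_H) where z
# heights come from wedge bonds with their narrow end at the carbon and the
# implicit hydrogen sits opposite the explicit substituents.  Negative = R.
.reference_carbon_parity <- function(record, ref, o_atom, ringc, exoc) {
  others <- c(o_atom, ringc, exoc)
  if (anyNA(others)) return(NA_real_)
  zs <- numeric(3)
  has_wedge <- FALSE
  for (j in seq_along(others)) {
    k <- which(record$bonds$begin == ref & record$bonds$end == others[j] &
                 record$bonds$wedge %in% c("up", "down"))
    if (length(k)) {
      has_wedge <- TRUE
      zs[j] <- if (record$bonds$wedge[k[1]] == "up") 1 else -1
    }
  }
  if (!has_wedge) return(NA_real_)
  vecs <- lapply(seq_along(others), function(j) {
    c(record$atoms$x[others[j]] - record$atoms$x[ref],
      record$atoms$y[others[j]] - record$atoms$y[ref],
      zs[j])
  })
  # normalize in-plane scale so the wedge z height is commensurate
  scale <- mean(vapply(vecs, function(v) sqrt(sum(v[1:2]^2)), numeric(1)))
  if (scale == 0) return(NA_real_)
  vecs <- lapply(vecs, function(v) c(v[1:2] / scale, v[3]))
  v_h <- -Reduce(`+`, vecs)
  m <- rbind(vecs[[1]] - v_h, vecs[[2]] - v_h, vecs[[3]] - v_h)
  d <- det(m)
  if (abs(d) < 1e-9) return(NA_real_)
  d
}
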