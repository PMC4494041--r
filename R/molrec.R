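# The MoleculeRecord container ("molrec"): one parsed connection-table
# record plus its SDF data fields.  Deliberately a plain list of base-R
# data frames so that invalid chemistry survives parsing untouched.

#' Construct a molecule record
#'
#' Low-level constructor used by the parsers and the fixture generator.
#' Atom indices are 1-based throughout, matching molfile numbering.
#'
#' @param atoms data frame with columns `symbol`, `x`, `y`, `z`, and
#'   optionally `charge`, `radical`, `isotope`, `valence_override`.
#' @param bonds data frame with columns `begin`, `end`, `order`
#'   (one of "single", "double", "triple", "aromatic", "query") and
#'   optionally `wedge` (one of "none", "up", "down", "either_sp3",
#'   "cross_double").
#' @param chiral_flag logical; the molfile counts-line chiral flag.
#' @param sdf_fields named character vector of SDF data fields.
#' @param mapped named list with any of `REGID`, `SMILES`, `InChI`.
#' @param source_index integer position of the record in its input file.
#' @param name molfile header name line.
#' @param z_3d_threshold |z| above which the record counts as 3D.
#' @return An object of class `molrec`.
#' @export
new_molrec <- function(atoms, bonds, chiral_flag = FALSE,
                       sdf_fields = character(), mapped = list(),
                       source_index = 1L, name = "",
                       z_3d_threshold = 1e-4) {
  n <- nrow(atoms)
  atoms$index <- seq_len(n)
  for (col in c("charge", "radical", "isotope")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(0L, n)
  }
  if (is.null(atoms$valence_override)) {
    atoms$valence_override <- rep(NA_integer_, n)
  }
  if (is.null(atoms$z)) atoms$z <- rep(0, n)
  atoms$is_query <- is_query_symbol(atoms$symbol)
  if (is.null(bonds$wedge)) bonds$wedge <- rep("none", nrow(bonds))
  if (nrow(bonds)) {
    if (any(bonds$begin == bonds$end)) {
      stop("bond with identical endpoints")
    }
    if (any(bonds$begin < 1 | bonds$begin > n | bonds$end < 1 |
            bonds$end > n)) {
      stop("bond endpoint references a non-existent atom")
    }
  }
  structure(
    list(
      atoms = atoms[, c("index", "symbol", "charge", "radical", "isotope",
                        "x", "y", "z", "valence_override", "is_query")],
      bonds = bonds[, c("begin", "end", "order", "wedge"), drop = FALSE],
      chiral_flag = isTRUE(chiral_flag),
      sdf_fields = sdf_fields,
      mapped = mapped,
      source_index = as.integer(source_index),
      name = name,
      has_3d = any(abs(atoms$z) > z_3d_threshold),
      parse_error = NULL,
      kekule = NULL
    ),
    class = "molrec"
  )
}

#' Stub record standing in for an unparsable SDF entry
#' @param message parse failure message.
#' @param source_index record position in the input stream.
#' @keywords internal
failed_molrec <- function(message, source_index = 1L) {
  rec <- new_molrec(
    atoms = data.frame(symbol = character(), x = numeric(), y = numeric(),
                       z = numeric(), stringsAsFactors = FALSE),
    bonds = data.frame(begin = integer(), end = integer(),
                       order = character(), wedge = character(),
                       stringsAsFactors = FALSE),
    source_index = source_index
  )
  rec$parse_error <- message
  rec
}

#' @export
print.molrec <- function(x, ...) {
  if (!is.null(x$parse_error)) {
    cat("<molrec> record", x$source_index, "FAILED TO PARSE:",
        x$parse_error, "\n")
    return(invisible(x))
  }
  cat(sprintf("<molrec> %d atoms, %d bonds%s%s%s\n",
              nrow(x$atoms), nrow(x$bonds),
              if (x$chiral_flag) ", chiral flag" else "",
              if (x$has_3d) ", 3D" else "",
              if (length(x$sdf_fields))
                sprintf(", %d SDF fields", length(x$sdf_fields)) else ""))
  invisible(x)
}

# ---- graph helpers ---------------------------------------------------------

#' Neighbor atom indices of each atom
#' @return list indexed by atom of integer vectors.
#' @keywords internal
neighbor_list <- function(record) {
  n <- nrow(record$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(record$bonds))) {
    b <- record$bonds$begin[k]
    e <- record$bonds$end[k]
    nb[[b]] <- c(nb[[b]], e)
    nb[[e]] <- c(nb[[e]], b)
  }
  nb
}

#' Connected components (fragments) of a record
#' @return integer vector: fragment id per atom.
#' @keywords internal
fragment_ids <- function(record) {
  n <- nrow(record$atoms)
  nb <- neighbor_list(record)
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in nb[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Extract one fragment as a standalone record
#' @keywords internal
subset_record <- function(record, atom_idx) {
  atom_idx <- sort(atom_idx)
  remap <- match(seq_len(nrow(record$atoms)), atom_idx)
  keep_bond <- record$bonds$begin %in% atom_idx &
    record$bonds$end %in% atom_idx
  bonds <- record$bonds[keep_bond, , drop = FALSE]
  bonds$begin <- remap[bonds$begin]
  bonds$end <- remap[bonds$end]
  atoms <- record$atoms[atom_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  new_molrec(atoms, bonds, chiral_flag = record$chiral_flag,
             source_index = record$source_index, name = record$name)
}

# Numeric bond order; aromatic counts 1.5, query NA.
.bond_order_num <- function(order) {
  unname(c(single = 1, double = 2, triple = 3, aromatic = 1.5,
           query = NA_real_)[order])
}

#' Sum of explicit bond orders at each atom
#'
#' Aromatic bonds count 1.5 each (so a benzene carbon sums to 4 together
#' with the kekulized interpretation); query bonds make the sum NA.
#' @keywords internal
explicit_valence <- function(record) {
  n <- nrow(record$atoms)
  v <- rep(0, n)
  ord <- .bond_order_num(record$bonds$order)
  for (k in seq_len(nrow(record$bonds))) {
    v[record$bonds$begin[k]] <- v[record$bonds$begin[k]] + ord[k]
    v[record$bonds$end[k]] <- v[record$bonds$end[k]] + ord[k]
  }
  v
}

#' Implicit hydrogen count per atom under the valence model
#'
#' Fills each atom up to the smallest *common* valence for its element and
#' charge that accommodates the drawn bonds plus unpaired electrons; atoms
#' that exceed every common valence get no implicit hydrogens (the MDL
#' convention).  A molfile valence override wins outright.
#' @keywords internal
implicit_h_counts <- function(record, model = default_valence_model()) {
  used <- explicit_valence(record) + record$atoms$radical
  n <- nrow(record$atoms)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (record$atoms$is_query[i] || is.na(used[i])) {
      out[i] <- 0L
      next
    }
    ov <- record$atoms$valence_override[i]
    if (!is.na(ov)) {
      out[i] <- max(0L, as.integer(ov - used[i]))
      next
    }
    allowed <- valence_sets(model, record$atoms$symbol[i],
                            record$atoms$charge[i])
    common <- allowed$common[allowed$common >= used[i]]
    out[i] <- if (length(common)) as.integer(min(common) - used[i]) else 0L
  }
  out
}

#' Net formal charge of a record
#' @param record a `molrec`.
#' @return integer net charge.
#' @export
net_charge <- function(record) {
  sum(record$atoms$charge)
}

#' Molecular formula (Hill order) including implicit hydrogens
#'
#' Used by the reprotonation conservation checks.
#' @param record a `molrec`.
#' @return a single string, e.g. `"C2H6O"`.
#' @export
molecular_formula <- function(record) {
  h_imp <- implicit_h_counts(record)
  syms <- record$atoms$symbol
  counts <- table(syms)
  n_h <- sum(h_imp) + if ("H" %in% names(counts)) counts[["H"]] else 0
  counts <- counts[names(counts) != "H"]
  carbon <- counts[names(counts) == "C"]
  rest <- counts[names(counts) != "C"]
  rest <- rest[order(names(rest))]
  piece <- function(sym, k) {
    if (k == 0) "" else if (k == 1) sym else paste0(sym, k)
  }
  parts <- character()
  if (length(carbon)) parts <- c(parts, piece("C", carbon[[1]]))
  if (n_h > 0) parts <- c(parts, piece("H", n_h))
  for (s in names(rest)) parts <- c(parts, piece(s, rest[[s]]))
  paste(parts, collapse = "")
}
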