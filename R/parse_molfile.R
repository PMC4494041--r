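# V2000 molfile reading and writing.  The parser keeps whatever it is given:
# query atoms, impossible valences, stray wedges and hypervalent nitrogens
# all pass through so the validation battery can see them.  Only structural
# corruption (bad counts line, truncated blocks) raises a parse error.

.molfile_charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                           `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# M RAD codes: 1 = singlet (two paired non-bonding electrons),
# 2 = doublet (one unpaired), 3 = triplet (two unpaired).  Stored as the
# number of electrons withheld from bonding/implicit-H filling.
.molfile_radical_codes <- c(`1` = 2L, `2` = 1L, `3` = 2L)

.parse_stop <- function(line_no, msg) {
  stop(structure(
    class = c("chemcheck_parse_error", "error", "condition"),
    list(message = sprintf("molfile line %d: %s", line_no, msg),
         call = NULL, line = line_no)
  ))
}

.int_field <- function(s) {
  s <- trimws(s)
  if (s == "" || is.na(s)) return(0L)
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) NA_integer_ else v
}

#' Parse a V2000 molfile block
#'
#' Reads the header, counts line, atom and bond blocks and the property
#' block ("M  CHG", "M  RAD", "M  ISO"; property lines supersede the
#' atom-block charge/radical codes, per the V2000 rule that a single
#' `M  CHG`/`M  RAD` line resets all atom-block values of that kind).
#' Query atoms ("A", "*", "Q", ...) and query bond types (5-8) are flagged,
#' not rejected.  V3000 blocks are rejected with a clear error.
#'
#' @param text a single string or character vector of lines.
#' @param source_index record position, stored on the result.
#' @param z_3d_threshold |z| above which the record counts as 3D.
#' @return A [new_molrec()] object.
#' @examples
#' rec <- parse_molfile(make_fixture("contains_3d")$molfile)
#' rec$has_3d
#' @export
parse_molfile <- function(text, source_index = 1L, z_3d_threshold = 1e-4) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  if (length(lines) < 4L) .parse_stop(length(lines), "truncated molfile")
  name <- trimws(lines[1])
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE) ||
      any(startsWith(lines, "M  V30"))) {
    .parse_stop(4L, "V3000 connection tables are not supported (V2000 only)")
  }
  natoms <- .int_field(substr(counts, 1, 3))
  nbonds <- .int_field(substr(counts, 4, 6))
  chiral <- .int_field(substr(counts, 13, 15))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0) {
    .parse_stop(4L, "malformed counts line")
  }
  atom_rows <- lines[seq(5, length.out = natoms)]
  if (natoms > 0 && (length(lines) < 4 + natoms ||
                     anyNA(atom_rows) || any(nchar(atom_rows) < 32))) {
    .parse_stop(4 + natoms, "truncated atom block")
  }
  bond_start <- 5 + natoms
  bond_rows <- lines[seq(bond_start, length.out = nbonds)]
  if (nbonds > 0 && (length(lines) < 4 + natoms + nbonds ||
                     anyNA(bond_rows) || any(nchar(bond_rows) < 9))) {
    .parse_stop(4 + natoms + nbonds, "truncated bond block")
  }

  atoms <- data.frame(
    symbol = character(natoms), x = numeric(natoms), y = numeric(natoms),
    z = numeric(natoms), charge = integer(natoms),
    radical = integer(natoms), isotope = integer(natoms),
    valence_override = rep(NA_integer_, natoms),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(natoms)) {
    row <- atom_rows[i]
    xyz <- suppressWarnings(as.numeric(c(substr(row, 1, 10),
                                         substr(row, 11, 20),
                                         substr(row, 21, 30))))
    if (anyNA(xyz)) .parse_stop(4 + i, "unreadable atom coordinates")
    atoms$x[i] <- xyz[1]; atoms$y[i] <- xyz[2]; atoms$z[i] <- xyz[3]
    atoms$symbol[i] <- trimws(substr(row, 32, 34))
    if (atoms$symbol[i] == "") .parse_stop(4 + i, "missing atom symbol")
    chg_code <- .int_field(substr(row, 37, 39))
    if (!is.na(chg_code) && as.character(chg_code) %in%
        names(.molfile_charge_codes)) {
      atoms$charge[i] <- .molfile_charge_codes[[as.character(chg_code)]]
      if (chg_code == 4L) atoms$radical[i] <- 1L
    }
    val <- .int_field(substr(row, 49, 51))
    if (!is.na(val) && val > 0L) {
      atoms$valence_override[i] <- if (val == 15L) 0L else val
    }
  }

  bonds <- data.frame(
    begin = integer(nbonds), end = integer(nbonds),
    order = character(nbonds), wedge = character(nbonds),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nbonds)) {
    row <- bond_rows[k]
    b <- .int_field(substr(row, 1, 3))
    e <- .int_field(substr(row, 4, 6))
    ty <- .int_field(substr(row, 7, 9))
    st <- if (nchar(row) >= 12) .int_field(substr(row, 10, 12)) else 0L
    if (is.na(b) || is.na(e) || b < 1 || e < 1 || b > natoms || e > natoms) {
      .parse_stop(4 + natoms + k, "bond references a non-existent atom")
    }
    if (b == e) .parse_stop(4 + natoms + k, "bond with identical endpoints")
    order <- switch(as.character(ty), `1` = "single", `2` = "double",
                    `3` = "triple", `4` = "aromatic", "query")
    wedge <- "none"
    if (order == "single") {
      wedge <- switch(as.character(st), `1` = "up", `6` = "down",
                      `4` = "either_sp3", "none")
    } else if (order == "double" && !is.na(st) && st == 3L) {
      wedge <- "cross_double"
    }
    bonds$begin[k] <- b; bonds$end[k] <- e
    bonds$order[k] <- order; bonds$wedge[k] <- wedge
  }

  # property block: first M CHG / M RAD line encountered resets that kind
  prop_start <- 5 + natoms + nbonds
  prop_lines <- if (length(lines) >= prop_start)
    lines[prop_start:length(lines)] else character()
  seen_chg <- FALSE
  seen_rad <- FALSE
  for (row in prop_lines) {
    if (startsWith(row, "M  END")) break
    tag <- substr(row, 1, 6)
    if (!tag %in% c("M  CHG", "M  RAD", "M  ISO")) next
    toks <- suppressWarnings(
      as.integer(strsplit(trimws(substr(row, 7, nchar(row))), "\\s+")[[1]]))
    if (!length(toks) || anyNA(toks)) next
    nn <- toks[1]
    pairs <- toks[-1]
    if (length(pairs) < 2 * nn) next
    if (tag == "M  CHG" && !seen_chg) {
      atoms$charge[] <- 0L
      seen_chg <- TRUE
    }
    if (tag == "M  RAD" && !seen_rad) {
      atoms$radical[] <- 0L
      seen_rad <- TRUE
    }
    for (j in seq_len(nn)) {
      ai <- pairs[2 * j - 1]
      vv <- pairs[2 * j]
      if (ai < 1 || ai > natoms) next
      if (tag == "M  CHG") atoms$charge[ai] <- vv
      if (tag == "M  RAD") {
        atoms$radical[ai] <-
          if (as.character(vv) %in% names(.molfile_radical_codes))
            .molfile_radical_codes[[as.character(vv)]] else 0L
      }
      if (tag == "M  ISO") atoms$isotope[ai] <- vv
    }
  }

  new_molrec(atoms, bonds, chiral_flag = !is.na(chiral) && chiral == 1L,
             source_index = source_index, name = name,
             z_3d_threshold = z_3d_threshold)
}

#' Write one record as a V2000 molfile block
#'
#' The writer round-trips everything the parser reads: connection table,
#' wedges, charges (as "M  CHG"), radicals ("M  RAD"), isotopes ("M  ISO")
#' and the chiral flag.
#'
#' @param record a `molrec`.
#' @return A single string (no trailing "$$$$").
#' @export
write_molfile <- function(record) {
  a <- record$atoms
  b <- record$bonds
  counts <- sprintf("%3d%3d  0  0%3d  0  0  0  0  0999 V2000",
                    nrow(a), nrow(b), as.integer(record$chiral_flag))
  atom_lines <- vapply(seq_len(nrow(a)), function(i) {
    val <- a$valence_override[i]
    val_code <- if (is.na(val)) 0L else if (val == 0L) 15L else val
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0%3d  0  0  0  0  0  0",
            a$x[i], a$y[i], a$z[i], a$symbol[i], val_code)
  }, character(1))
  order_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L,
                  query = 8L)
  wedge_code <- c(none = 0L, up = 1L, down = 6L, either_sp3 = 4L,
                  cross_double = 3L)
  bond_lines <- vapply(seq_len(nrow(b)), function(k) {
    sprintf("%3d%3d%3d%3d", b$begin[k], b$end[k],
            order_code[[b$order[k]]], wedge_code[[b$wedge[k]]])
  }, character(1))
  prop <- character()
  emit_pairs <- function(tag, idx, val) {
    out <- character()
    while (length(idx)) {
      take <- seq_len(min(8L, length(idx)))
      out <- c(out, paste0(
        tag, sprintf("%3d", length(take)),
        paste0(sprintf(" %3d %3d", idx[take], val[take]), collapse = "")))
      idx <- idx[-take]; val <- val[-take]
    }
    out
  }
  chg <- which(a$charge != 0L)
  if (length(chg)) prop <- c(prop, emit_pairs("M  CHG", chg, a$charge[chg]))
  rad <- which(a$radical != 0L)
  if (length(rad)) {
    code <- ifelse(a$radical[rad] == 1L, 2L, 3L)
    prop <- c(prop, emit_pairs("M  RAD", rad, code))
  }
  iso <- which(a$isotope != 0L)
  if (length(iso)) prop <- c(prop, emit_pairs("M  ISO", iso, a$isotope[iso]))
  paste(c(record$name, "  chemcheck", "", counts, atom_lines, bond_lines,
          prop, "M  END"), collapse = "\n")
}
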