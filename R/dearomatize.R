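# Dearomatization checking: a record drawn with aromatic-type (4) bonds must
# admit exactly one hydrogen placement on its aromatic heteroatoms for the
# implicit hydrogens to be restorable.  The check enumerates hydrogen
# placements ("flexible" ring nitrogens can be pyridine-like, taking a ring
# double bond, or pyrrole-like, taking the hydrogen) and tests each for a
# perfect matching of ring double bonds over the atoms that need one.

# Perfect matching existence on an adjacency list restricted to `need`.
.has_perfect_matching <- function(adj, need) {
  need <- sort(need)
  rec <- function(remaining) {
    if (!length(remaining)) return(TRUE)
    v <- remaining[1]
    partners <- intersect(adj[[v]], remaining[-1])
    for (w in partners) {
      if (rec(setdiff(remaining, c(v, w)))) return(TRUE)
    }
    FALSE
  }
  if (length(need) %% 2L == 1L) return(FALSE)
  rec(need)
}

# One matching (list of atom pairs), or NULL.
.find_perfect_matching <- function(adj, need) {
  need <- sort(need)
  rec <- function(remaining) {
    if (!length(remaining)) return(list())
    v <- remaining[1]
    partners <- intersect(adj[[v]], remaining[-1])
    for (w in partners) {
      rest <- rec(setdiff(remaining, c(v, w)))
      if (!is.null(rest)) return(c(list(c(v, w)), rest))
    }
    NULL
  }
  rec(need)
}

#' Classify aromatic-subsystem atoms for hydrogen placement
#'
#' Returns, per aromatic atom: "matched" (must take a ring double bond),
#' "saturated" (cannot; contributes a lone pair or an existing H), or
#' "flexible" (a neutral ring nitrogen with no exocyclic substituent beyond
#' one single bond and no drawn H — it may play either role).
#' @keywords internal
.aromatic_roles <- function(record) {
  bonds <- record$bonds
  arom_rows <- which(bonds$order == "aromatic")
  atoms_in <- sort(unique(c(bonds$begin[arom_rows], bonds$end[arom_rows])))
  roles <- character(0)
  for (i in atoms_in) {
    sym <- record$atoms$symbol[i]
    chg <- record$atoms$charge[i]
    rows <- which(bonds$begin == i | bonds$end == i)
    exo <- rows[bonds$order[rows] != "aromatic"]
    exo_double <- any(bonds$order[exo] %in% c("double", "triple"))
    exo_h <- sum(record$atoms$symbol[
      ifelse(bonds$begin[exo] == i, bonds$end[exo], bonds$begin[exo])] == "H")
    n_arom <- length(rows) - length(exo)
    role <-
      if (sym %in% c("O", "S", "Se", "Te") && chg == 0) "saturated"
      else if (sym == "N" && chg == -1) "saturated"
      else if (sym == "N" && chg == 0) {
        if (exo_double) "matched"
        else if (length(exo) > 0 || exo_h > 0) "saturated" # N-R / N-H drawn
        else "flexible"
      }
      else if (sym == "N" && chg == 1) {
        if (length(exo) > 0 || exo_double) "matched" else "flexible"
      }
      else if (sym == "C" || sym == "B") {
        if (exo_double) "saturated" else "matched"
      }
      else "saturated"
    roles[[as.character(i)]] <- role
  }
  list(atoms = atoms_in, roles = roles, arom_rows = arom_rows)
}

#' Check that dearomatization is unique
#'
#' Enumerates all hydrogen placements on flexible aromatic nitrogens and all
#' ring double-bond assignments (perfect matchings).  Zero valid solutions
#' yields Error `dearomatization_failed`; two or more hydrogen-placement
#' classes yields Error `dearomatization_not_unique`.  A unique solution
#' annotates the record (`record$kekule`) with the kekulized bond orders so
#' the valence check can use them.  Enumeration is capped at
#' `config$dearomatization_cap` placements; hitting the cap reports the
#' ambiguity.
#'
#' @param record a `molrec`.
#' @param config a [chemcheck_options()] list.
#' @return list with `issues` (list of `chem_issue`) and `record` (possibly
#'   annotated).
#' @export
check_dearomatization <- function(record, config = chemcheck_options()) {
  info <- .aromatic_roles(record)
  if (!length(info$atoms)) return(list(issues = list(), record = record))
  bonds <- record$bonds
  adj <- lapply(seq_len(nrow(record$atoms)), function(i) integer())
  for (k in info$arom_rows) {
    b <- bonds$begin[k]; e <- bonds$end[k]
    adj[[b]] <- c(adj[[b]], e)
    adj[[e]] <- c(adj[[e]], b)
  }
  flex <- info$atoms[info$roles[as.character(info$atoms)] == "flexible"]
  fixed_need <- info$atoms[info$roles[as.character(info$atoms)] == "matched"]
  n_flex <- length(flex)
  cap <- config$dearomatization_cap
  if (2^n_flex > cap) {
    return(list(issues = list(issue(
      "dearomatization_not_unique", atoms = info$atoms,
      note = sprintf("more than %d hydrogen placements; enumeration capped",
                     cap))), record = record))
  }
  solutions <- list()
  for (mask in 0:(2^n_flex - 1)) {
    take_h <- if (n_flex) flex[bitwAnd(mask, 2^(seq_len(n_flex) - 1)) > 0]
              else integer()
    need <- sort(c(fixed_need, setdiff(flex, take_h)))
    if (.has_perfect_matching(adj, need)) {
      solutions[[length(solutions) + 1L]] <- take_h
    }
  }
  if (!length(solutions)) {
    return(list(issues = list(issue("dearomatization_failed",
                                    atoms = info$atoms)),
                record = record))
  }
  if (length(solutions) > 1L) {
    return(list(issues = list(issue(
      "dearomatization_not_unique", atoms = info$atoms,
      note = sprintf("%d hydrogen placements admit a kekulization",
                     length(solutions)))), record = record))
  }
  # unique: annotate kekulized orders for the valence check
  take_h <- solutions[[1]]
  need <- sort(c(fixed_need, setdiff(flex, take_h)))
  matching <- .find_perfect_matching(adj, need)
  kek <- rep(1, length(info$arom_rows))
  names(kek) <- as.character(info$arom_rows)
  for (pair in matching) {
    hit <- info$arom_rows[
      (bonds$begin[info$arom_rows] == pair[1] &
         bonds$end[info$arom_rows] == pair[2]) |
        (bonds$begin[info$arom_rows] == pair[2] &
           bonds$end[info$arom_rows] == pair[1])]
    kek[as.character(hit[1])] <- 2
  }
  record$kekule <- kek
  list(issues = list(), record = record)
}
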