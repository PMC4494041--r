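# Independent brute-force oracles shared by the dearomatization and
# acceptance tests.

# Oracle: count hydrogen-placement classes admitting a valid double-bond
# assignment, by exhaustive enumeration over subsets of aromatic edges.
brute_force_dearomatization <- function(record) {
  bonds <- record$bonds
  arom <- which(bonds$order == "aromatic")
  atoms_in <- sort(unique(c(bonds$begin[arom], bonds$end[arom])))
  if (!length(atoms_in)) return(1L)
  # role per aromatic atom (same chemistry, independent of the matching code)
  role_of <- function(i) {
    sym <- record$atoms$symbol[i]
    chg <- record$atoms$charge[i]
    rows <- which(bonds$begin == i | bonds$end == i)
    exo <- rows[bonds$order[rows] != "aromatic"]
    exo_double <- any(bonds$order[exo] %in% c("double", "triple"))
    if (sym %in% c("O", "S", "Se", "Te") && chg == 0) return("saturated")
    if (sym == "N" && chg == -1) return("saturated")
    if (sym == "N" && chg == 0) {
      if (exo_double) return("matched")
      if (length(exo) > 0) return("saturated")
      return("flexible")
    }
    if (sym == "N" && chg == 1) {
      if (length(exo) > 0 || exo_double) return("matched")
      return("flexible")
    }
    if (sym %in% c("C", "B")) {
      return(if (exo_double) "saturated" else "matched")
    }
    "saturated"
  }
  roles <- vapply(atoms_in, role_of, character(1))
  flex <- atoms_in[roles == "flexible"]
  fixed_need <- atoms_in[roles == "matched"]
  m <- length(arom)
  good_placements <- 0L
  for (mask_h in 0:(2^length(flex) - 1)) {
    take_h <- if (length(flex))
      flex[bitwAnd(mask_h, 2^(seq_along(flex) - 1)) > 0] else integer()
    need <- sort(c(fixed_need, setdiff(flex, take_h)))
    found <- FALSE
    for (mask_e in 0:(2^m - 1)) { # every subset of aromatic edges as doubles
      dbl <- arom[bitwAnd(mask_e, 2^(seq_len(m) - 1)) > 0]
      deg <- integer(nrow(record$atoms))
      for (k in dbl) {
        deg[bonds$begin[k]] <- deg[bonds$begin[k]] + 1L
        deg[bonds$end[k]] <- deg[bonds$end[k]] + 1L
      }
      ok <- all(deg[need] == 1L) &&
        all(deg[setdiff(atoms_in, need)] == 0L)
      if (ok) {
        found <- TRUE
        break
      }
    }
    if (found) good_placements <- good_placements + 1L
  }
  good_placements
}

outcome_of <- function(record) {
  iss <- chemcheck:::.codes_of(check_dearomatization(record)$issues)
  if ("dearomatization_failed" %in% iss) return("failed")
  if ("dearomatization_not_unique" %in% iss) return("not_unique")
  "unique"
}

outcome_from_count <- function(n) {
  if (n == 0L) "failed" else if (n == 1L) "unique" else "not_unique"
}

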