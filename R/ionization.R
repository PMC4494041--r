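# Competitive ionization: in a partially ionized structure the most acidic
# proton (smallest rank) should be removed first.  Acid/base groups are
# matched by SMARTS; the proton move itself is applied as a formal-charge
# flip at the group's acid/base-differing atom, which conserves net charge,
# heavy atoms and molecular formula by construction and leaves the rest of
# the connection table (wedges, atom numbering) untouched.

.ionization_state <- new.env(parent = emptyenv())

#' Load ranked acid/base groups from XML
#'
#' Each `<acidgroup>` element must carry the attributes `rank`, `acid`,
#' `base`, `acid2base`, `base2acid` (plus an optional `name`).  SMARTS and
#' SMIRKS are validated; the position of the protonation-state atom is
#' derived by diffing the formal charges of the acid and base query atoms.
#'
#' @param text XML text or file path.
#' @return list of `AcidGroup` entries sorted by rank: each has `name`,
#'   `rank`, `acid`, `base`, `acid2base`, `base2acid`, `proton_pos`
#'   (1-based atom position within the SMARTS match), `acid_charge`,
#'   `base_charge`.
#' @export
load_acid_groups <- function(text) {
  doc <- xml2::read_xml(text)
  nodes <- xml2::xml_find_all(doc, ".//acidgroup")
  if (!length(nodes)) stop("no <acidgroup> elements found")
  required <- c("rank", "acid", "base", "acid2base", "base2acid")
  groups <- lapply(nodes, function(node) {
    attrs <- vapply(required, function(a) xml2::xml_attr(node, a),
                    character(1))
    name <- xml2::xml_attr(node, "name")
    if (is.na(name)) name <- paste0("rank", attrs[["rank"]])
    if (anyNA(attrs)) {
      stop("acidgroup '", name, "' is missing attribute(s): ",
           paste(required[is.na(attrs)], collapse = ", "))
    }
    rank <- suppressWarnings(as.integer(attrs[["rank"]]))
    if (is.na(rank) || rank <= 0L) {
      stop("acidgroup '", name, "' has a non-positive rank")
    }
    list(name = name, rank = rank, acid = attrs[["acid"]],
         base = attrs[["base"]], acid2base = attrs[["acid2base"]],
         base2acid = attrs[["base2acid"]])
  })
  # duplicate rank with identical SMARTS is a definition error
  sig <- vapply(groups, function(g) paste(g$rank, g$acid, g$base),
                character(1))
  if (anyDuplicated(sig)) {
    stop("duplicate acidgroup definition: ", sig[duplicated(sig)][1])
  }
  smarts <- unlist(lapply(groups, function(g) c(g$acid, g$base)))
  ok <- backend_smarts_ok(unique(smarts))
  if (!all(ok)) {
    bad <- unique(smarts)[!ok][1]
    stop("invalid SMARTS in acid groups: ", bad)
  }
  smirks <- unlist(lapply(groups, function(g) c(g$acid2base, g$base2acid)))
  ok <- backend_smirks_ok(unique(smirks))
  if (!all(ok)) {
    stop("invalid SMIRKS in acid groups: ", unique(smirks)[!ok][1])
  }
  diffs <- chem_backend(lapply(groups, function(g)
    list(op = "query_charge_diff", acid = g$acid, base = g$base)))
  for (i in seq_along(groups)) {
    d <- diffs[[i]]
    if (!isTRUE(d$ok) || length(d$positions) != 1L) {
      stop("acidgroup '", groups[[i]]$name,
           "': acid and base SMARTS must differ in exactly one atom's ",
           "formal charge")
    }
    groups[[i]]$proton_pos <- d$positions[[1]]$pos
    groups[[i]]$acid_charge <- d$positions[[1]]$acid_charge
    groups[[i]]$base_charge <- d$positions[[1]]$base_charge
  }
  groups[order(vapply(groups, `[[`, integer(1), "rank"))]
}

#' The shipped FDA competitive-ionization table
#' @return list of acid groups (33 entries, ranks 10..330).
#' @export
default_acid_groups <- function() {
  if (is.null(.ionization_state$default)) {
    path <- system.file("extdata", "fda_acid_groups.xml",
                        package = "chemcheck")
    .ionization_state$default <- load_acid_groups(path)
  }
  .ionization_state$default
}

#' Match acid/base groups in a record
#'
#' Finds every acid-form and base-form match; overlapping matches (sharing
#' any atom) are resolved by keeping the lowest-rank match, ties broken by
#' form (acid first) then first atom index, so the retained matches have
#' disjoint atom sets.
#'
#' @param record a `molrec`.
#' @param groups acid groups from [load_acid_groups()].
#' @param config a [chemcheck_options()] list.
#' @return object of class `chem_ionization`: data frame `matches` with
#'   columns `name`, `rank`, `form`, `proton_atom`, `fragment`, and list
#'   column `atoms`.
#' @export
assign_ionization_state <- function(record, groups = default_acid_groups(),
                                    config = chemcheck_options()) {
  empty <- data.frame(name = character(), rank = integer(),
                      form = character(), proton_atom = integer(),
                      fragment = integer(), stringsAsFactors = FALSE)
  empty$atoms <- list()
  if (!nrow(record$atoms) || any(record$atoms$is_query) ||
      any(record$bonds$order == "query")) {
    return(structure(list(matches = empty), class = "chem_ionization"))
  }
  patterns <- unique(unlist(lapply(groups, function(g) c(g$acid, g$base))))
  res <- backend_analyze(record, patterns)
  if (!isTRUE(res$ok)) {
    return(structure(list(matches = empty), class = "chem_ionization"))
  }
  frag <- fragment_ids(record)
  cand <- list()
  for (g in groups) {
    for (form in c("acid", "base")) {
      hits <- res$matches[[g[[form]]]]
      for (h in hits) {
        cand[[length(cand) + 1L]] <- list(
          name = g$name, rank = g$rank, form = form,
          atoms = h, proton_atom = h[g$proton_pos],
          fragment = frag[h[1]]
        )
      }
    }
  }
  if (!length(cand)) {
    return(structure(list(matches = empty), class = "chem_ionization"))
  }
  ord <- order(vapply(cand, `[[`, integer(1), "rank"),
               match(vapply(cand, `[[`, character(1), "form"),
                     c("acid", "base")),
               vapply(cand, function(x) min(x$atoms), integer(1)))
  used <- logical(nrow(record$atoms))
  keep <- list()
  for (x in cand[ord]) {
    if (any(used[x$atoms])) next
    used[x$atoms] <- TRUE
    keep[[length(keep) + 1L]] <- x
  }
  matches <- data.frame(
    name = vapply(keep, `[[`, character(1), "name"),
    rank = vapply(keep, `[[`, integer(1), "rank"),
    form = vapply(keep, `[[`, character(1), "form"),
    proton_atom = vapply(keep, `[[`, integer(1), "proton_atom"),
    fragment = vapply(keep, `[[`, integer(1), "fragment"),
    stringsAsFactors = FALSE
  )
  matches$atoms <- lapply(keep, `[[`, "atoms")
  structure(list(matches = matches), class = "chem_ionization")
}

#' @export
print.chem_ionization <- function(x, ...) {
  m <- x$matches
  if (!nrow(m)) {
    cat("<ionization state> no acid/base groups matched\n")
    return(invisible(x))
  }
  cat("<ionization state>\n")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-22s rank %3d  %s  proton atom %d\n",
                m$name[i], m$rank[i], m$form[i], m$proton_atom[i]))
  }
  invisible(x)
}

#' Check competitive ionization
#'
#' Flags a partially ionized system in which an ionized (base-form) group
#' outranks a still-neutral (acid-form) group: some acid with rank r_a is
#' neutral while a base with rank r_b > r_a is ionized, i.e. a weaker acid
#' lost its proton first.  Equal ranks never violate.
#'
#' @param state a `chem_ionization` from [assign_ionization_state()].
#' @param config a [chemcheck_options()] list; with
#'   `per_fragment_ionization` the comparison is restricted to groups on the
#'   same fragment.
#' @return A single Information `chem_issue`, or `NULL`.
#' @export
check_competitive_ionization <- function(state,
                                         config = chemcheck_options()) {
  m <- state$matches
  if (!nrow(m)) return(NULL)
  scopes <- if (isTRUE(config$per_fragment_ionization)) unique(m$fragment)
            else NA_integer_
  for (scope in scopes) {
    mm <- if (is.na(scope)) m else m[m$fragment == scope, , drop = FALSE]
    acids <- mm[mm$form == "acid", , drop = FALSE]
    bases <- mm[mm$form == "base", , drop = FALSE]
    if (!nrow(acids) || !nrow(bases)) next
    r_a <- min(acids$rank)
    r_b <- max(bases$rank)
    if (r_a < r_b) {
      a <- acids[which.min(acids$rank), ]
      b <- bases[which.max(bases$rank), ]
      return(issue(
        "strongest_acid_not_ionized_first",
        atoms = sort(unique(c(a$atoms[[1]], b$atoms[[1]]))),
        note = sprintf("neutral %s (rank %d) vs ionized %s (rank %d)",
                       a$name, a$rank, b$name, b$rank)))
    }
  }
  NULL
}

# apply one proton move: set the proton atom's charge to the target form's
.flip_form <- function(record, match_row, groups, to_form) {
  g <- groups[[which(vapply(groups, `[[`, character(1), "name") ==
                       match_row$name)[1]]]
  target <- if (to_form == "acid") g$acid_charge else g$base_charge
  record$atoms$charge[match_row$proton_atom] <- as.integer(target)
  record
}

#' Reprotonate to the canonical ionization state
#'
#' While the competitive-ionization check finds a violation, one proton is
#' moved: the highest-rank ionized group is reprotonated (base -> acid) and
#' the lowest-rank neutral acid deprotonated (acid -> base).  Each step
#' strictly decreases the sum of ionized ranks, so the loop terminates; on
#' a violation-free record the input is returned unchanged.  Net charge and
#' molecular formula are conserved.
#'
#' @param record a `molrec`.
#' @param groups acid groups.
#' @param config a [chemcheck_options()] list.
#' @return list with `record` (possibly reprotonated), `changed` (logical)
#'   and `issues` (a `reprotonation_failed` Warning if standardization had
#'   to give up; empty otherwise).
#' @export
reprotonate_to_canonical <- function(record,
                                     groups = default_acid_groups(),
                                     config = chemcheck_options()) {
  original <- record
  changed <- FALSE
  for (step in seq_len(100L)) {
    state <- assign_ionization_state(record, groups, config)
    if (is.null(check_competitive_ionization(state, config))) {
      return(list(record = record, changed = changed, issues = list()))
    }
    m <- state$matches
    scope_m <- m
    if (isTRUE(config$per_fragment_ionization)) {
      # fix the first violating fragment
      for (fr in unique(m$fragment)) {
        mm <- m[m$fragment == fr, , drop = FALSE]
        a <- mm[mm$form == "acid", , drop = FALSE]
        b <- mm[mm$form == "base", , drop = FALSE]
        if (nrow(a) && nrow(b) && min(a$rank) < max(b$rank)) {
          scope_m <- mm
          break
        }
      }
    }
    acids <- scope_m[scope_m$form == "acid", , drop = FALSE]
    bases <- scope_m[scope_m$form == "base", , drop = FALSE]
    bases <- bases[order(-bases$rank, bases$proton_atom), , drop = FALSE]
    acids <- acids[order(acids$rank, acids$proton_atom), , drop = FALSE]
    new_rec <- tryCatch({
      r <- .flip_form(record, bases[1, ], groups, "acid")
      .flip_form(r, acids[1, ], groups, "base")
    }, error = function(e) NULL)
    if (is.null(new_rec)) {
      return(list(record = original, changed = FALSE,
                  issues = list(issue("reprotonation_failed"))))
    }
    record <- new_rec
    changed <- TRUE
  }
  list(record = original, changed = FALSE,
       issues = list(issue("reprotonation_failed",
                           note = "did not converge in 100 proton moves")))
}
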