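# Valence checking against the data-driven valence model.

.valence_state <- new.env(parent = emptyenv())

#' Load a valence model
#'
#' @param path YAML file mapping element -> charge -> common/uncommon valence
#'   sets; defaults to the model shipped with the package.
#' @return list of class `chem_valence_model`.
#' @export
load_valence_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "valences.yaml", package = "chemcheck")
  }
  structure(yaml::read_yaml(path), class = "chem_valence_model")
}

#' The shipped default valence model
#' @return list of class `chem_valence_model`.
#' @export
default_valence_model <- function() {
  if (is.null(.valence_state$default)) {
    .valence_state$default <- load_valence_model()
  }
  .valence_state$default
}

#' Allowed valence sets for an (element, charge) pair
#'
#' @return list with numeric vectors `common` and `uncommon`; both empty
#'   when the pair is not covered by the model (such atoms are unchecked).
#' @keywords internal
valence_sets <- function(model, symbol, charge) {
  entry <- model[[symbol]]
  if (!is.null(entry)) {
    sets <- entry[[as.character(charge)]]
    if (!is.null(sets)) {
      return(list(common = as.numeric(unlist(sets$common)),
                  uncommon = as.numeric(unlist(sets$uncommon))))
    }
  }
  list(common = numeric(), uncommon = numeric())
}

#' Check drawn valences against the model
#'
#' The drawn valence of an atom is its bond-order sum (aromatic bonds use
#' the kekulized orders computed by [check_dearomatization()] when the
#' record carries a unique kekulization; otherwise such atoms are skipped),
#' plus the radical adjustment, filled up with implicit hydrogens to the
#' smallest accommodating *common* valence (the MDL convention).  A valence
#' in the common set yields nothing; only in the uncommon set, a Warning
#' `unusual_valence`; outside both, an Error `bad_valence`.  Query atoms are
#' reported by the dedicated query-atom check and skipped here.
#'
#' @param record a `molrec`.
#' @param model a `chem_valence_model`.
#' @return list of `chem_issue` (`bad_valence` / `unusual_valence`), each
#'   carrying its atom locants.
#' @export
check_valences <- function(record, model = default_valence_model()) {
  n <- nrow(record$atoms)
  if (!n) return(list())
  bonds <- record$bonds
  aromatic_atoms <- unique(c(bonds$begin[bonds$order == "aromatic"],
                             bonds$end[bonds$order == "aromatic"]))
  kekule <- record$kekule # named numeric: bond row -> order, when unique
  used <- rep(0, n)
  skip <- rep(FALSE, n)
  ord <- .bond_order_num(bonds$order)
  if (!is.null(kekule)) ord[as.integer(names(kekule))] <- kekule
  for (k in seq_len(nrow(bonds))) {
    if (is.na(ord[k])) { # query bond: both ends unchecked
      skip[bonds$begin[k]] <- TRUE
      skip[bonds$end[k]] <- TRUE
      next
    }
    used[bonds$begin[k]] <- used[bonds$begin[k]] + ord[k]
    used[bonds$end[k]] <- used[bonds$end[k]] + ord[k]
  }
  if (is.null(kekule) && length(aromatic_atoms)) {
    skip[aromatic_atoms] <- TRUE # no unique kekulization: cannot judge
  }
  used <- used + record$atoms$radical
  bad <- integer()
  unusual <- integer()
  for (i in seq_len(n)) {
    if (skip[i] || record$atoms$is_query[i]) next
    sets <- valence_sets(model, record$atoms$symbol[i],
                         record$atoms$charge[i])
    if (!length(sets$common) && !length(sets$uncommon)) next
    ov <- record$atoms$valence_override[i]
    v <- if (!is.na(ov)) max(ov, used[i]) else {
      fill <- sets$common[sets$common >= used[i]]
      if (length(fill)) min(fill) else used[i]
    }
    if (v %in% sets$common) next
    if (v %in% sets$uncommon) unusual <- c(unusual, i) else bad <- c(bad, i)
  }
  out <- list()
  if (length(bad)) out <- c(out, list(issue("bad_valence", atoms = bad)))
  if (length(unusual)) {
    out <- c(out, list(issue("unusual_valence", atoms = unusual)))
  }
  out
}
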