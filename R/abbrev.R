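# SMARTS element-class abbreviations ({Hal}, {M}, {NM}, ...).  The table is
# shipped as editable YAML (inst/extdata/abbreviations.yaml); each entry is a
# list of element symbols plus an optional charge, and expands to a SMARTS
# atom alternation over atomic numbers so that aromatic and aliphatic forms
# both match (e.g. {NM} must hit the nitrogen of a porphyrin).

.abbrev_state <- new.env(parent = emptyenv())

#' Load a SMARTS abbreviation table
#'
#' @param path YAML file; defaults to the table shipped with the package.
#' @return named list: abbreviation name -> list(elements, charge).
#' @export
load_abbreviations <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.abbrev_state$default)) return(.abbrev_state$default)
    path <- system.file("extdata", "abbreviations.yaml",
                        package = "chemcheck")
    tab <- yaml::read_yaml(path)
    .abbrev_state$default <- tab
    return(tab)
  }
  yaml::read_yaml(path)
}

.charge_suffix <- function(charge) {
  if (is.null(charge) || charge == 0) return("")
  if (charge == 1) return("+")
  if (charge == -1) return("-")
  if (charge > 1) return(paste0("+", charge))
  paste0("-", abs(charge))
}

.abbrev_expansion <- function(entry) {
  nums <- atomic_number(unlist(entry$elements))
  if (anyNA(nums)) {
    stop("abbreviation table contains a non-element symbol: ",
         paste(unlist(entry$elements)[is.na(nums)], collapse = ", "))
  }
  suffix <- .charge_suffix(entry$charge)
  paste0("[", paste0("#", nums, suffix, collapse = ","), "]")
}

#' Expand element-class abbreviations in a SMARTS pattern
#'
#' Every `{Name}` placeholder is replaced by an atom alternation over the
#' elements of that class; the result is plain SMARTS.  Patterns without
#' placeholders pass through unchanged (the expansion is idempotent).
#'
#' @param pattern SMARTS string, possibly containing `{...}` placeholders.
#' @param table abbreviation table from [load_abbreviations()].
#' @return expanded SMARTS string.
#' @examples
#' expand_abbreviations("{Hal}")
#' expand_abbreviations("c1ccccc1")
#' @export
expand_abbreviations <- function(pattern, table = load_abbreviations()) {
  hits <- gregexpr("\\{[^{}]+\\}", pattern)[[1]]
  if (hits[1] == -1L) return(pattern)
  tokens <- unique(regmatches(pattern, gregexpr("\\{[^{}]+\\}",
                                                pattern))[[1]])
  for (tok in tokens) {
    name <- substr(tok, 2, nchar(tok) - 1)
    entry <- table[[name]]
    if (is.null(entry)) {
      stop("unknown SMARTS abbreviation: {", name, "}")
    }
    pattern <- gsub(tok, .abbrev_expansion(entry), pattern, fixed = TRUE)
  }
  pattern
}
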