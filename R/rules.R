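# The dictionary rule engine: validation-rule XML parsing and evaluation.
#
# Rule XML schema (matching the platform's user-rule format):
#   <rules origin="default|user">
#     <Warning name="code" message="topic" description="details">
#       <test name="SMARTStest" param="SMARTS"/>          -- single
#       <or> <test .../> <test .../> </or>                 -- OR-combined
#       <and> <test .../> <test .../> </and>               -- AND-combined
#     </Warning>
#     ...
#   </rules>
# Severity tag names are Error / Warning / Information.  Multiple direct
# <test> children (no wrapper) are treated as OR.  Only SMARTS tests are
# supported.

.rules_state <- new.env(parent = emptyenv())

.snake_case <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_+|_+$", "", x)
}

#' Load a validation-rule XML file or string
#'
#' SMARTS abbreviations are expanded at load time and every expanded pattern
#' is checked for syntactic validity; a bad pattern is a load error naming
#' the rule.  A test whose `name` is not `"SMARTStest"` is an
#' unsupported-test error (only SMARTS tests are supported at present).
#'
#' @param text XML text or a file path.
#' @param abbreviations abbreviation table for [expand_abbreviations()].
#' @return A `chem_ruleset`: list with `rules` (list of rule objects, each
#'   with `name`, `severity`, `message`, `description`, `tests`,
#'   `combinator`) and `origin`.
#' @export
load_ruleset_xml <- function(text, abbreviations = load_abbreviations()) {
  doc <- xml2::read_xml(text)
  origin <- xml2::xml_attr(doc, "origin")
  if (is.na(origin)) origin <- "user"
  severities <- c("Error", "Warning", "Information")
  rule_nodes <- xml2::xml_find_all(
    doc, paste0("./", paste(severities, collapse = " | ./")))
  rules <- lapply(rule_nodes, function(node) {
    severity <- xml2::xml_name(node)
    message <- xml2::xml_attr(node, "message")
    if (is.na(message)) message <- ""
    descr <- xml2::xml_attr(node, "description")
    if (is.na(descr)) descr <- ""
    name <- xml2::xml_attr(node, "name")
    if (is.na(name) || !nzchar(name)) name <- .snake_case(message)
    kids <- xml2::xml_children(node)
    kid_names <- xml2::xml_name(kids)
    if (length(kids) == 1L && kid_names %in% c("and", "or")) {
      combinator <- kid_names
      tests <- xml2::xml_children(kids[[1]])
    } else {
      tests <- kids
      combinator <- if (length(kids) > 1L) "or" else "single"
    }
    if (!length(tests)) {
      stop("rule '", name, "' has no tests")
    }
    test_names <- xml2::xml_attr(tests, "name")
    bad <- test_names != "SMARTStest" | is.na(test_names)
    if (any(bad)) {
      stop("rule '", name, "': test name '",
           test_names[which(bad)[1]],
           "' is not supported (only SMARTS tests are supported at present)")
    }
    params <- xml2::xml_attr(tests, "param")
    if (anyNA(params) || !all(nzchar(params))) {
      stop("rule '", name, "' has a test without a param attribute")
    }
    expanded <- vapply(params, expand_abbreviations, character(1),
                       table = abbreviations, USE.NAMES = FALSE)
    list(name = name, severity = severity, message = message,
         description = descr, tests = expanded, combinator = combinator)
  })
  names(rules) <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(names(rules))) {
    stop("duplicate rule names: ",
         paste(unique(names(rules)[duplicated(names(rules))]),
               collapse = ", "))
  }
  all_tests <- unique(unlist(lapply(rules, `[[`, "tests")))
  if (length(all_tests)) {
    ok <- backend_smarts_ok(all_tests)
    if (!all(ok)) {
      bad_pat <- all_tests[!ok][1]
      bad_rule <- names(rules)[vapply(rules, function(r)
        bad_pat %in% r$tests, logical(1))][1]
      stop("rule '", bad_rule, "': invalid SMARTS after expansion: ",
           bad_pat)
    }
  }
  structure(list(rules = rules, origin = origin,
                 include_builtin = identical(origin, "default")),
            class = "chem_ruleset")
}

#' The default platform rule set
#'
#' Loads `inst/extdata/default_rules.xml` (fragment detection, charge
#' patterns, metal bonds, functional groups, free carbon monoxide) and
#' attaches the two built-in structural checks that SMARTS cannot express:
#' more-than-one-radical and non-zero net charge.
#'
#' @return a `chem_ruleset`.
#' @export
default_ruleset <- function() {
  if (!is.null(.rules_state$default)) return(.rules_state$default)
  path <- system.file("extdata", "default_rules.xml", package = "chemcheck")
  rs <- load_ruleset_xml(path)
  .rules_state$default <- rs
  rs
}

# Structural checks attached to the default rule set: these inspect atom
# properties that SMARTS has no primitive for.
.builtin_checks <- function(record) {
  out <- list()
  rad_atoms <- which(record$atoms$radical > 0L)
  if (length(rad_atoms) > 1L) {
    out <- c(out, list(issue("multiple_radicals", atoms = rad_atoms)))
  }
  q <- net_charge(record)
  if (q != 0L) {
    out <- c(out, list(issue("net_charge_nonzero",
                             note = sprintf("net charge %+d", q))))
  }
  out
}

#' Evaluate dictionary rules against a record
#'
#' A rule with combinator `single` or `or` fires when any of its SMARTS
#' tests matches; an `and` rule fires only when all tests match.  A rule
#' firing several times on one record yields a single issue carrying all
#' match locants.  Patterns are matched against the aromaticity-perceived
#' form of the connection table; records that the matcher cannot interpret
#' (query atoms/bonds, non-kekulizable aromatics) yield no dictionary
#' issues — their defects are reported by the dedicated atom/bond and
#' dearomatization checks instead.
#'
#' @param record a `molrec`.
#' @param ruleset a `chem_ruleset` from [load_ruleset_xml()] /
#'   [default_ruleset()].
#' @return list of `chem_issue`.
#' @export
evaluate_rules <- function(record, ruleset = default_ruleset()) {
  out <- list()
  if (isTRUE(ruleset$include_builtin)) {
    out <- c(out, .builtin_checks(record))
  }
  if (!length(ruleset$rules) || !nrow(record$atoms)) return(out)
  if (any(record$atoms$is_query) || any(record$bonds$order == "query")) {
    return(out)
  }
  patterns <- unique(unlist(lapply(ruleset$rules, `[[`, "tests")))
  res <- backend_analyze(record, patterns)
  if (!isTRUE(res$ok)) return(out)
  for (rule in ruleset$rules) {
    hit_list <- lapply(rule$tests, function(p) res$matches[[p]])
    fired <- vapply(hit_list, function(h) length(h) > 0L, logical(1))
    fires <- if (rule$combinator == "and") all(fired) else any(fired)
    if (!fires) next
    atoms <- sort(unique(unlist(hit_list)))
    reg <- issue_registry()
    if (rule$name %in% reg$code) {
      out <- c(out, list(issue(rule$name, atoms = atoms)))
    } else {
      out <- c(out, list(issue(rule$name, atoms = atoms,
                               severity = rule$severity,
                               message = rule$message)))
    }
  }
  out
}
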