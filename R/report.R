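# Per-record orchestration and the aggregated, filterable report.
# Checks run in a fixed order so downstream checks can consume upstream
# annotations (the dearomatization check hands its unique kekulization to
# the valence check):
#   query atoms/bonds -> dearomatization -> valence -> wedge battery ->
#   undefined-stereo category -> relative/cross/3D flags -> dictionary
#   rules -> competitive ionization -> ring shapes -> cross-validation ->
#   duplicate fragments.

.analyze_op <- function(record, patterns, want_inchi) {
  list(op = "analyze", molblock = write_molfile(record),
       patterns = as.list(patterns), want_inchi = want_inchi)
}

.ruleset_patterns <- function(ruleset) {
  unique(unlist(lapply(ruleset$rules, `[[`, "tests")))
}

.group_patterns <- function(groups) {
  unique(unlist(lapply(groups, function(g) c(g$acid, g$base))))
}

.record_usable <- function(record) {
  is.null(record$parse_error) && nrow(record$atoms) > 0 &&
    !any(record$atoms$is_query) && !any(record$bonds$order == "query")
}

# Warm the backend cache for a batch of records with at most two python
# invocations, so validate_record() afterwards runs from cache.
.prefetch_backend <- function(records, ruleset, groups) {
  rule_pats <- .ruleset_patterns(ruleset)
  ion_pats <- .group_patterns(groups)
  ops <- list()
  smiles_ops <- list()
  for (rec in records) {
    if (!.record_usable(rec)) next
    ops <- c(ops, list(.analyze_op(rec, rule_pats, FALSE)),
             list(.analyze_op(rec, ion_pats, FALSE)),
             list(.analyze_op(rec, character(), TRUE)))
    frag <- fragment_ids(rec)
    if (max(frag, 0L) >= 2L) {
      for (f in seq_len(max(frag))) {
        ops <- c(ops, list(.analyze_op(subset_record(rec, which(frag == f)),
                                       character(), TRUE)))
      }
    }
    smiles <- rec$mapped$SMILES
    if (!is.null(smiles) && nzchar(trimws(smiles))) {
      smiles_ops <- c(smiles_ops, list(list(op = "smiles_to_molblock",
                                            smiles = trimws(smiles))))
    }
  }
  res <- chem_backend(c(ops, smiles_ops))
  # second stage: InChI for records parsed from mapped SMILES
  stage2 <- list()
  if (length(smiles_ops)) {
    tail_res <- res[seq(length(ops) + 1L, length(res))]
    for (r in tail_res) {
      if (isTRUE(r$ok)) {
        rec <- parse_molfile(r$molblock)
        rec$atoms$x <- 0; rec$atoms$y <- 0; rec$atoms$z <- 0
        rec$has_3d <- FALSE
        stage2 <- c(stage2, list(.analyze_op(rec, character(), TRUE)))
      }
    }
  }
  if (length(stage2)) chem_backend(stage2)
  invisible(NULL)
}

.run_check <- function(issues_so_far, expr) {
  res <- tryCatch(expr, error = function(e) {
    list(issue("internal_check_error", note = conditionMessage(e)))
  })
  if (inherits(res, "chem_issue")) res <- list(res)
  if (is.null(res)) res <- list()
  c(issues_so_far, res)
}

#' Validate one record
#'
#' Runs the full battery in a fixed order and returns the concatenated
#' issues.  An internal failure in one check yields an
#' `internal_check_error` issue and the remaining checks still run.
#'
#' @param record a `molrec`.
#' @param config a [chemcheck_options()] list.
#' @param ruleset dictionary rules ([default_ruleset()]).
#' @param groups acid/base groups ([default_acid_groups()]).
#' @param model valence model ([default_valence_model()]).
#' @return list of `chem_issue`, each stamped with the record's
#'   `source_index`.
#' @export
validate_record <- function(record, config = chemcheck_options(),
                            ruleset = default_ruleset(),
                            groups = default_acid_groups(),
                            model = default_valence_model()) {
  issues <- list()
  if (!is.null(record$parse_error)) {
    issues <- list(issue("parse_error", note = record$parse_error))
  } else {
    q_atoms <- which(record$atoms$is_query)
    if (length(q_atoms)) {
      issues <- c(issues, list(issue("query_atom", atoms = q_atoms)))
    }
    q_bonds <- which(record$bonds$order == "query")
    if (length(q_bonds)) {
      issues <- c(issues, list(issue(
        "query_bond", bonds = q_bonds,
        atoms = unique(c(record$bonds$begin[q_bonds],
                         record$bonds$end[q_bonds])))))
    }
    dearom <- tryCatch(check_dearomatization(record, config),
                       error = function(e) list(
                         issues = list(issue("internal_check_error",
                                             note = conditionMessage(e))),
                         record = record))
    issues <- c(issues, dearom$issues)
    record <- dearom$record
    issues <- .run_check(issues, check_valences(record, model))
    issues <- .run_check(issues, validate_wedges(record, config))
    issues <- .run_check(issues, categorize_undefined_stereo(record, config))
    issues <- .run_check(issues, check_relative_and_cross(record, config))
    issues <- .run_check(issues, evaluate_rules(record, ruleset))
    issues <- .run_check(issues, check_competitive_ionization(
      assign_ionization_state(record, groups, config), config))
    issues <- .run_check(issues, classify_rings(record, config)$issues)
    issues <- .run_check(issues, detect_l_pyranose(record, config))
    inchi_res <- tryCatch(generate_standard_inchi(record),
                          error = function(e) list(
                            inchi = NULL,
                            issues = list(issue("internal_check_error",
                                                note = conditionMessage(e)))))
    issues <- c(issues, inchi_res$issues)
    issues <- .run_check(issues,
                         crossvalidate_smiles(record, inchi_res$inchi,
                                              config))
    issues <- .run_check(issues,
                         crossvalidate_inchi(record, inchi_res$inchi,
                                             config))
    issues <- .run_check(issues, detect_duplicates(record))
  }
  lapply(issues, function(i) {
    i$record_index <- record$source_index
    i
  })
}

#' Build a validation report over many records
#'
#' @param records list of `molrec` (e.g. from [parse_sdf()]).
#' @param config a [chemcheck_options()] list; with `standardize = TRUE`
#'   records violating competitive ionization are reprotonated before
#'   validation and the standardized connection table is kept in the entry.
#' @param ruleset,groups,model as in [validate_record()].
#' @return A `chem_report`: list with `entries` (per record: `record_index`,
#'   `regid`, `inchi`, `issues`, `record`), `summary` (issue code ->
#'   distinct-record count), `config_snapshot`, `backend` (software
#'   versions).
#' @export
build_report <- function(records, config = chemcheck_options(),
                         ruleset = default_ruleset(),
                         groups = default_acid_groups(),
                         model = default_valence_model()) {
  tryCatch(.prefetch_backend(records, ruleset, groups),
           error = function(e) NULL)
  entries <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    standardized <- FALSE
    extra <- list()
    if (isTRUE(config$standardize) && .record_usable(rec)) {
      rep_res <- reprotonate_to_canonical(rec, groups, config)
      extra <- rep_res$issues
      if (rep_res$changed) {
        rec <- rep_res$record
        standardized <- TRUE
      }
    }
    issues <- c(validate_record(rec, config, ruleset, groups, model),
                lapply(extra, function(x) {
                  x$record_index <- rec$source_index
                  x
                }))
    inchi <- if (.record_usable(rec)) {
      generate_standard_inchi(rec)$inchi
    } else NULL
    entries[[i]] <- list(
      record_index = rec$source_index,
      regid = rec$mapped$REGID,
      inchi = inchi,
      standardized = standardized,
      issues = issues,
      record = rec
    )
  }
  structure(list(
    entries = entries,
    summary = .summarize_entries(entries),
    config_snapshot = config,
    backend = tryCatch(backend_version(), error = function(e) NULL)
  ), class = "chem_report")
}

.summarize_entries <- function(entries) {
  codes <- unlist(lapply(entries, function(e) unique(.codes_of(e$issues))))
  if (!length(codes)) return(integer())
  counts <- table(codes)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(names(out))]
}

#' @export
print.chem_report <- function(x, ...) {
  cat(sprintf("<chem_report> %d records, %d with issues\n",
              length(x$entries),
              sum(vapply(x$entries, function(e) length(e$issues) > 0,
                         logical(1)))))
  if (length(x$summary)) {
    reg <- issue_registry()
    for (code in names(x$summary)) {
      sev <- reg$severity[match(code, reg$code)]
      cat(sprintf("  %-12s %-36s %d\n",
                  ifelse(is.na(sev), "custom", sev), code,
                  x$summary[[code]]))
    }
  }
  invisible(x)
}

#' Filter a report by severity and issue code
#'
#' Entries are retained when they carry at least one issue matching both
#' filters; an empty filter matches everything.  The original report is
#' untouched.
#'
#' @param report a `chem_report`.
#' @param severities character vector of severities to keep (subset of
#'   Error/Warning/Information), or `NULL` for all.
#' @param codes character vector of issue codes to keep, or `NULL` for all.
#' @return A filtered `chem_report`.
#' @export
filter_report <- function(report, severities = NULL, codes = NULL) {
  if (!is.null(severities)) {
    bad <- setdiff(severities, c("Error", "Warning", "Information"))
    if (length(bad)) {
      stop("unknown severities: ", paste(bad, collapse = ", "),
           " (valid: Error, Warning, Information)")
    }
  }
  if (!is.null(codes)) {
    known <- unique(c(issue_registry()$code,
                      unlist(lapply(report$entries, function(e)
                        .codes_of(e$issues)))))
    bad <- setdiff(codes, known)
    if (length(bad)) {
      stop("unknown issue codes: ", paste(bad, collapse = ", "),
           "\nvalid codes: ", paste(sort(known), collapse = ", "))
    }
  }
  keep <- vapply(report$entries, function(e) {
    any(vapply(e$issues, function(i) {
      (is.null(severities) || i$severity %in% severities) &&
        (is.null(codes) || i$code %in% codes)
    }, logical(1)))
  }, logical(1))
  out <- report
  out$entries <- report$entries[keep]
  out$summary <- .summarize_entries(out$entries)
  out
}

#' Serialize a report to JSON
#'
#' One JSON object per record plus a summary block; deterministic for a
#' given input and configuration (no timestamps).
#'
#' @param report a `chem_report`.
#' @param path output file, or `NULL` to return the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  entries <- lapply(report$entries, function(e) {
    list(
      record_index = e$record_index,
      regid = e$regid %||% NULL,
      inchi = e$inchi %||% NULL,
      standardized = e$standardized,
      issues = lapply(e$issues, function(i) {
        list(code = i$code, severity = i$severity, message = i$message,
             note = i$note %||% NULL,
             atoms = as.integer(i$atoms), bonds = as.integer(i$bonds))
      })
    )
  })
  payload <- list(
    backend = report$backend,
    config = report$config_snapshot,
    summary = as.list(report$summary),
    records = entries
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
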