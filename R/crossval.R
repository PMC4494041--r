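# Standard-InChI generation from the connection table and cross-validation
# of depositor-supplied SMILES / InChI fields.  The connection table is the
# primary structure source; SMILES and InChI fields are secondary and are
# compared through the InChI they imply.

.strip_stereo_layers <- function(inchi) {
  # drop /b /t /m /s layers for the triage comparison mode
  gsub("/[btms][^/]*", "", inchi)
}

#' Generate the standard InChI of a record
#'
#' @param record a `molrec`; must be free of query atoms/bonds (those yield
#'   an `inchi_generation_failed` Error instead).
#' @return list with `inchi` (string or `NULL`) and `issues`.
#' @export
generate_standard_inchi <- function(record) {
  if (!nrow(record$atoms)) {
    return(list(inchi = NULL,
                issues = list(issue("inchi_generation_failed",
                                    note = "empty record"))))
  }
  if (any(record$atoms$is_query) || any(record$bonds$order == "query")) {
    locants <- which(record$atoms$is_query)
    return(list(inchi = NULL,
                issues = list(issue("inchi_generation_failed",
                                    atoms = locants,
                                    note = "query atoms/bonds present"))))
  }
  res <- backend_analyze(record, character(), want_inchi = TRUE)
  if (!isTRUE(res$ok) || is.null(res$inchi)) {
    note <- res$error %||% res$inchi_error %||% "unknown failure"
    return(list(inchi = NULL,
                issues = list(issue("inchi_generation_failed",
                                    note = note))))
  }
  list(inchi = res$inchi, issues = list())
}

#' Cross-validate a mapped SMILES field
#'
#' Parses the depositor SMILES, generates its standard InChI and compares it
#' with the InChI generated from the connection table.
#'
#' @param record a `molrec` with `mapped$SMILES` set (otherwise `NULL` is
#'   returned).
#' @param record_inchi the record's own standard InChI (computed if
#'   missing).
#' @param config a [chemcheck_options()] list; with
#'   `compare_stereo_layer = FALSE` the stereo layers are ignored.
#' @return A Warning `chem_issue` (`smiles_mismatch` / `smiles_invalid`) or
#'   `NULL`.
#' @export
crossvalidate_smiles <- function(record, record_inchi = NULL,
                                 config = chemcheck_options()) {
  smiles <- record$mapped$SMILES
  if (is.null(smiles) || !nzchar(trimws(smiles))) return(NULL)
  if (is.null(record_inchi)) {
    record_inchi <- generate_standard_inchi(record)$inchi
  }
  if (is.null(record_inchi)) return(NULL) # generation failure reported once
  smi_rec <- tryCatch(parse_smiles(smiles),
                      chemcheck_invalid_smiles = function(e) NULL)
  if (is.null(smi_rec)) {
    return(issue("smiles_invalid", note = smiles))
  }
  smi_inchi <- generate_standard_inchi(smi_rec)$inchi
  if (is.null(smi_inchi)) {
    return(issue("smiles_invalid",
                 note = paste("no InChI from SMILES", smiles)))
  }
  a <- record_inchi
  b <- smi_inchi
  if (!isTRUE(config$compare_stereo_layer)) {
    a <- .strip_stereo_layers(a)
    b <- .strip_stereo_layers(b)
  }
  if (!identical(trimws(a), trimws(b))) {
    return(issue("smiles_mismatch",
                 note = sprintf("structure %s vs SMILES %s", a, b)))
  }
  NULL
}

#' Cross-validate a mapped InChI field
#'
#' Whitespace-trimmed string comparison against the generated standard
#' InChI.  A non-standard prefix ("InChI=1/") is flagged without
#' comparison.
#'
#' @inheritParams crossvalidate_smiles
#' @return A Warning `chem_issue` (`inchi_mismatch` / `inchi_nonstandard`)
#'   or `NULL`.
#' @export
crossvalidate_inchi <- function(record, record_inchi = NULL,
                                config = chemcheck_options()) {
  supplied <- record$mapped$InChI
  if (is.null(supplied) || !nzchar(trimws(supplied))) return(NULL)
  supplied <- trimws(supplied)
  if (!startsWith(supplied, "InChI=1S/")) {
    return(issue("inchi_nonstandard", note = substr(supplied, 1, 40)))
  }
  if (is.null(record_inchi)) {
    record_inchi <- generate_standard_inchi(record)$inchi
  }
  if (is.null(record_inchi)) return(NULL)
  a <- trimws(record_inchi)
  b <- supplied
  if (!isTRUE(config$compare_stereo_layer)) {
    a <- .strip_stereo_layers(a)
    b <- .strip_stereo_layers(b)
  }
  if (!identical(a, b)) {
    return(issue("inchi_mismatch",
                 note = sprintf("generated %s vs supplied %s", a, b)))
  }
  NULL
}

#' Detect duplicate fragments within a record
#'
#' Fragments are grouped by their standard InChI; a group of two or more
#' yields `duplicate_molecules`, and a record consisting solely of copies of
#' one molecule additionally yields `only_duplicate_molecules`.
#'
#' @param record a `molrec`.
#' @return list of Warning `chem_issue` (possibly empty).
#' @export
detect_duplicates <- function(record) {
  if (any(record$atoms$is_query) || any(record$bonds$order == "query")) {
    return(list())
  }
  frag <- fragment_ids(record)
  nfrag <- max(frag, 0L)
  if (nfrag < 2L) return(list())
  parts <- lapply(seq_len(nfrag), function(f) which(frag == f))
  ops <- lapply(parts, function(idx) {
    list(op = "analyze", molblock = write_molfile(subset_record(record, idx)),
         patterns = list(), want_inchi = TRUE)
  })
  res <- chem_backend(ops)
  keys <- vapply(res, function(r) {
    if (isTRUE(r$ok) && !is.null(r$inchi)) r$inchi else NA_character_
  }, character(1))
  if (anyNA(keys)) return(list()) # uninterpretable fragment: no verdict
  out <- list()
  groups <- split(seq_len(nfrag), keys)
  dup_groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(dup_groups)) {
    atoms <- sort(unlist(parts[unlist(dup_groups)]))
    out <- c(out, list(issue("duplicate_molecules", atoms = atoms)))
    if (length(groups) == 1L) {
      out <- c(out, list(issue("only_duplicate_molecules")))
    }
  }
  out
}
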