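# Issue objects and the registry of every code the package can emit.
# Severities follow the platform's three-level model: Information, Warning,
# Error.  Codes are stable snake_case identifiers; messages are the concise
# topics shown in reports.

.issue_registry_rows <- function() {
  r <- function(code, severity, message, fixture = TRUE) {
    data.frame(code = code, severity = severity, message = message,
               fixture = fixture, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r("parse_error", "Error", "Record could not be parsed"),
    r("query_atom", "Error", "Invalid atom symbol (query atom)"),
    r("query_bond", "Error", "Query bond type"),
    r("dearomatization_failed", "Error",
      "Aromatic system cannot be dearomatized"),
    r("dearomatization_not_unique", "Error",
      "Dearomatization is not unique, cannot restore hydrogens"),
    r("bad_valence", "Error", "Bad valence"),
    r("unusual_valence", "Warning", "Structure contains unusual valence"),
    r("wedge_on_non_stereocenter", "Error",
      "Non-stereocenter is marked with stereo bonds"),
    r("wedge_points_at_stereocenter", "Error",
      "Up or down bond points from the atom at a stereocenter"),
    r("stereo_bond_direction_nonsense", "Error",
      "Direction of stereo bond makes no sense"),
    r("stereo_bond_angle_too_small", "Warning",
      "Angle between stereo bonds is too small"),
    r("two_same_wedges_at_center", "Error",
      "Two up or two down bonds on the same atom"),
    r("up_and_down_at_center", "Error",
      "Both up and down stereo bonds at the same stereocenter"),
    r("implicit_h_near_stereocenter", "Error",
      "Implicit hydrogen near stereocenter is ambiguous"),
    r("undefined_stereo_epimers", "Information",
      "Partially undefined stereo - epimers"),
    r("undefined_stereo_partial_mixtures", "Information",
      "Partially undefined stereo - mixtures"),
    r("undefined_stereo_enantiomers", "Information",
      "Completely undefined stereo - enantiomers"),
    r("undefined_stereo_mixtures", "Information",
      "Completely undefined stereo - mixtures"),
    r("relative_stereo", "Warning",
      "Relative stereo (wedge or hash bonds but no chiral flag)"),
    r("unknown_double_bond_stereo", "Information",
      "Double bond explicitly marked as unknown (cross bond)"),
    r("stereobond_in_ring", "Information", "Stereo bond in ring"),
    r("contains_3d", "Information", "Contains 3D coordinates"),
    r("fragment_small_molecule", "Warning",
      "Small-molecule fragment (methane, ammonia, water, S, B)"),
    r("multiple_radicals", "Warning", "More than one radical center"),
    r("net_charge_nonzero", "Information", "Overall charge is non-zero"),
    r("adjacent_like_charges", "Information",
      "Adjacent atoms with like charges"),
    r("metal_nonmetal_bond", "Information",
      "Covalent bond connecting a metal to a non-metal"),
    r("metal_nitrogen_bond", "Information", "Contains metal-nitrogen bond"),
    r("metal_oxygen_bond", "Information", "Contains metal-oxygen bond"),
    r("contains_enol", "Information", "Contains enol function"),
    r("non_1h_tetrazole", "Information", "Contains non-1H-tetrazole"),
    r("iminol_tautomer", "Information", "Contains N=C-OH group"),
    r("azide_drawn_hypervalent", "Information",
      "Azide written as N#N=N"),
    r("free_carbon_monoxide", "Warning", "Free carbon monoxide"),
    r("strongest_acid_not_ionized_first", "Information",
      "Strongest acid not ionized first in partially-ionized system"),
    r("perspective_ring_depiction", "Information",
      "Perspective (chair/boat) depiction of a pyranose-like ring"),
    r("haworth_projection", "Information",
      "Contains a perspective Haworth formula"),
    r("contains_l_pyranose", "Information", "Contains L-pyranose"),
    r("inchi_generation_failed", "Error", "InChI generation failed"),
    r("smiles_mismatch", "Warning", "SMILES does not match the structure"),
    r("smiles_invalid", "Warning", "Mapped SMILES cannot be parsed"),
    r("inchi_mismatch", "Warning", "InChI does not match the structure"),
    r("inchi_nonstandard", "Warning",
      "Mapped InChI is not a standard InChI"),
    r("duplicate_molecules", "Warning", "Duplicate molecules"),
    r("only_duplicate_molecules", "Warning",
      "Contains only multiple instances of the same molecule"),
    r("reprotonation_failed", "Warning",
      "Standardization could not reprotonate the record",
      fixture = FALSE),
    r("internal_check_error", "Error",
      "Internal failure while running a check", fixture = FALSE)
  ))
}

#' Registry of all issue codes
#'
#' One row per issue code the validator can emit: its stable identifier,
#' default severity and report message.  `fixture` marks codes that the
#' fixture suite can trigger deliberately (everything except internal
#' faults).
#'
#' @return data frame with columns `code`, `severity`, `message`, `fixture`.
#' @examples
#' table(issue_registry()$severity)
#' @export
issue_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .issue_registry_rows()
    cache
  }
})

#' Construct one validation issue
#'
#' @param code registered issue code.
#' @param atoms,bonds integer locants (1-based molfile indices).
#' @param note optional extra detail appended to the message.
#' @param severity override of the registry severity (used for the
#'   configurable-angle rule and user XML rules).
#' @param message,record_index overrides/metadata.
#' @return list of class `chem_issue`.
#' @export
issue <- function(code, atoms = integer(), bonds = integer(), note = NULL,
                  severity = NULL, message = NULL, record_index = NA_integer_) {
  reg <- issue_registry()
  row <- match(code, reg$code)
  if (is.na(row) && (is.null(severity) || is.null(message))) {
    stop("unregistered issue code: ", code)
  }
  structure(list(
    code = code,
    severity = if (!is.null(severity)) severity else reg$severity[row],
    message = if (!is.null(message)) message else reg$message[row],
    note = note,
    atoms = as.integer(atoms),
    bonds = as.integer(bonds),
    record_index = as.integer(record_index)
  ), class = "chem_issue")
}

#' @export
print.chem_issue <- function(x, ...) {
  cat(sprintf("[%s] %s: %s%s%s\n", x$severity, x$code, x$message,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else "",
              if (length(x$atoms))
                paste0(" atoms ", paste(x$atoms, collapse = ",")) else ""))
  invisible(x)
}

#' Flatten a list of issues to a data frame
#'
#' @param issues list of `chem_issue` objects.
#' @return data frame with one row per issue.
#' @export
issues_df <- function(issues) {
  if (!length(issues)) {
    return(data.frame(code = character(), severity = character(),
                      message = character(), note = character(),
                      atoms = character(), bonds = character(),
                      record_index = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(issues, function(is) {
    data.frame(
      code = is$code, severity = is$severity, message = is$message,
      note = if (is.null(is$note)) NA_character_ else is$note,
      atoms = paste(is$atoms, collapse = ","),
      bonds = paste(is$bonds, collapse = ","),
      record_index = is$record_index, stringsAsFactors = FALSE
    )
  }))
}

.codes_of <- function(issues) {
  vapply(issues, function(i) i$code, character(1))
}
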