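# SMILES input.  Parsing is delegated to the backend (SMILES -> kekulized
# molblock -> parse_molfile) so that a SMILES-derived record shares the
# exact container and downstream checks of a molfile-derived one.  Such
# records carry no depiction: coordinates are zeroed and has_3d is FALSE;
# they exist for cross-validation.

#' Signal an invalid-SMILES condition
#' @keywords internal
.invalid_smiles <- function(s, why) {
  stop(structure(
    class = c("chemcheck_invalid_smiles", "error", "condition"),
    list(message = sprintf("invalid SMILES '%s': %s", s, why), call = NULL)
  ))
}

#' Parse a SMILES string into a molecule record
#'
#' @param s a single non-empty SMILES string.
#' @param source_index stored on the record.
#' @return A `molrec` with all coordinates zero (`has_3d` FALSE).
#'   Unparsable SMILES raise a condition of class
#'   `chemcheck_invalid_smiles` (consumed by [crossvalidate_smiles()] as a
#'   Warning rather than a crash).
#' @examples
#' \dontrun{
#' rec <- parse_smiles("CCO")
#' nrow(rec$atoms)
#' }
#' @export
parse_smiles <- function(s, source_index = 1L) {
  if (!is.character(s) || length(s) != 1L || !nzchar(trimws(s))) {
    .invalid_smiles(as.character(s)[1], "empty input")
  }
  res <- chem_backend(list(list(op = "smiles_to_molblock",
                                smiles = trimws(s))))[[1]]
  if (!isTRUE(res$ok)) {
    .invalid_smiles(s, res$error %||% "parse failed")
  }
  rec <- parse_molfile(res$molblock, source_index = source_index)
  rec$atoms$x <- 0
  rec$atoms$y <- 0
  rec$atoms$z <- 0
  rec$has_3d <- FALSE
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
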