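# SDF stream reading/writing and the depositor field map.

#' Build an SDF field map
#'
#' Binds depositor SDF data-field names to the reserved fields `REGID`,
#' `SMILES` and `InChI` so that [parse_sdf()] can fill `record$mapped` and
#' the cross-validation checks can run.  Each reserved field may be bound
#' at most once.
#'
#' @param ... named arguments, `DEPOSITOR_FIELD = "RESERVED"`, e.g.
#'   `DATABASE_ID = "REGID"`; alternatively a single named character vector.
#' @return A named character vector (class `chem_field_map`).
#' @examples
#' fm <- field_map(DATABASE_ID = "REGID", Canonical_Smiles = "SMILES")
#' @export
field_map <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      is.character(args[[1]])) {
    map <- args[[1]]
  } else {
    map <- vapply(args, as.character, character(1))
  }
  reserved <- c("REGID", "SMILES", "InChI")
  bad <- setdiff(unname(map), reserved)
  if (length(bad)) {
    stop("field map targets must be one of ", paste(reserved, collapse = ", "),
         "; got: ", paste(bad, collapse = ", "))
  }
  dup <- unname(map)[duplicated(unname(map))]
  if (length(dup)) {
    stop("reserved field bound more than once: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(map, class = "chem_field_map")
}

#' Parse a field-map specification of the form "FIELD=REGID"
#' @param specs character vector like `c("DB_ID=REGID", "smiles=SMILES")`.
#' @keywords internal
parse_field_map_specs <- function(specs) {
  if (!length(specs)) return(field_map(character()))
  parts <- regmatches(specs, regexec("^(.*)=(REGID|SMILES|InChI)$", specs))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop("bad --map specification (expect FIELD=REGID|SMILES|InChI): ",
         paste(specs[bad], collapse = ", "))
  }
  map <- vapply(parts, `[`, character(1), 3L)
  names(map) <- vapply(parts, `[`, character(1), 2L)
  field_map(map)
}

.apply_field_map <- function(record, map) {
  if (!length(map)) return(record)
  for (fld in names(map)) {
    if (fld %in% names(record$sdf_fields)) {
      record$mapped[[unname(map[[fld]])]] <-
        trimws(record$sdf_fields[[fld]])
    }
  }
  record
}

#' Parse an SDF stream
#'
#' Records are delimited by "$$$$".  A record whose molfile block fails to
#' parse is returned as a stub carrying the parse failure (see
#' [validate_record()], which turns it into a record-level Error issue);
#' it never aborts the surrounding stream.
#'
#' @param input a file path, connection, or character vector of lines.
#' @param map a [field_map()] binding SDF fields to `REGID`/`SMILES`/`InChI`.
#' @param z_3d_threshold passed through to [parse_molfile()].
#' @return A list of `molrec` objects, `source_index` numbered from 1.
#' @export
parse_sdf <- function(input, map = field_map(), z_3d_threshold = 1e-4) {
  lines <- if (is.character(input) && length(input) == 1L &&
               !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else if (length(input) == 1L) {
    strsplit(input, "\n", fixed = TRUE)[[1]]
  } else {
    input
  }
  # split on delimiter lines
  delim <- which(startsWith(lines, "$$$$"))
  starts <- c(1L, delim + 1L)
  ends <- c(delim - 1L, length(lines))
  records <- list()
  idx <- 0L
  for (r in seq_along(starts)) {
    if (starts[r] > ends[r]) next
    chunk <- lines[starts[r]:ends[r]]
    if (!any(nzchar(trimws(chunk)))) next
    idx <- idx + 1L
    m_end <- which(startsWith(chunk, "M  END"))
    mol_part <- if (length(m_end)) chunk[seq_len(m_end[1])] else chunk
    rec <- tryCatch(
      parse_molfile(mol_part, source_index = idx,
                    z_3d_threshold = z_3d_threshold),
      error = function(e) failed_molrec(conditionMessage(e), idx)
    )
    data_part <- if (length(m_end) && m_end[1] < length(chunk))
      chunk[(m_end[1] + 1L):length(chunk)] else character()
    rec$sdf_fields <- .parse_sdf_fields(data_part)
    rec <- .apply_field_map(rec, map)
    records[[idx]] <- rec
  }
  records
}

.parse_sdf_fields <- function(lines) {
  fields <- character()
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^>.*<([^>]+)>", lines[i]))[[1]]
    if (length(m) == 2L) {
      j <- i + 1L
      vals <- character()
      while (j <= length(lines) && nzchar(trimws(lines[j])) &&
             !startsWith(lines[j], ">")) {
        vals <- c(vals, lines[j])
        j <- j + 1L
      }
      fields[[m[2]]] <- paste(vals, collapse = "\n")
      i <- j
    } else {
      i <- i + 1L
    }
  }
  fields
}

#' Write records as an SDF stream
#'
#' Round-trips everything [parse_sdf()] reads: connection table, wedges,
#' charges, chiral flag and data fields.
#'
#' @param records list of `molrec` objects.
#' @param path output file path or connection; `NULL` returns the text.
#' @return Invisibly, the number of records written (or the SDF text when
#'   `path` is `NULL`).
#' @export
write_sdf <- function(records, path = NULL) {
  blocks <- vapply(records, function(rec) {
    fields <- rec$sdf_fields
    field_lines <- character()
    for (nm in names(fields)) {
      field_lines <- c(field_lines, sprintf(">  <%s>", nm),
                       strsplit(fields[[nm]], "\n", fixed = TRUE)[[1]], "")
    }
    paste(c(write_molfile(rec), field_lines, "$$$$"), collapse = "\n")
  }, character(1))
  text <- paste(blocks, collapse = "\n")
  if (is.null(path)) return(invisible(text))
  writeLines(text, path)
  invisible(length(records))
}
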