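# Bridge to the bundled RDKit helper (inst/python/chem_backend.py).
# Requests are batched: one python process handles an arbitrary list of ops,
# so whole-file validation costs a single interpreter start-up.  Results are
# memoized per op within the session.

.backend_state <- new.env(parent = emptyenv())

.find_python <- function() {
  if (!is.null(.backend_state$python)) return(.backend_state$python)
  for (cand in c(Sys.getenv("CHEMCHECK_PYTHON"), "python", "python3")) {
    if (!nzchar(cand)) next
    path <- Sys.which(cand)
    if (nzchar(path)) {
      ok <- suppressWarnings(system2(
        path, c("-c", shQuote("import rdkit")),
        stdout = FALSE, stderr = FALSE)) == 0L
      if (ok) {
        .backend_state$python <- path
        return(path)
      }
    }
  }
  stop("chemcheck needs a python interpreter with rdkit on the PATH ",
       "(looked for 'python' and 'python3'; set CHEMCHECK_PYTHON to ",
       "override)")
}

.backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "chemcheck")
  if (!nzchar(path)) stop("chem_backend.py not found in installed package")
  path
}

#' Run a batch of backend ops
#'
#' @param ops list of op lists, each with an `op` element.
#' @return list of result lists, same order as `ops`.
#' @keywords internal
chem_backend <- function(ops) {
  if (!length(ops)) return(list())
  if (is.null(.backend_state$cache)) {
    .backend_state$cache <- new.env(parent = emptyenv())
  }
  keys <- vapply(ops, function(op) {
    paste(rawToChar(serialize(op, NULL, ascii = TRUE)), collapse = "")
  }, character(1))
  digests <- vapply(keys, function(k) {
    # cheap stable key: length + simple rolling hash of the serialized op
    chars <- utf8ToInt(k)
    paste0(length(chars), ":",
           sum(chars * (seq_along(chars) %% 97 + 1)) %% 2147483647, ":",
           sum(chars) %% 999983)
  }, character(1))
  results <- vector("list", length(ops))
  miss <- integer()
  for (i in seq_along(ops)) {
    hit <- .backend_state$cache[[digests[i]]]
    if (!is.null(hit) && identical(hit$key, keys[i])) {
      results[[i]] <- hit$value
    } else {
      miss <- c(miss, i)
    }
  }
  if (length(miss)) {
    req <- tempfile(fileext = ".json")
    resp <- tempfile(fileext = ".json")
    on.exit(unlink(c(req, resp)), add = TRUE)
    jsonlite::write_json(ops[miss], req, auto_unbox = TRUE, digits = NA,
                         null = "null")
    status <- system2(.find_python(), c(.backend_script(), req, resp),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(resp)) {
      stop("chemistry backend failed (python exit status ", status, ")")
    }
    got <- jsonlite::read_json(resp, simplifyVector = FALSE)
    if (length(got) != length(miss)) {
      stop("chemistry backend returned ", length(got), " results for ",
           length(miss), " ops")
    }
    for (j in seq_along(miss)) {
      i <- miss[j]
      results[[i]] <- got[[j]]
      assign(digests[i], list(key = keys[i], value = got[[j]]),
             envir = .backend_state$cache)
    }
  }
  results
}

#' Is the RDKit backend available?
#' @return `TRUE` or `FALSE`.
#' @export
backend_available <- function() {
  ok <- tryCatch({
    .find_python()
    TRUE
  }, error = function(e) FALSE)
  ok
}

#' Version of the chemistry backend
#'
#' Reported in every validation report so that generated InChIs are tied to
#' the software version that produced them.
#' @return named list with `rdkit` version string.
#' @export
backend_version <- function() {
  if (is.null(.backend_state$version)) {
    .backend_state$version <- chem_backend(list(list(op = "version")))[[1]]
  }
  .backend_state$version
}

#' SMARTS matches of several patterns against one record
#'
#' @param record a `molrec` (must be free of query atoms/bonds).
#' @param patterns character vector of SMARTS.
#' @param want_inchi also generate the standard InChI.
#' @return list with `ok`, `error`, `matches` (named by pattern, each a list
#'   of integer vectors of 1-based atom indices), `inchi`, `inchi_error`.
#' @keywords internal
backend_analyze <- function(record, patterns = character(),
                            want_inchi = FALSE) {
  res <- chem_backend(list(list(
    op = "analyze",
    molblock = write_molfile(record),
    patterns = as.list(patterns),
    want_inchi = want_inchi
  )))[[1]]
  if (isTRUE(res$ok)) {
    res$matches <- lapply(res$matches, function(m) {
      lapply(m$hits, function(h) as.integer(unlist(h)))
    })
  }
  res
}

#' Validate SMARTS patterns syntactically
#' @keywords internal
backend_smarts_ok <- function(patterns) {
  if (!length(patterns)) return(logical())
  res <- chem_backend(list(list(op = "validate_smarts",
                                patterns = as.list(patterns))))[[1]]
  vapply(res$ok, isTRUE, logical(1))
}

#' Validate SMIRKS strings syntactically
#' @keywords internal
backend_smirks_ok <- function(smirks) {
  if (!length(smirks)) return(logical())
  res <- chem_backend(list(list(op = "validate_smirks",
                                smirks = as.list(smirks))))[[1]]
  vapply(res$ok, isTRUE, logical(1))
}
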