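# Bridge to the RDKit chemistry backend. All chemistry in the package funnels
# through chem_call(), which runs one batched subprocess per request so the
# Python startup cost is paid once per dataset, not once per molecule.

chem_bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "ic50net")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet installed
    path <- system.file("inst", "python", "chem_bridge.py", package = "ic50net")
  }
  if (!nzchar(path)) stopf("chem_bridge.py not found in the installed package")
  path
}

chem_python <- function() {
  py <- Sys.getenv("IC50NET_PYTHON", unset = "python")
  if (!nzchar(Sys.which(py))) {
    stopf("python interpreter '%s' not found on PATH (set IC50NET_PYTHON to override)", py)
  }
  py
}

#' Low-level call into the RDKit backend
#'
#' @param op one of `"canonicalize"`, `"featurize"`.
#' @param smiles character vector of SMILES strings.
#' @param options named list of backend options.
#' @return a list with one entry per input SMILES; each entry has `ok` and
#'   either result fields or `error`.
#' @keywords internal
#' @noRd
chem_call <- function(op, smiles, options = list()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(
    list(op = op, smiles = I(smiles), options = options),
    req,
    auto_unbox = TRUE
  )
  status <- system2(chem_python(), c(chem_bridge_script(), req, res),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(res)) {
    stopf("chemistry backend failed (op = %s, exit status %s)", op, status)
  }
  jsonlite::read_json(res)
}

#' Canonicalize SMILES strings
#'
#' Maps every way of writing a molecule to one canonical string, as produced
#' by RDKit. Identical molecules written differently (kekulized vs aromatic
#' benzene, reordered atoms) canonicalize to the same string; the result is
#' stable across calls.
#'
#' @param smiles character vector of SMILES.
#' @param largest_fragment if `TRUE`, multi-fragment inputs (salts, mixtures)
#'   are reduced to their largest fragment by heavy-atom count before
#'   canonicalization.
#' @param on_error `"stop"` (default) raises an error naming the first
#'   offending string; `"na"` returns `NA` for unparsable entries.
#' @return with `details = FALSE` (default) a character vector of canonical
#'   SMILES; otherwise a data.frame with columns `input`, `canonical`,
#'   `n_frags`, `ok`, `error`.
#' @param details return the full per-molecule data.frame.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))  # same string twice
#' }
#' @export
canonicalize_smiles <- function(smiles, largest_fragment = FALSE,
                                on_error = c("stop", "na"), details = FALSE) {
  on_error <- match.arg(on_error)
  out <- chem_call("canonicalize", smiles,
                   list(largest_fragment = largest_fragment))
  ok <- vapply(out, function(x) isTRUE(x$ok), logical(1))
  canon <- rep(NA_character_, length(smiles))
  canon[ok] <- vapply(out[ok], function(x) x$canonical, character(1))
  if (on_error == "stop" && any(!ok)) {
    stopf("invalid SMILES: %s", out[[which(!ok)[1]]]$error)
  }
  if (!details) return(canon)
  data.frame(
    input = smiles,
    canonical = canon,
    n_frags = vapply(out, function(x) as.integer(x$n_frags %||% NA_integer_), integer(1)),
    ok = ok,
    error = vapply(out, function(x) x$error %||% NA_character_, character(1)),
    stringsAsFactors = FALSE
  )
}

# Raw featurization records straight from the backend, one per SMILES.
chem_featurize_raw <- function(smiles) {
  chem_call("featurize", smiles)
}
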