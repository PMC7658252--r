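# Bridge to the RDKit batch backend (inst/python/chem_backend.py).
# Every call ships a whole vector of molecules, so the per-process start-up
# cost is paid once per pipeline stage, not per molecule.

.chem_env <- new.env(parent = emptyenv())

#' Locate the Python interpreter used for the chemistry backend
#'
#' Defaults to `python` on the PATH; override with the `SYNTHFORGE_PYTHON`
#' environment variable.  The interpreter must have RDKit installed.
#' @return Path to the interpreter.
#' @export
chem_python <- function() {
  Sys.getenv("SYNTHFORGE_PYTHON", unset = "python")
}

chem_backend_script <- function() {
  system.file("python", "chem_backend.py", package = "synthforge", mustWork = TRUE)
}

#' Call the chemistry backend
#'
#' Low-level entry point used by all modules.  `payload` is serialized to
#' JSON, handed to the backend task, and the JSON result is returned as a
#' nested list.  Exposed so users can reach backend tasks (e.g. `canonical`)
#' directly.
#'
#' @param task Backend task name (e.g. "standardize", "match", "react").
#' @param payload Named list; character vectors are passed as JSON arrays.
#' @return Parsed JSON result as a list.
#' @export
chem_call <- function(task, payload) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  # wrap atomic vectors in as.list so length-1 inputs stay JSON arrays
  payload <- lapply(payload, function(x) if (is.atomic(x)) as.list(x) else x)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    chem_python(),
    c(chem_backend_script(), task, infile, outfile),
    stdout = FALSE, stderr = errfile
  ))
  if (!identical(status, 0L)) {
    err <- if (file.exists(errfile)) paste(readLines(errfile, warn = FALSE), collapse = "\n") else ""
    stop("chemistry backend task '", task, "' failed (exit ", status, "):\n", err,
         call. = FALSE)
  }
  jsonlite::fromJSON(outfile, simplifyVector = FALSE)
}

# scalar-or-NULL helper for list plucking
.pluck <- function(rec, field, default = NA) {
  v <- rec[[field]]
  if (is.null(v)) default else v
}

#' Canonical SMILES
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of RDKit canonical SMILES (`NA` if unparseable).
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- chem_call("canonical", list(smiles = smiles))
  vapply(res$smiles, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Stereo-aware, tautomer-invariant structure key
#'
#' The unique identifier used for deduplication and product counting: the
#' canonical tautomer of the structure is computed first, then its
#' stereo-aware canonical SMILES is taken.  Two tautomers of the same
#' compound share a key; two enantiomers do not.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of keys (`NA` if unparseable).
#' @export
molecule_key <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  res <- chem_call("keys", list(smiles = smiles))
  vapply(res$keys, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Count symmetry-distinct substructure match sites
#'
#' A "site" is a distinct set of matched atoms: matches that differ only in
#' the order the pattern walks the same atoms collapse to one site.
#'
#' @param patterns Character vector of SMARTS patterns.
#' @param smiles Character vector of SMILES.
#' @return Integer matrix `length(patterns) x length(smiles)` of site counts
#'   (`NA` for unparseable molecules).
#' @export
match_sites <- function(patterns, smiles) {
  if (length(patterns) == 0 || length(smiles) == 0) {
    return(matrix(integer(0), nrow = length(patterns), ncol = length(smiles)))
  }
  res <- chem_call("match", list(patterns = patterns, smiles = smiles))
  if (!is.null(res$error)) stop(res$error, call. = FALSE)
  m <- matrix(NA_integer_, nrow = length(patterns), ncol = length(smiles))
  for (i in seq_along(res$sites)) {
    row <- res$sites[[i]]
    m[i, ] <- vapply(row, function(x) if (is.null(x)) NA_integer_ else as.integer(x),
                     integer(1))
  }
  rownames(m) <- names(patterns)
  m
}

#' Molecular descriptors for annotation and property predicates
#'
#' @param smiles Character vector of SMILES.
#' @return A tibble with one row per input: mw, logp (atom-contribution
#'   Crippen logP), tpsa, fsp3, rotatable_bonds, hbd/hba (Lipinski
#'   definitions), heavy_atoms, ring_count, net_charge, and the eight
#'   descriptors of the QED desirability model (prefix `qed_`).
#' @export
mol_descriptors <- function(smiles) {
  cols <- c("mw", "logp", "tpsa", "fsp3", "rotatable_bonds", "hbd", "hba",
            "heavy_atoms", "ring_count", "net_charge",
            "qed_mw", "qed_alogp", "qed_hba", "qed_hbd", "qed_psa",
            "qed_rotb", "qed_arom", "qed_alerts")
  if (length(smiles) == 0) {
    out <- c(list(smiles = character(0), ok = logical(0)),
             stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(tibble::as_tibble(out))
  }
  res <- chem_call("descriptors", list(smiles = smiles))
  recs <- res$records
  out <- tibble::tibble(
    smiles = smiles,
    ok = vapply(recs, function(r) isTRUE(r$ok), logical(1))
  )
  for (cl in cols) {
    out[[cl]] <- vapply(recs, function(r) as.numeric(.pluck(r, cl, NA_real_)),
                        numeric(1))
  }
  out
}
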