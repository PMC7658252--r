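# Protecting-group handling: detection, removal, and the UN/DP id suffix.
#
# Seven protecting groups are supported (amine: Boc, Fmoc, Cbz; carboxyl:
# tert-butyl and benzyl esters; hydroxyl: tert-butyl ether and benzoate).
# Definitions ship as a CSV data file so the set can be extended.

#' Load protecting-group definitions
#'
#' @param path CSV file with columns label, attach_class, smarts,
#'   removal_smirks, note.  Defaults to the set shipped with the package.
#' @return Tibble of definitions.
#' @export
load_protecting_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protecting_groups.csv",
                        package = "synthforge", mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

.pg_payload <- function(pgs) {
  lapply(seq_len(nrow(pgs)), function(i) {
    list(label = pgs$label[i], smarts = pgs$smarts[i],
         removal_smirks = pgs$removal_smirks[i])
  })
}

#' Detect protecting groups
#'
#' Reports every occurrence of each supported protecting group together with
#' the attachment atom (0-based atom index of the masked heteroatom).
#'
#' @param smiles Character vector of SMILES.
#' @param pgs Protecting-group definitions ([load_protecting_groups()]).
#' @return Tibble with columns index (position in `smiles`), smiles, label,
#'   site.  Zero rows when nothing is protected.
#' @export
detect_pgs <- function(smiles, pgs = load_protecting_groups()) {
  empty <- tibble::tibble(index = integer(0), smiles = character(0),
                          label = character(0), site = integer(0))
  if (length(smiles) == 0) return(empty)
  res <- chem_call("detect_pgs", list(pgs = .pg_payload(pgs), smiles = smiles))$records
  rows <- list()
  for (i in seq_along(res)) {
    hits <- res[[i]]
    if (is.null(hits) || length(hits) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      index = i,
      smiles = smiles[i],
      label = vapply(hits, function(h) h$label, character(1)),
      site = vapply(hits, function(h) as.integer(h$site), integer(1))
    )
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Remove protecting groups until none remain
#'
#' Applies the removal templates repeatedly until no protecting group is
#' detected; a molecule without protecting groups is returned unchanged
#' (canonicalized).  Removal is exhaustive, so the result is idempotent.
#'
#' @inheritParams detect_pgs
#' @return Tibble with columns smiles, free_smiles, removed (list column of
#'   label multisets), n_removed, ok, error.
#' @export
deprotect <- function(smiles, pgs = load_protecting_groups()) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0), free_smiles = character(0),
                          removed = list(), n_removed = integer(0),
                          ok = logical(0), error = character(0)))
  }
  res <- chem_call("deprotect", list(pgs = .pg_payload(pgs), smiles = smiles))$records
  tibble::tibble(
    smiles = smiles,
    free_smiles = vapply(res, function(r) as.character(.pluck(r, "smiles_free", NA_character_)), character(1)),
    removed = lapply(res, function(r) unlist(r$removed) %||% character(0)),
    n_removed = vapply(res, function(r) length(r$removed), integer(1)),
    ok = vapply(res, function(r) isTRUE(r$ok), logical(1)),
    error = vapply(res, function(r) as.character(.pluck(r, "error", NA_character_)), character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Suffix a product id with its protection provenance
#'
#' "-DP" (deprotected) when protecting groups were removed from the product,
#' "-UN" (unprotected) when the product came from unprotected building
#' blocks.
#'
#' @param base_id Character vector of base ids.
#' @param removed List (or vector) of removed-label multisets, one per id.
#' @return Character vector of suffixed ids.
#' @export
suffix_id <- function(base_id, removed) {
  if (!is.list(removed)) removed <- as.list(removed)
  stopifnot(length(base_id) == length(removed))
  n <- vapply(removed, function(x) length(x[!is.na(x) & nzchar(x)]), integer(1))
  paste0(base_id, ifelse(n > 0, "-DP", "-UN"))
}
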