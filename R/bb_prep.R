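# Building-block preparation: standardization, filtering, deduplication and
# role assignment with the dual-role / multi-site exclusion rules.

#' Standardize raw building-block SMILES
#'
#' Keeps the largest organic fragment (dropping salts and counterions),
#' normalizes and canonicalizes the structure, computes the
#' stereo-aware/tautomer-invariant unique key, a Bertz-type complexity, and
#' detects the seven supported protecting groups.
#'
#' @param smiles Character vector of raw SMILES.
#' @param ids Optional identifiers (generated as BB0001... when missing).
#' @return Tibble with columns bb_id, smiles_raw, smiles_std, unique_key,
#'   n_fragments, complexity, heavy_atoms, has_isotope, has_metal,
#'   protecting_groups (comma-separated labels) and rejected
#'   ("parse_error" or NA at this stage).
#' @export
standardize_bbs <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("BB%04d", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  if (length(smiles) == 0) {
    return(tibble::tibble(bb_id = character(0), smiles_raw = character(0),
                          smiles_std = character(0), unique_key = character(0),
                          n_fragments = integer(0), complexity = numeric(0),
                          heavy_atoms = integer(0), has_isotope = logical(0),
                          has_metal = logical(0), protecting_groups = character(0),
                          rejected = character(0)))
  }
  res <- chem_call("standardize", list(smiles = smiles))$records
  out <- tibble::tibble(
    bb_id = ids,
    smiles_raw = smiles,
    smiles_std = vapply(res, function(r) as.character(.pluck(r, "smiles_std", NA_character_)), character(1)),
    unique_key = vapply(res, function(r) as.character(.pluck(r, "key", NA_character_)), character(1)),
    n_fragments = vapply(res, function(r) as.integer(.pluck(r, "n_fragments", NA_integer_)), integer(1)),
    complexity = vapply(res, function(r) as.numeric(.pluck(r, "complexity", NA_real_)), numeric(1)),
    heavy_atoms = vapply(res, function(r) as.integer(.pluck(r, "heavy_atoms", NA_integer_)), integer(1)),
    has_isotope = vapply(res, function(r) isTRUE(r$has_isotope), logical(1)),
    has_metal = vapply(res, function(r) isTRUE(r$has_metal), logical(1)),
    rejected = vapply(res, function(r) {
      if (isTRUE(r$ok)) NA_character_ else as.character(.pluck(r, "error", "parse_error"))
    }, character(1))
  )
  # protecting-group annotation on the standardized structures
  out$protecting_groups <- ""
  ok <- !is.na(out$smiles_std)
  if (any(ok)) {
    pgs <- detect_pgs(out$smiles_std[ok])
    if (nrow(pgs) > 0) {
      lab <- vapply(split(pgs$label, pgs$index), function(x)
        paste(sort(unique(x)), collapse = ","), character(1))
      out$protecting_groups[ok][as.integer(names(lab))] <- lab
    }
  }
  out
}

#' Filter standardized building blocks
#'
#' Applies the isotope, metal and complexity filters.  "Metal" means any
#' atom outside H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I (boron and silicon
#' are retained because boronates and silanes are required coupling
#' partners).  Any explicit non-default isotope label rejects the block.
#'
#' @param bbs Tibble from [standardize_bbs()].
#' @param complexity_cutoff Bertz complexity above which a block is rejected.
#' @return The tibble with `rejected` set to "isotope", "metal",
#'   "complexity" or "none" (parse errors keep "parse_error").
#' @export
filter_bbs <- function(bbs, complexity_cutoff = 1200) {
  reason <- bbs$rejected
  open <- is.na(reason)
  reason[open & bbs$has_isotope] <- "isotope"
  open <- is.na(reason)
  reason[open & bbs$has_metal] <- "metal"
  open <- is.na(reason)
  reason[open & bbs$complexity > complexity_cutoff] <- "complexity"
  reason[is.na(reason)] <- "none"
  bbs$rejected <- reason
  bbs
}

#' Deduplicate building blocks on the unique key
#'
#' One record per unique key; the first occurrence wins.  The number of
#' removed duplicates is attached as attribute `n_removed`.
#'
#' @param bbs Tibble with a `unique_key` column.
#' @return Deduplicated tibble.
#' @export
deduplicate_bbs <- function(bbs) {
  keep <- !duplicated(bbs$unique_key) | is.na(bbs$unique_key)
  out <- bbs[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Prepare a building-block pool end to end
#'
#' Convenience wrapper: standardize, filter, deduplicate.  Returns both the
#' accepted pool and the rejection report.
#'
#' @inheritParams standardize_bbs
#' @inheritParams filter_bbs
#' @return List with `accepted` (deduplicated tibble of blocks with
#'   rejected == "none"), `rejected` (tibble bb_id, reason) and
#'   `n_duplicates_removed`.
#' @export
prep_building_blocks <- function(smiles, ids = NULL, complexity_cutoff = 1200) {
  std <- filter_bbs(standardize_bbs(smiles, ids), complexity_cutoff)
  acc <- std[std$rejected == "none", , drop = FALSE]
  acc <- deduplicate_bbs(acc)
  list(
    accepted = acc,
    rejected = tibble::tibble(bb_id = std$bb_id[std$rejected != "none"],
                              reason = std$rejected[std$rejected != "none"]),
    n_duplicates_removed = attr(acc, "n_removed")
  )
}

#' Assign building blocks to the two reactant roles of a transform
#'
#' A block matching both role patterns is excluded from both sets (polymer
#' risk); a block matching one role at more than one symmetry-distinct site
#' is excluded from that role (product mixtures).  Dual-role exclusion is
#' applied first.  The remaining single-site matchers become role members.
#'
#' @param t A `transform`.
#' @param bbs Tibble of accepted building blocks (needs bb_id, smiles_std).
#' @return List with elements `role_a` and `role_b`, each a `role_set`:
#'   transform_id, role ("A"/"B"), members, excluded_dual_role,
#'   excluded_multi_site (vectors of bb_id).
#' @export
assign_roles <- function(t, bbs) {
  m <- match_sites(c(t$role_a$smarts, t$role_b$smarts), bbs$smiles_std)
  sites_a <- m[1, ]
  sites_b <- m[2, ]
  dual <- which(sites_a > 0 & sites_b > 0)
  mk <- function(role, sites) {
    multi <- which(sites > 1)
    multi <- setdiff(multi, dual)
    members <- which(sites == 1)
    members <- setdiff(members, dual)
    structure(list(
      transform_id = t$id,
      role = role,
      members = bbs$bb_id[members],
      excluded_dual_role = bbs$bb_id[dual],
      excluded_multi_site = bbs$bb_id[multi]
    ), class = "role_set")
  }
  list(role_a = mk("A", sites_a), role_b = mk("B", sites_b))
}

#' @export
print.role_set <- function(x, ...) {
  cat(sprintf("<role_set %s of transform %d: %d member(s), %d dual-role, %d multi-site excluded>\n",
              x$role, x$transform_id, length(x$members),
              length(x$excluded_dual_role), length(x$excluded_multi_site)))
  invisible(x)
}
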