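# The enumeration engine: reactant pairs -> candidate products -> clause
# scoring -> class labels.  This is the computational core of the pipeline:
# every possible A x B pair of role members is tested, the product template
# is applied at the unique match site of each reactant, the scoring clauses
# are evaluated on reactants and product, and surviving reactions are saved
# with their score class.  KILLed and failed reactions go to the audit log.

#' Enumerate all reactant pairs of a transform
#'
#' Cross product of the two role member sets in deterministic
#' (sorted bb_id) order.  Exclusions were applied by [assign_roles()].
#'
#' @param role_a,role_b `role_set` objects from [assign_roles()].
#' @return Tibble with columns transform_id, bb_a, bb_b.
#' @export
enumerate_pairs <- function(role_a, role_b) {
  a <- sort(role_a$members)
  b <- sort(role_b$members)
  if (length(a) == 0 || length(b) == 0) {
    return(tibble::tibble(transform_id = integer(0), bb_a = character(0),
                          bb_b = character(0)))
  }
  grid <- expand.grid(bb_b = b, bb_a = a, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- tibble::tibble(transform_id = role_a$transform_id,
                        bb_a = grid$bb_a, bb_b = grid$bb_b)
  # self-pairing cannot happen (dual-role blocks were excluded) - assert it
  stopifnot(!any(out$bb_a == out$bb_b))
  out
}

#' Apply a transform's product template to reactant pairs
#'
#' Runs the SMIRKS template on each pair.  Multi-site reactants were
#' excluded upstream, so each pair yields at most one product; pairs where
#' the template produces several distinct structures are audited as
#' `ambiguous_product` and not saved.
#'
#' @param t A `transform`.
#' @param pairs Tibble from [enumerate_pairs()].
#' @param bbs Building-block tibble (bb_id, smiles_std).
#' @return `pairs` with added columns candidate_smiles (NA on failure) and
#'   audit_reason (NA on success; "no_product", "sanitization_failed" or
#'   "ambiguous_product").
#' @export
apply_transform <- function(t, pairs, bbs) {
  pairs$candidate_smiles <- NA_character_
  pairs$audit_reason <- NA_character_
  if (nrow(pairs) == 0) return(pairs)
  smi <- stats::setNames(bbs$smiles_std, bbs$bb_id)
  plist <- lapply(seq_len(nrow(pairs)), function(i) {
    list(smi[[pairs$bb_a[i]]], smi[[pairs$bb_b[i]]])
  })
  res <- chem_call("react", list(smirks = t$product_smirks, pairs = plist))$records
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (isTRUE(r$ok)) {
      prods <- unlist(r$products)
      if (length(prods) == 1) {
        pairs$candidate_smiles[i] <- prods
      } else {
        pairs$audit_reason[i] <- "ambiguous_product"
      }
    } else {
      pairs$audit_reason[i] <- as.character(.pluck(r, "error", "no_product"))
    }
  }
  pairs
}

# Evaluate every clause of a transform over a set of reactions.
# Returns list(delta, killed, trace) with trace a list of per-reaction
# tibbles (clause index, action, value).
.evaluate_clauses <- function(t, mol_a, mol_b, mol_p) {
  n <- length(mol_p)
  delta <- integer(n)
  killed <- logical(n)
  trace <- replicate(n, list(), simplify = FALSE)
  if (length(t$clauses) == 0 || n == 0) {
    return(list(delta = delta, killed = killed,
                trace = lapply(trace, .trace_tbl)))
  }
  scope_mols <- list(reactant_a = mol_a, reactant_b = mol_b, product = mol_p)
  # batch all SMARTS clauses in one backend call over the union of molecules
  smarts_idx <- which(vapply(t$clauses, function(cl) !is.null(cl$smarts), logical(1)))
  hit <- list()
  if (length(smarts_idx) > 0) {
    pats <- vapply(t$clauses[smarts_idx], function(cl) cl$smarts, character(1))
    uni <- unique(unlist(scope_mols, use.names = FALSE))
    m <- match_sites(pats, uni)
    for (k in seq_along(smarts_idx)) {
      ci <- smarts_idx[k]
      sc <- t$clauses[[ci]]$scope
      idx <- match(scope_mols[[sc]], uni)
      hit[[as.character(ci)]] <- !is.na(m[k, idx]) & m[k, idx] > 0
    }
  }
  prop_idx <- which(vapply(t$clauses, function(cl) !is.null(cl$property), logical(1)))
  if (length(prop_idx) > 0) {
    uni <- unique(unlist(scope_mols, use.names = FALSE))
    d <- mol_descriptors(uni)
    for (ci in prop_idx) {
      cl <- t$clauses[[ci]]
      idx <- match(scope_mols[[cl$scope]], uni)
      vals <- d[[cl$property]][idx]
      hit[[as.character(ci)]] <- do.call(cl$op, list(vals, cl$threshold)) %in% TRUE
    }
  }
  for (ci in seq_along(t$clauses)) {
    cl <- t$clauses[[ci]]
    h <- hit[[as.character(ci)]]
    if (is.null(h)) next
    for (i in which(h)) {
      trace[[i]][[length(trace[[i]]) + 1]] <- list(
        clause = ci, action = cl$action, value = .pluck(cl, "value", NA_integer_))
      if (cl$action == "ADD") delta[i] <- delta[i] + cl$value
      if (cl$action == "SUBTRACT") delta[i] <- delta[i] - cl$value
      if (cl$action == "KILL") killed[i] <- TRUE
    }
  }
  list(delta = delta, killed = killed, trace = lapply(trace, .trace_tbl))
}

.trace_tbl <- function(tr) {
  if (length(tr) == 0) {
    return(tibble::tibble(clause = integer(0), action = character(0),
                          value = integer(0)))
  }
  tibble::tibble(
    clause = vapply(tr, function(x) as.integer(x$clause), integer(1)),
    action = vapply(tr, function(x) x$action, character(1)),
    value = vapply(tr, function(x) as.integer(.pluck(x, "value", NA_integer_)),
                   integer(1))
  )
}

#' Score one reaction against a transform's clauses
#'
#' Each clause whose predicate matches its scope molecule contributes
#' +value (ADD) or -value (SUBTRACT); a matched KILL vetoes the reaction.
#' The clause trace lists every matched clause in file order.
#'
#' @param t A `transform`.
#' @param smiles_a,smiles_b Standardized reactant SMILES.
#' @param product Product SMILES from [apply_transform()].
#' @return List with elements `killed` (logical), `delta` (integer, NA when
#'   killed is reported as-is) and `trace` (tibble clause/action/value).
#' @export
score_reaction <- function(t, smiles_a, smiles_b, product) {
  ev <- .evaluate_clauses(t, smiles_a, smiles_b, product)
  list(killed = ev$killed[1], delta = ev$delta[1], trace = ev$trace[[1]])
}

#' Classify a net clause score into a synthesizability class
#'
#' Plus for any positive score; otherwise Neg\emph{n} with \emph{n} the
#' largest of 0, 10, 20, 30 not exceeding |delta| (0 and -5 are Neg0,
#' -10/-15 Neg10, -20/-25 Neg20, anything at or below -30 Neg30).
#'
#' @param delta Integer vector of net clause scores of non-killed reactions.
#' @return Character vector of class labels.
#' @export
classify_score <- function(delta) {
  stopifnot(is.numeric(delta))
  vapply(delta, function(d) {
    if (is.na(d)) return(NA_character_)
    if (d > 0) return("Plus")
    n <- max(c(0, 10, 20, 30)[c(0, 10, 20, 30) <= abs(d)])
    paste0("Neg", n)
  }, character(1))
}

.CLASS_LEVELS <- c("Plus", "Neg0", "Neg10", "Neg20", "Neg30")

#' Run the full enumeration over a rule set and building-block pool
#'
#' For every transform: assign roles, enumerate all reactant pairs, apply
#' the product template, evaluate the scoring clauses, deprotect saved
#' products and assign UN/DP-suffixed ids.  Failures of individual
#' reactions are logged in the audit table and never abort the run.  The
#' run is deterministic: identical inputs give byte-identical tables.
#'
#' @param transforms List of `transform` objects.
#' @param bbs Accepted building-block tibble ([prep_building_blocks()]).
#' @param id_prefix Prefix of generated product ids.
#' @return Object of class `library_run`: list with `records` (saved
#'   reactions: product_id, transform_id, bb_a, bb_b, product_smiles,
#'   product_protected_smiles, product_key, delta, class_label,
#'   clause_trace JSON, removed_pgs), `audit` (transform_id, bb_a, bb_b,
#'   reason, clause), and `stats` ([library_stats()]).
#' @export
run_library <- function(transforms, bbs, id_prefix = "P") {
  rec_list <- list()
  audit_list <- list()
  tested <- stats::setNames(integer(length(transforms)),
                            vapply(transforms, function(t) as.character(t$id), character(1)))
  smi <- stats::setNames(bbs$smiles_std, bbs$bb_id)
  for (t in transforms) {
    roles <- assign_roles(t, bbs)
    pairs <- enumerate_pairs(roles$role_a, roles$role_b)
    tested[as.character(t$id)] <- nrow(pairs)
    if (nrow(pairs) == 0) next
    pairs <- apply_transform(t, pairs, bbs)
    bad <- !is.na(pairs$audit_reason)
    if (any(bad)) {
      audit_list[[length(audit_list) + 1]] <- tibble::tibble(
        transform_id = t$id, bb_a = pairs$bb_a[bad], bb_b = pairs$bb_b[bad],
        reason = pairs$audit_reason[bad], clause = NA_integer_)
    }
    ok <- pairs[!bad, , drop = FALSE]
    if (nrow(ok) == 0) next
    ev <- .evaluate_clauses(t, smi[ok$bb_a], smi[ok$bb_b], ok$candidate_smiles)
    if (any(ev$killed)) {
      kidx <- which(ev$killed)
      kill_clause <- vapply(kidx, function(i) {
        tr <- ev$trace[[i]]
        k <- tr$clause[tr$action == "KILL"]
        if (length(k) > 0) k[1] else NA_integer_
      }, integer(1))
      audit_list[[length(audit_list) + 1]] <- tibble::tibble(
        transform_id = t$id, bb_a = ok$bb_a[kidx], bb_b = ok$bb_b[kidx],
        reason = "killed", clause = kill_clause)
    }
    keep <- which(!ev$killed)
    if (length(keep) == 0) next
    rec_list[[length(rec_list) + 1]] <- tibble::tibble(
      transform_id = t$id,
      bb_a = ok$bb_a[keep], bb_b = ok$bb_b[keep],
      candidate_smiles = ok$candidate_smiles[keep],
      delta = ev$delta[keep],
      clause_trace = vapply(ev$trace[keep], function(tr)
        as.character(jsonlite::toJSON(tr, auto_unbox = FALSE)), character(1))
    )
  }
  audit <- if (length(audit_list) > 0) do.call(rbind, audit_list) else
    tibble::tibble(transform_id = integer(0), bb_a = character(0),
                   bb_b = character(0), reason = character(0), clause = integer(0))
  if (length(rec_list) == 0) {
    records <- tibble::tibble(
      product_id = character(0), transform_id = integer(0), bb_a = character(0),
      bb_b = character(0), product_smiles = character(0),
      product_protected_smiles = character(0), product_key = character(0),
      delta = integer(0), class_label = character(0), clause_trace = character(0),
      removed_pgs = character(0))
    stats <- library_stats(records, audit, tested)
    return(structure(list(records = records, audit = audit, stats = stats),
                     class = "library_run"))
  }
  records <- do.call(rbind, rec_list)
  # deprotect saved products and assign suffixed ids
  dep <- deprotect(records$candidate_smiles)
  records$product_smiles <- dep$free_smiles
  records$product_protected_smiles <- ifelse(dep$n_removed > 0,
                                             records$candidate_smiles,
                                             NA_character_)
  records$removed_pgs <- vapply(dep$removed, paste, character(1), collapse = ",")
  base_id <- sprintf("%s%08d", id_prefix, seq_len(nrow(records)))
  records$product_id <- suffix_id(base_id, dep$removed)
  records$product_key <- molecule_key(records$product_smiles)
  records$class_label <- classify_score(records$delta)
  records$candidate_smiles <- NULL
  records <- records[, c("product_id", "transform_id", "bb_a", "bb_b",
                         "product_smiles", "product_protected_smiles",
                         "product_key", "delta", "class_label", "clause_trace",
                         "removed_pgs")]
  stats <- library_stats(records, audit, tested)
  structure(list(records = records, audit = audit, stats = stats),
            class = "library_run")
}

#' @export
print.library_run <- function(x, ...) {
  cat(sprintf("<library_run: %d saved reaction(s), %d audited failure(s)>\n",
              nrow(x$records), nrow(x$audit)))
  print(x$stats)
  invisible(x)
}
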