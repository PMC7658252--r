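# Shared fixtures, memoized per test session: the shipped transforms, a
# small prepared library for engine tests, and the full default fixture run
# used by the acceptance properties.

.sf_cache <- new.env(parent = emptyenv())

sf_transforms <- function() {
  if (is.null(.sf_cache$tf)) .sf_cache$tf <- default_transforms()
  .sf_cache$tf
}

sf_transform <- function(id) {
  tf <- sf_transforms()
  tf[[which(vapply(tf, function(t) t$id, integer(1)) == id)]]
}

# ~50-block library for engine-level tests
sf_small_spec <- function() {
  library_spec(carboxylic_acids = 6, primary_amines = 6, secondary_amines = 2,
               aryl_bromides = 4, boronic_acids = 3, alkyl_bromides = 3,
               azides = 3, alkynes = 3, alcohols = 4, sulfonyl_chlorides = 3,
               diketones_14 = 2, aryl_diamines = 2, aldehydes = 3, decoys = 2,
               seed = 42)
}

sf_small_prep <- function() {
  if (is.null(.sf_cache$small_prep)) {
    bbs <- generate_library(sf_small_spec())
    .sf_cache$small_bbs <- bbs
    .sf_cache$small_prep <- prep_building_blocks(bbs$smiles, bbs$bb_id)
  }
  .sf_cache$small_prep
}

sf_small_bbs <- function() {
  sf_small_prep()
  .sf_cache$small_bbs
}

sf_small_run <- function() {
  if (is.null(.sf_cache$small_run)) {
    .sf_cache$small_run <- run_library(sf_transforms(), sf_small_prep()$accepted)
  }
  .sf_cache$small_run
}

# full default fixture library (the package's study conditions)
sf_full_bbs <- function() {
  if (is.null(.sf_cache$full_bbs)) .sf_cache$full_bbs <- generate_library()
  .sf_cache$full_bbs
}

sf_full_prep <- function() {
  if (is.null(.sf_cache$full_prep)) {
    bbs <- sf_full_bbs()
    .sf_cache$full_prep <- prep_building_blocks(bbs$smiles, bbs$bb_id)
  }
  .sf_cache$full_prep
}

sf_full_run <- function() {
  if (is.null(.sf_cache$full_run)) {
    .sf_cache$full_run <- run_library(sf_transforms(), sf_full_prep()$accepted)
  }
  .sf_cache$full_run
}

# Brute-force role-assignment oracle, independent of assign_roles():
# enumerates ALL raw substructure matches and re-derives site counts as the
# number of distinct matched atom sets.
sf_oracle_roles <- function(t, bbs) {
  count_sites <- function(pattern) {
    res <- chem_call("match_all", list(pattern = pattern, smiles = bbs$smiles_std))
    vapply(res$matches, function(mlist) {
      if (is.null(mlist)) return(NA_integer_)
      sets <- unique(lapply(mlist, function(x) sort(unlist(x))))
      length(sets)
    }, integer(1))
  }
  sa <- count_sites(t$role_a$smarts)
  sb <- count_sites(t$role_b$smarts)
  dual <- sa > 0 & sb > 0
  list(
    members_a = sort(bbs$bb_id[sa == 1 & !dual]),
    members_b = sort(bbs$bb_id[sb == 1 & !dual]),
    dual = sort(bbs$bb_id[dual]),
    multi_a = sort(bbs$bb_id[sa > 1 & !dual]),
    multi_b = sort(bbs$bb_id[sb > 1 & !dual])
  )
}
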