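# Building-block preparation: standardization, filters, tautomer/stereo
# deduplication semantics and role assignment with exclusion rules.

test_that("standardization keeps the largest organic fragment and detects PGs", {
  std <- standardize_bbs(c("CCN.Cl", "NCCO", "CC(C)(C)OC(=O)NCCO", "not-a-smiles"))
  expect_identical(std$smiles_std[1], "CCN")
  expect_identical(std$n_fragments[1], 2L)
  expect_identical(std$smiles_std[2], "NCCO")
  expect_identical(std$protecting_groups[2], "")
  expect_identical(std$protecting_groups[3], "Boc")
  expect_identical(std$rejected[4], "parse_error")
})

test_that("isotope, metal and complexity filters set the rejection reason", {
  std <- filter_bbs(standardize_bbs(c("[13CH3]C(=O)O", "CC[Sn](CC)CC", "CCO")))
  expect_identical(std$rejected, c("isotope", "metal", "none"))
  # a sane cutoff keeps ethanol; a tiny one rejects it
  std2 <- filter_bbs(standardize_bbs("CCO"), complexity_cutoff = 1)
  expect_identical(std2$rejected, "complexity")
})

test_that("deduplication is keyed on stereo-aware, tautomer-invariant identity", {
  # same molecule, different atom order -> one record
  d1 <- deduplicate_bbs(standardize_bbs(c("OCC", "CCO")))
  expect_identical(nrow(d1), 1L)
  expect_identical(attr(d1, "n_removed"), 1L)
  # enantiomers stay distinct
  d2 <- deduplicate_bbs(standardize_bbs(c("C[C@H](N)C(=O)O", "C[C@@H](N)C(=O)O")))
  expect_identical(nrow(d2), 2L)
  # keto/enol pair of the same compound collapses
  d3 <- deduplicate_bbs(standardize_bbs(c("CC(=O)CC", "CC(O)=CC")))
  expect_identical(nrow(d3), 1L)
  # idempotence
  d4 <- deduplicate_bbs(d3)
  expect_identical(d4$unique_key, d3$unique_key)
  expect_identical(attr(d4, "n_removed"), 0L)
})

test_that("role assignment applies dual-role and multi-site exclusions", {
  t <- sf_transform(101)  # amide: acid + amine
  bbs <- standardize_bbs(c("Nc1ccc(C(=O)O)cc1",  # matches both roles
                           "Nc1cccc(N)c1",       # amine at two distinct sites
                           "Nc1ccccc1",          # aniline: clean member
                           "CC(=O)O",            # acid member
                           "CCCC"))              # matches nothing
  roles <- assign_roles(t, bbs)
  expect_identical(roles$role_a$excluded_dual_role, "BB0001")
  expect_identical(roles$role_b$excluded_dual_role, "BB0001")
  expect_identical(roles$role_b$excluded_multi_site, "BB0002")
  expect_true("BB0003" %in% roles$role_b$members)
  expect_identical(roles$role_a$members, "BB0004")
  # partition: every matching block lands in exactly one bucket per role
  for (rs in roles) {
    buckets <- c(rs$members, rs$excluded_dual_role, rs$excluded_multi_site)
    expect_false(anyDuplicated(buckets) > 0)
  }
})

test_that("role assignment agrees with the brute-force matcher on a ~50-block library", {
  prep <- sf_small_prep()
  for (id in c(101, 103, 107)) {
    t <- sf_transform(id)
    roles <- assign_roles(t, prep$accepted)
    oracle <- sf_oracle_roles(t, prep$accepted)
    expect_identical(sort(roles$role_a$members), oracle$members_a)
    expect_identical(sort(roles$role_b$members), oracle$members_b)
    expect_identical(sort(roles$role_a$excluded_dual_role), oracle$dual)
    expect_identical(sort(roles$role_a$excluded_multi_site), oracle$multi_a)
    expect_identical(sort(roles$role_b$excluded_multi_site), oracle$multi_b)
  }
})
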