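# Rule format: loading, schema validation, serialization round-trip and
# the semantic diagnostics of validate_transform().

test_that("the shipped rule set loads and passes validation cleanly", {
  tf <- sf_transforms()
  expect_length(tf, 8)
  ids <- vapply(tf, function(t) t$id, integer(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_equal(sum(vapply(tf, function(t) t$ring_forming, logical(1))), 3)
  for (t in tf) {
    expect_s3_class(t, "transform")
    expect_identical(validate_transform(t), character(0))
  }
})

test_that("a single-rule file round-trips through serialization", {
  tf <- sf_transforms()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(tf[1], path)
  back <- load_rules(path)
  expect_length(back, 1)
  t0 <- tf[[1]]; t1 <- back[[1]]
  expect_identical(t1$id, t0$id)
  expect_identical(t1$role_a$smarts, t0$role_a$smarts)
  expect_identical(t1$role_b$smarts, t0$role_b$smarts)
  expect_identical(t1$product_smirks, t0$product_smirks)
  expect_identical(length(t1$clauses), length(t0$clauses))
  for (i in seq_along(t0$clauses)) {
    expect_identical(t1$clauses[[i]]$scope, t0$clauses[[i]]$scope)
    expect_identical(t1$clauses[[i]]$action, t0$clauses[[i]]$action)
    expect_identical(t1$clauses[[i]]$value, t0$clauses[[i]]$value)
    expect_identical(t1$clauses[[i]]$smarts, t0$clauses[[i]]$smarts)
  }
})

test_that("an empty rule list loads as an empty list", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("transforms: []", path)
  expect_identical(load_rules(path), list())
})

.minimal_rule_yaml <- function(value_line) {
  c("transforms:",
    "  - id: 900",
    "    name: test amide",
    "    ring_forming: false",
    "    role_a: {smarts: '[CX3](=[OX1])[OX2H1]', example: 'CC(=O)O'}",
    "    role_b: {smarts: '[NX3;H2]', example: 'NCC'}",
    "    product_smirks: '[CX3:1](=[OX1:2])[OX2H1].[NX3;H2:3]>>[CX3:1](=[OX1:2])[NX3:3]'",
    "    leaving_groups: [{formula: H2O, heavy_atoms: 1}]",
    "    clauses:",
    value_line)
}

test_that("clause values off the 5..30 multiple-of-five grid are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(.minimal_rule_yaml(
    "      - {scope: reactant_b, action: ADD, value: 7, smarts: '[NX3H2]'}"), path)
  expect_error(load_rules(path), "multiple of 5")
  # the permissive flag admits off-grid values
  tf <- load_rules(path, permissive = TRUE)
  expect_identical(tf[[1]]$clauses[[1]]$value, 7L)
  # KILL clauses must not carry a value
  writeLines(.minimal_rule_yaml(
    "      - {scope: reactant_b, action: KILL, value: 5, smarts: '[SX2H]'}"), path)
  expect_error(load_rules(path), "KILL")
})

test_that("unparseable patterns raise an error naming the pattern", {
  path <- withr::local_tempfile(fileext = ".yaml")
  lines <- .minimal_rule_yaml(
    "      - {scope: reactant_b, action: ADD, value: 5, smarts: '[[broken'}")
  writeLines(lines, path)
  expect_error(load_rules(path), "\\[\\[broken")
})

test_that("validate_transform flags duplicated clauses and atom bookkeeping errors", {
  t <- sf_transform(101)
  # duplicated clause
  t_dup <- t
  t_dup$clauses <- c(t_dup$clauses, t_dup$clauses[1])
  expect_length(validate_transform(t_dup), 1)
  expect_match(validate_transform(t_dup), "duplicated clause")
  # template drops one atom (water) but the declaration says two
  t_bad <- t
  t_bad$leaving_groups <- list(list(formula = "H2O", heavy_atoms = 2))
  diags <- validate_transform(t_bad)
  expect_length(diags, 1)
  expect_match(diags, "drops 1 mapped atom")
})
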