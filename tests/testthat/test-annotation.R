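# Product annotation: descriptors, rule-of-five/three, PAINS, demerits, QED.

test_that("descriptors match hand-countable values", {
  d <- mol_descriptors(c("CCc1ccccc1", "c1ccccc1", "CCCC"))
  # ethylbenzene: 2 of 8 carbons sp3
  expect_equal(d$fsp3[1], 0.25)
  # benzene: rigid, apolar
  expect_identical(as.integer(d$rotatable_bonds[2]), 0L)
  expect_equal(d$tpsa[2], 0)
  # n-butane: one rotatable bond
  expect_identical(as.integer(d$rotatable_bonds[3]), 1L)
})

test_that("rule-of-five and rule-of-three count threshold exceedances", {
  expect_identical(ro5_violations(600, 6, 0, 5), 2L)
  expect_identical(ro5_violations(300, 2, 1, 3), 0L)
  expect_identical(ro5_violations(501, 5.01, 6, 11), 4L)
  expect_identical(ro3_violations(250, 2, 1, 2, 50), 0L)
  expect_identical(ro3_violations(301, 3.5, 4, 4, 61), 5L)
})

test_that("PAINS matching flags a rhodanine and passes ethanol", {
  p <- pains_count(c("O=C1NC(=S)SC1=Cc1ccccc1", "CCO"))
  expect_gte(p$pains_count[1], 1L)
  expect_identical(p$pains_count[2], 0L)
  expect_true(is.na(pains_count("not-a-smiles")$pains_count))
})

test_that("demerit totals are additive with strict/loose thresholds", {
  rules <- tibble::tibble(rule_id = c("T1", "T2"),
                          smarts = c("[OX2H1]", "[NX3H2]"),
                          demerit = c(50, 25),
                          description = c("hydroxyl", "primary amine"))
  # no matches
  d0 <- demerit_score("CCCC", rules)
  expect_identical(d0$demerits, 0)
  expect_identical(d0$matched_rules, "")
  # two matched rules valued 50 and 25 -> 75, strict pass
  d1 <- demerit_score("NCCO", rules)
  expect_identical(d1$demerits, 75)
  expect_setequal(strsplit(d1$matched_rules, ",")[[1]], c("T1", "T2"))
  expect_true(d1$strict_pass)
  # total 120 -> strict fail, loose pass
  rules2 <- tibble::tibble(rule_id = "T3", smarts = "[OX2H1]", demerit = 120,
                           description = "x")
  d2 <- demerit_score("CCO", rules2)
  expect_identical(d2$demerits, 120)
  expect_false(d2$strict_pass)
  expect_true(d2$loose_pass)
  # the shipped representative rule set loads and matches its own exemplars
  shipped <- load_demerit_rules()
  expect_gt(nrow(shipped), 10)
  expect_gt(demerit_score("CCS", shipped)$demerits, 0)
})

test_that("QED is in (0,1], deterministic, and agrees with the reference implementation", {
  mols <- c("CC(=O)Oc1ccccc1C(=O)O",                 # aspirin
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C",            # caffeine
            "CC(=O)NCCc1c[nH]c2ccccc12",             # an enumerated amide
            "c1ccc(-c2cn(-c3ccccc3)nn2)cc1")         # a triazole product
  q1 <- qed_score(mols)
  q2 <- qed_score(mols)
  expect_true(all(q1 > 0 & q1 <= 1))
  expect_identical(q1, q2)
  ref <- unlist(chem_call("qed_reference", list(smiles = mols))$qed)
  expect_equal(q1, ref, tolerance = 1e-3)
})

test_that("annotations are invariant to atom order and salt forms", {
  a <- annotate_products("CC(=O)NCCc1ccccc1")
  b <- annotate_products(canonical_smiles("c1ccccc1CCNC(=O)C"))
  cols <- c("mw", "logp", "tpsa", "fsp3", "rotatable_bonds", "hbd", "hba",
            "ro5_violations", "pains_count", "demerits", "qed")
  expect_equal(as.list(a[cols]), as.list(b[cols]))
})

test_that("an annotation error is carried, not thrown", {
  ann <- annotate_products(c("CCO", "][bogus"))
  expect_true(is.na(ann$annotation_error[1]))
  expect_identical(ann$annotation_error[2], "sanitization_failed")
  expect_true(is.na(ann$mw[2]))
})
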