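# Per-product drug-design annotation: physicochemical descriptors,
# rule-of-five / rule-of-three violations, PAINS alerts, an additive
# demerit score from substructure rules, and the QED drug-likeness
# estimate.

#' Rule-of-five violation count
#'
#' Number of Lipinski criteria exceeded: mw > 500, logp > 5, hbd > 5,
#' hba > 10.
#'
#' @param mw,logp,hbd,hba Descriptor vectors (Lipinski H-bond definitions).
#' @return Integer vector 0..4.
#' @export
ro5_violations <- function(mw, logp, hbd, hba) {
  as.integer((mw > 500) + (logp > 5) + (hbd > 5) + (hba > 10))
}

#' Rule-of-three violation count
#'
#' Fragment-likeness criteria exceeded: mw > 300, logp > 3, hbd > 3,
#' rotatable_bonds > 3, tpsa > 60.
#'
#' @param mw,logp,hbd,rotatable_bonds,tpsa Descriptor vectors.
#' @return Integer vector 0..5.
#' @export
ro3_violations <- function(mw, logp, hbd, rotatable_bonds, tpsa) {
  as.integer((mw > 300) + (logp > 3) + (hbd > 3) +
               (rotatable_bonds > 3) + (tpsa > 60))
}

#' PAINS alert count
#'
#' Number of distinct pan-assay-interference patterns matched, using the
#' published PAINS catalog bundled with the chemistry backend.
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble with columns smiles, pains_count, entries (comma-joined
#'   matched pattern names); count NA for unparseable input.
#' @export
pains_count <- function(smiles) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0), pains_count = integer(0),
                          entries = character(0)))
  }
  res <- chem_call("pains", list(smiles = smiles))$records
  tibble::tibble(
    smiles = smiles,
    pains_count = vapply(res, function(r)
      as.integer(.pluck(r, "count", NA_integer_)), integer(1)),
    entries = vapply(res, function(r)
      paste(unlist(r$entries), collapse = ","), character(1))
  )
}

#' Load demerit rules
#'
#' Substructure rules with additive penalty values flagging reactive or
#' promiscuous compounds (lower total is better).  The shipped file is a
#' small representative subset written for this package (see its
#' `_synthetic` name); drop in a complete rule file with the same columns
#' to use a full set.
#'
#' @param path CSV with columns rule_id, smarts, demerit, description.
#' @return Tibble of rules.
#' @export
load_demerit_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demerit_rules_synthetic.csv",
                        package = "synthforge", mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Additive demerit score
#'
#' Sum of the demerit values of all matched rules, with pass flags at the
#' strict (<100) and loose (<160) thresholds used in practice to triage
#' screening compounds.
#'
#' @param smiles Character vector of SMILES.
#' @param rules Demerit rule tibble ([load_demerit_rules()]).
#' @return Tibble with columns smiles, demerits, matched_rules
#'   (comma-joined rule ids), strict_pass, loose_pass.
#' @export
demerit_score <- function(smiles, rules = load_demerit_rules()) {
  if (length(smiles) == 0) {
    return(tibble::tibble(smiles = character(0), demerits = numeric(0),
                          matched_rules = character(0),
                          strict_pass = logical(0), loose_pass = logical(0)))
  }
  m <- match_sites(rules$smarts, smiles)
  hit <- !is.na(m) & m > 0
  demerits <- as.numeric(rules$demerit %*% hit)
  matched <- vapply(seq_along(smiles), function(j)
    paste(rules$rule_id[hit[, j]], collapse = ","), character(1))
  tibble::tibble(
    smiles = smiles,
    demerits = demerits,
    matched_rules = matched,
    strict_pass = demerits < 100,
    loose_pass = demerits < 160
  )
}

# Asymmetric double sigmoid desirability parameters of the QED model
# (published weights; identical to those encoded in standard toolkits).
.QED_ADS <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
             E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,
             E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,
             E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 0.000000001,
             E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,
             E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB   = c(A = 0.010000000, B = 272.4121427, C = 2.558379970, D = 1.565547684,
             E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM   = c(A = 3.217788970, B = 957.7374108, C = 2.274627939, D = 0.000000001,
             E = 1.317690384, F = 0.375760881, DMAX = 312.3372610),
  ALERTS = c(A = 0.010000000, B = 1199.094025, C = -0.09002883, D = 0.000000001,
             E = 0.185904477, F = 0.875193782, DMAX = 417.7253140)
)

.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.qed_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])
  e2 <- 1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])
  unname((p["A"] + p["B"] / e1 * (1 - 1 / e2)) / p["DMAX"])
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability-transformed descriptors
#' (molecular weight, logP, H-bond acceptors/donors, polar surface area,
#' rotatable bonds, aromatic rings, structural alerts), using the published
#' mean-weight set.  The descriptor inputs come from the chemistry backend;
#' the desirability aggregation is computed here.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of QED values in (0, 1]; NA for unparseable input.
#' @export
qed_score <- function(smiles) {
  d <- mol_descriptors(smiles)
  qed_from_properties(d)
}

#' QED from precomputed descriptor properties
#'
#' @param d Tibble with columns qed_mw, qed_alogp, qed_hba, qed_hbd,
#'   qed_psa, qed_rotb, qed_arom, qed_alerts ([mol_descriptors()]).
#' @return Numeric vector of QED values.
#' @export
qed_from_properties <- function(d) {
  props <- list(MW = d$qed_mw, ALOGP = d$qed_alogp, HBA = d$qed_hba,
                HBD = d$qed_hbd, PSA = d$qed_psa, ROTB = d$qed_rotb,
                AROM = d$qed_arom, ALERTS = d$qed_alerts)
  num <- 0
  for (nm in names(.QED_WEIGHTS)) {
    num <- num + .QED_WEIGHTS[[nm]] * log(.qed_ads(props[[nm]], .QED_ADS[[nm]]))
  }
  exp(num / sum(.QED_WEIGHTS))
}

#' Annotate products with the drug-design descriptor block
#'
#' Computes, per product: mw, logp, tpsa, fsp3, rotatable_bonds, hbd, hba,
#' ro5_violations, ro3_violations, pains_count, qed, demerits (plus pass
#' flags).  All values are pure functions of the canonical structure.
#' Unparseable structures carry an annotation error and do not abort the
#' run.
#'
#' @param smiles Character vector of product SMILES.
#' @param demerit_rules Demerit rule tibble.
#' @return Tibble with one row per product.
#' @export
annotate_products <- function(smiles, demerit_rules = load_demerit_rules()) {
  d <- mol_descriptors(smiles)
  out <- tibble::tibble(
    smiles = smiles,
    annotation_error = ifelse(d$ok, NA_character_, "sanitization_failed"),
    mw = d$mw, logp = d$logp, tpsa = d$tpsa, fsp3 = d$fsp3,
    rotatable_bonds = as.integer(d$rotatable_bonds),
    hbd = as.integer(d$hbd), hba = as.integer(d$hba)
  )
  out$ro5_violations <- ro5_violations(out$mw, out$logp, out$hbd, out$hba)
  out$ro3_violations <- ro3_violations(out$mw, out$logp, out$hbd,
                                       out$rotatable_bonds, out$tpsa)
  out$pains_count <- pains_count(smiles)$pains_count
  dem <- demerit_score(smiles, demerit_rules)
  out$demerits <- dem$demerits
  out$demerit_strict_pass <- dem$strict_pass
  out$demerit_loose_pass <- dem$loose_pass
  out$qed <- qed_from_properties(d)
  out
}
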