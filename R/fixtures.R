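# Seeded generator of toy building-block libraries with controlled
# functional-group composition.  Molecules are assembled from a fixed pool
# of simple scaffolds and inert decorations, so they are valid by
# construction; randomness only selects which candidates are used.  The
# generator emulates, at desk scale, a vendor building-block pool: one
# reactive group per block (plus deliberately planted exclusion cases),
# a fraction of protected variants, and a few inert decoys.

.ALKYL_FRAGS <- c("CC", "CCC", "CC(C)C", "CCCC", "C1CCCCC1", "CC(F)(F)F",
                  "CCOC", "C1CCC(C)CC1", "CCCOC", "CCCCC")
.ARYL_FRAGS <- c("c1ccccc1", "c1ccc(C)cc1", "c1ccc(F)cc1", "c1ccc(OC)cc1",
                 "c1ccc(Cl)cc1", "c1ccncc1", "c1ccc(C(F)(F)F)cc1",
                 "c1cccc(C)c1", "c1ccc(CC)cc1", "c1ccc(OCC)cc1",
                 "c1cccc(F)c1", "c1cccc(Cl)c1", "c1ccc2ccccc2c1",
                 "c1ccc(C(C)C)cc1", "c1cc(F)cc(C)c1", "c1ccsc1")

.candidates <- function(templates, frags) {
  unlist(lapply(templates, function(tpl) paste0(tpl, frags)))
}

.CLASS_CANDIDATES <- list(
  carboxylic_acids = function() .candidates(c("OC(=O)", "OC(=O)C"),
                                            c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  primary_amines = function() c(.candidates("N", c(.ALKYL_FRAGS, .ARYL_FRAGS)),
                                .candidates("NC", .ARYL_FRAGS),
                                .candidates("NC(C)", .ALKYL_FRAGS)),
  secondary_amines = function() c(.candidates("CN", .ALKYL_FRAGS),
                                  "C1CCNCC1", "O1CCNCC1", "C1CCCNC1"),
  aryl_bromides = function() .candidates("Br", .ARYL_FRAGS),
  boronic_acids = function() .candidates("OB(O)", .ARYL_FRAGS),
  alkyl_bromides = function() .candidates("BrC", c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  azides = function() paste0(c(.ALKYL_FRAGS, .ARYL_FRAGS), "N=[N+]=[N-]"),
  alkynes = function() .candidates("C#C", c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  alcohols = function() .candidates(c("OC", "OC(C)"), c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  sulfonyl_chlorides = function() .candidates("ClS(=O)(=O)",
                                              c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  diketones_14 = function() .candidates("CC(=O)CCC(=O)", .ALKYL_FRAGS),
  aryl_diamines = function() paste0("Nc1ccc(", c("C", "F", "Cl", "OC", "CC",
                                                 "C(F)(F)F", "CCC", "OCC"),
                                    ")cc1N"),
  aldehydes = function() .candidates("O=C", c(.ALKYL_FRAGS, .ARYL_FRAGS)),
  decoys = function() c("CCCCCC", "CCOCC", "c1ccccc1CCC", "CC#N", "CCCF",
                        "c1ccc2ccccc2c1", "CC(C)OC(C)C", "CCCCOC")
)

# classes that support a protected variant, with the transformation applied
.protect_variant <- function(class, smiles) {
  switch(class,
    primary_amines = list(smiles = sub("^N", "CC(C)(C)OC(=O)N", smiles),
                          pg = "Boc"),
    carboxylic_acids = list(smiles = sub("^OC\\(=O\\)", "CC(C)(C)OC(=O)", smiles),
                            pg = "tBu_ester"),
    alcohols = list(smiles = paste0("c1ccccc1C(=O)", smiles), pg = "benzoate"),
    NULL
  )
}

.PLANTS <- list(
  dual_role = c("Nc1ccc(C(=O)O)cc1",      # acid + amine: amide-rule dual
                "OB(O)c1ccc(Br)cc1"),     # bromide + boronic: coupling dual
  multi_site = c("Nc1cccc(N)c1",          # two amine sites
                 "OC(=O)CCCC(=O)O"),      # two acid sites
  rejects = c("[13CH3]c1ccccc1",          # isotope label
              "CC[Sn](CC)CC",             # tin
              "COC(=O)C1CC2CN3CCc4c([nH]c5cc(OC)ccc45)C3CC2C(OC(=O)c2cc(OC)c(OC)c(OC)c2)C1OC"),  # over-complex
  twins = c(twin_free = "NCCc1c[nH]c2ccccc12",
            twin_protected = "NCCc1cn(C(=O)OC(C)(C)C)c2ccccc12"),
  clause_probes = c(carboxylic_acids = "O=CCCCC(=O)O",  # aldehyde on an acid
                    alcohols = "OCCc1ccc(O)cc1",        # phenol next to the alcohol
                    primary_amines = "NCCS",            # thiol on an amine
                    primary_amines2 = "NCCO",           # hydroxyl on an amine
                    boronic_acids = "OB(O)c1ccccn1",    # boron ortho to ring N
                    boronic_acids2 = "OB(O)c1ccncc1",   # 4-pyridyl boronic
                    primary_amines3 = "Nc1ccncc1")      # aminopyridine
)

#' Specify a toy building-block library
#'
#' Counts per functional-group class, the fraction of protected variants in
#' the classes that support protection (primary amines via Boc, acids via
#' tert-butyl ester, alcohols via benzoate), planted exclusion/rejection
#' cases, and the seed.  The defaults produce the ~190-block library used
#' throughout the package's own validation.
#'
#' @param carboxylic_acids,primary_amines,secondary_amines,aryl_bromides,boronic_acids,alkyl_bromides,azides,alkynes,alcohols,sulfonyl_chlorides,diketones_14,aryl_diamines,aldehydes,decoys
#'   Non-negative class counts.
#' @param frac_protected Fraction (0..1) of protected variants per
#'   protectable class (floor of fraction times count).
#' @param n_dual_role,n_multi_site,n_rejects Number of planted dual-role,
#'   multi-site and reject cases (at most 2, 2 and 3).
#' @param include_twins Plant the protected/unprotected twin pair used to
#'   demonstrate product convergence after deprotection.
#' @param include_probes Plant four blocks whose side groups trigger
#'   scoring clauses (aldehyde-acid, phenol-alcohol, thiol-amine,
#'   hydroxyl-amine).
#' @param seed Integer RNG seed.
#' @return Object of class `library_spec`.
#' @export
library_spec <- function(carboxylic_acids = 24, primary_amines = 24,
                         secondary_amines = 12, aryl_bromides = 16,
                         boronic_acids = 12, alkyl_bromides = 12,
                         azides = 10, alkynes = 10, alcohols = 16,
                         sulfonyl_chlorides = 10, diketones_14 = 8,
                         aryl_diamines = 8, aldehydes = 10, decoys = 8,
                         frac_protected = 0.2,
                         n_dual_role = 2, n_multi_site = 2, n_rejects = 3,
                         include_twins = TRUE, include_probes = TRUE,
                         seed = 20201111) {
  counts <- c(carboxylic_acids = carboxylic_acids,
              primary_amines = primary_amines,
              secondary_amines = secondary_amines,
              aryl_bromides = aryl_bromides, boronic_acids = boronic_acids,
              alkyl_bromides = alkyl_bromides, azides = azides,
              alkynes = alkynes, alcohols = alcohols,
              sulfonyl_chlorides = sulfonyl_chlorides,
              diketones_14 = diketones_14, aryl_diamines = aryl_diamines,
              aldehydes = aldehydes, decoys = decoys)
  if (any(counts < 0)) stop("class counts must be non-negative", call. = FALSE)
  if (frac_protected < 0 || frac_protected > 1)
    stop("frac_protected must be in [0, 1]", call. = FALSE)
  stopifnot(n_dual_role <= 2, n_multi_site <= 2, n_rejects <= 3)
  structure(list(counts = counts, frac_protected = frac_protected,
                 n_dual_role = n_dual_role, n_multi_site = n_multi_site,
                 n_rejects = n_rejects, include_twins = include_twins,
                 include_probes = include_probes, seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate a toy building-block library
#'
#' Deterministic for a given spec and seed.  Optionally writes the SMILES
#' file (`library.smi`) and the ground-truth table (`ground_truth.csv`) to
#' a directory.
#'
#' @param spec A [library_spec()].
#' @param dir Optional output directory.
#' @return Tibble with columns bb_id, smiles, class, planted_pg,
#'   planted_case.
#' @export
generate_library <- function(spec = library_spec(), dir = NULL) {
  stopifnot(inherits(spec, "library_spec"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  rows <- list()
  add_row <- function(smiles, class, pg = "", case = "none") {
    rows[[length(rows) + 1]] <<- list(smiles = smiles, class = class,
                                      planted_pg = pg, planted_case = case)
  }
  for (cls in names(spec$counts)) {
    n <- spec$counts[[cls]]
    if (n == 0) next
    cand <- .CLASS_CANDIDATES[[cls]]()
    if (n > length(cand))
      stop(sprintf("class %s: requested %d but only %d distinct candidates",
                   cls, n, length(cand)), call. = FALSE)
    chosen <- sample(cand, n)
    n_prot <- if (!is.null(.protect_variant(cls, "X")) || cls %in%
                  c("primary_amines", "carboxylic_acids", "alcohols"))
      floor(spec$frac_protected * n) else 0
    for (i in seq_len(n)) {
      if (i <= n_prot) {
        pv <- .protect_variant(cls, chosen[i])
        add_row(pv$smiles, cls, pg = pv$pg, case = "protected")
      } else {
        add_row(chosen[i], cls)
      }
    }
  }
  for (s in utils::head(.PLANTS$dual_role, spec$n_dual_role))
    add_row(s, "planted", case = "dual_role")
  for (s in utils::head(.PLANTS$multi_site, spec$n_multi_site))
    add_row(s, "planted", case = "multi_site")
  reject_cases <- c("reject_isotope", "reject_metal", "reject_complexity")
  for (i in seq_len(spec$n_rejects))
    add_row(.PLANTS$rejects[i], "planted", case = reject_cases[i])
  if (spec$include_twins) {
    add_row(.PLANTS$twins[["twin_free"]], "primary_amines", case = "twin_free")
    add_row(.PLANTS$twins[["twin_protected"]], "primary_amines",
            pg = "Boc", case = "twin_protected")
  }
  if (spec$include_probes) {
    probe_class <- c("carboxylic_acids", "alcohols", "primary_amines",
                     "primary_amines", "boronic_acids", "boronic_acids",
                     "primary_amines")
    for (i in seq_along(.PLANTS$clause_probes))
      add_row(.PLANTS$clause_probes[[i]], probe_class[i], case = "clause_probe")
  }
  out <- tibble::tibble(
    bb_id = sprintf("BB%04d", seq_along(rows)),
    smiles = vapply(rows, function(r) r$smiles, character(1)),
    class = vapply(rows, function(r) r$class, character(1)),
    planted_pg = vapply(rows, function(r) r$planted_pg, character(1)),
    planted_case = vapply(rows, function(r) r$planted_case, character(1))
  )
  if (anyDuplicated(out$smiles))
    out <- out[!duplicated(out$smiles), , drop = FALSE]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_smiles_file(out[, c("smiles", "bb_id")], file.path(dir, "library.smi"))
    utils::write.csv(out, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  out
}
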