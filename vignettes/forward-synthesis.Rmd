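---
title: "Forward-synthesis enumeration with scored expert-system rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-synthesis enumeration with scored expert-system rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthforge)
```

## The method

Most virtual screening libraries answer the question "does this molecule
bind?" long before anyone asks "can it be made?".  synthforge takes the
forward-synthetic route: start from a pool of purchasable building blocks
(BBs), apply a curated set of reaction *transforms* — each encoding one
well-understood laboratory chemistry — and keep only products whose
synthesis the rules consider plausible.  The output is a library in which
every member arrives with its one-step recipe: two catalog reactants, a
named chemistry, and a score expressing the rule author's confidence.

A transform couples:

* two **role patterns** (SMARTS), defining which BBs can act as reactant A
  and reactant B;
* a **product template** (SMIRKS), mapping one A-match plus one B-match to
  one product, with declared leaving groups;
* an ordered list of **scoring clauses**.  A clause tests a substructure
  (or a named property such as heavy-atom count) against one of three
  scopes — reactant A, reactant B, or the tentative product — and either
  ADDs to the reaction score, SUBTRACTs from it, or KILLs the reaction
  outright.  Values are qualitative expert judgments in increments of
  five, between 5 and 30.

For each transform the engine enumerates every A x B pair of role members,
applies the template, evaluates the clauses, and bins each surviving
reaction by its net clause score delta:

| class | condition |
|-------|-----------|
| Plus  | delta > 0 |
| Neg0  | 0 >= delta > -10 |
| Neg10 | -10 >= delta > -20 |
| Neg20 | -20 >= delta > -30 |
| Neg30 | delta <= -30 |

The binning rule is "Neg*n* with *n* the largest of 0/10/20/30 not
exceeding |delta|"; since clause values are multiples of five, a delta of
-5 is Neg0 and -15 is Neg10.  Whether a transform's intrinsic quality
(typical yield, reliability) should shift this classification is a real
design question; here the class is a function of the clause delta only,
and intrinsic quality stays in the rule's opaque metadata, because the
class is meant to express *structure-specific* risk on top of a chemistry
that was deemed good enough to ship in the rule set.

KILLed and failed reactions are not discarded silently: they go to an
audit log with the clause or failure reason, since collections of
computationally "failed" reactions are themselves useful (e.g. as negative
training data).

## Building-block preparation

Raw vendor SMILES pass through four stages:

1. **Standardization** — keep the largest organic fragment (dropping salts
   and counterions) and canonicalize.
2. **Filters** — reject explicit isotope labels, any element outside
   H/B/C/N/O/F/Si/P/S/Cl/Se/Br/I (boron and silicon stay: boronates and
   silanes are legitimate coupling partners), and structures whose Bertz
   complexity exceeds a cutoff (default 1200, roughly the point where a
   "building block" stops looking like one; configurable).
3. **Deduplication** — one record per *unique key*: the stereo-aware
   canonical SMILES of the canonical tautomer.  Enantiomers stay distinct;
   keto/enol forms of one compound collapse.  Tautomer canonicalization is
   run with stereo removal disabled so the key stays stereo-sensitive.
4. **Role assignment** — per transform, a BB matching *both* roles is
   excluded from both (reacting A with itself breeds polymers), and a BB
   matching one role at more than one site is excluded from that role
   (several products from one pair = an unusable mixture).  Dual-role
   exclusion is applied first.  A "site" is a distinct set of matched
   atoms: a symmetric pattern walking the same atoms in two orders is one
   site, but two chemically equivalent loci on a symmetric molecule (the
   two nitrogens of piperazine, the two amines of benzene-1,3-diamine)
   are two sites and exclude the block.  This is deliberately
   conservative: even when symmetry makes the two mono-products identical,
   the second free site survives into the product and invites
   over-reaction.

## Products, protecting groups, identity

Products are stored **deprotected**.  Seven protecting groups are
recognised (amine: Boc, Fmoc, Cbz; carboxyl: tert-butyl and benzyl
esters; hydroxyl: tert-butyl ether and benzoate); removal templates are
applied exhaustively, so deprotection is idempotent, and the product id
gets a `-DP` suffix (or `-UN` when no group was removed).  The as-generated
protected form is kept alongside.  BBs themselves are never modified — a
protected and an unprotected version of the same block are both allowed to
react, and their products converge to one unique key after deprotection;
both reaction records are kept (they are different syntheses), while
unique-product counting collapses them.

Product identity everywhere is the same stereo-aware, tautomer-invariant
key used for BB deduplication.  This matters inside the engine too: an
unsymmetric aryl-1,2-diamine condensed with an aldehyde yields the two
N–H tautomers of one benzimidazole depending on template orientation; the
engine recognises them as one product rather than auditing the pair as
ambiguous.

## The shipped rule set

Eight transforms re-express widely used coupling and ring-forming
chemistries: amide coupling, sulfonamide formation, biaryl cross-coupling
(bromide + boronic acid), ether synthesis, azide–alkyne cycloaddition,
aryl amination, pyrrole synthesis from 1,4-diketones, and benzimidazole
condensation — the last three ring-forming.  Clauses encode standard
practical knowledge: primary aliphatic amines couple cleanly (ADD),
anilines are slower (SUBTRACT), aldehydes on an acid partner divert the
amine (KILL), thiols poison palladium (KILL), basic heteroaryl boronic
acids protodeboronate (SUBTRACT 20, worse when boron sits next to the
ring nitrogen), and so on.  They are qualitative judgments, not fitted
parameters.  The file format is YAML with a published JSON Schema
(`inst/schema/transforms.schema.json`); users can ship their own rule
files.

## The fixture generator

`generate_library()` emulates a vendor BB pool at desk scale
(~190 blocks by default): counts per functional-group class, a protected
fraction (default 20% of amines/acids/alcohols, as Boc / tert-butyl ester /
benzoate respectively), inert decoys, planted dual-role and multi-site
exclusion cases, three planted rejects (isotope, tin, an over-complex
natural-product-like structure), a protected/unprotected twin pair, and
six "clause probes" — blocks like 2-pyridylboronic acid or an
aldehyde-bearing acid whose side groups deterministically fire specific
ADD/SUBTRACT/KILL clauses so every score class is exercised.  Molecules
are assembled from a fixed pool of simple scaffolds and inert decorations,
so validity is guaranteed by construction and the seed only selects which
candidates appear.

What the toy pool does *not* emulate: the property distributions, salt
forms, stereochemical richness or sheer scale of a real catalog.  Green
tests therefore demonstrate the correctness of the machinery (exclusion
logic, clause arithmetic, bookkeeping identities, determinism), not the
chemical realism of any particular score.

## Library-level analytics

For N building blocks and T two-reactant transforms the theoretical
maximum is N²/2 · T (unordered pairs).  The package reports the
success ratio (theoretical max / saved), the KILL loss rate
(1 − saved/tested), and a SAR-neighbor estimate: projecting saved products
onto the flattened triangular N x N matrix with fill f = saved/(N²/2), a
product has on average f · N neighbors sharing one building block.  With
the published production-run inputs (143,365 matched BBs, 1.75 · 10⁹
saved) the formula gives ≈ 2.44 · 10⁴; the originally reported "about
24,800" is slightly above the value implied by its own printed
intermediates, and this package reports the formula result.

The ring-system census treats a ring system as a connected component of
ring atoms and ring bonds — fused and spiro assemblies are one unit —
identified by the canonical SMILES of that substructure.  Exocyclic
substituents, including carbonyl oxygens on a ring, are excluded; this is
one of several defensible boundaries and is fixed here so counts are
comparable across runs.  Database overlap is an exact set intersection of
unique keys, meaningful only when both sides use the same
canonicalization.

Display conventions are fixed to match how such bookkeeping is usually
printed: class shares to two decimals, the success ratio to two
significant figures, the theoretical maximum to the nearest billion.

## Annotation

Each product can be annotated with: molecular weight, atom-contribution
(Crippen) logP — a documented, reproducible substitute for proprietary
logP models — TPSA, fraction of sp³ carbons, rotatable bonds, Lipinski
H-bond donors/acceptors, rule-of-five violations (mw > 500, logp > 5,
hbd > 5, hba > 10), rule-of-three violations (mw > 300, logp > 3,
hbd > 3, rotb > 3, tpsa > 60), PAINS alert counts from the published
catalog, QED, and an additive demerit score.  QED is computed in the
package as the published weighted geometric mean of eight
desirability-transformed descriptors, and cross-checked in the test suite
against an independent implementation to 10⁻³.  The demerit framework
loads any rule file of (SMARTS, value) pairs and reports strict (<100)
and loose (<160) pass flags; the shipped file is a small representative
subset written for this package (hence its `_synthetic` name), not the
full published 275-rule set.

## Numerical and engineering choices

* **Chemistry backend.** All molecular primitives run in RDKit through a
  batch JSON subprocess (`chem_call()`), one process per pipeline stage
  rather than per molecule.  Results are pure functions of canonical
  structures, so runs are deterministic and byte-identical given identical
  inputs.
* **Problem sizes.** The default validation library (~190 blocks, 8 rules,
  ~2,500 tested pairs, ~2,400 saved reactions) was chosen as the smallest
  pool in which every rule, every exclusion path, every protecting group
  and every score class occurs; the full suite and the acceptance script
  each complete in about a minute on one core.
* **Degenerate inputs.** Unparseable SMILES become explicit
  `parse_error` records; single-reaction failures (template misfire,
  unsanitizable product) are audited and never abort a run; an empty rule
  file is an empty library.
* **Aromatic N–H restoration.** Removing a carbamate from an indole-type
  nitrogen leaves an aromatic nitrogen without its hydrogen; the backend
  restores the H (five-membered-ring nitrogens only, and only when
  sanitization fails without it) before canonicalization.
* **Ambiguity as an assertion.** After multi-site exclusion each pair can
  yield at most one product (up to tautomer identity); if a template ever
  produces several distinct structures the engine audits the pair as
  `ambiguous_product` instead of guessing.

## Known limitations

Single-step, two-reactant chemistry only; no intramolecular application of
coupling rules (polymer/macrocycle risk is handled by exclusion, not
modelling); the clause vocabulary covers substructure tests and three
named properties, not computed electronic properties; the shipped demerit
set is representative, not complete; and scores remain qualitative expert
judgments — a Plus class label is a statement about rule-encoded
knowledge, not a yield prediction.
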