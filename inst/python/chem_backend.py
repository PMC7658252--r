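#!/usr/bin/env python
"""Batch chemistry backend for the synthforge R package.

Called as:  python chem_backend.py <task> <input.json> <output.json>

Every task reads one JSON payload and writes one JSON result, so a whole
vector of molecules is processed per process invocation.  All heavy
cheminformatics (parsing, canonicalisation, substructure matching, reaction
application, descriptors) is delegated to RDKit; the R side owns the
rule semantics, scoring arithmetic and library bookkeeping.
"""

import json
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import AllChem, Crippen, QED, Descriptors, rdMolDescriptors
from rdkit.Chem import GraphDescriptors, FilterCatalog
from rdkit.Chem.MolStandardize import rdMolStandardize

rdBase.DisableLog("rdApp.*")

# Elements permitted in building blocks; B and Si retained because boronate
# and silane reactants are legitimate coupling partners.
ALLOWED_ELEMENTS = {"H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I"}

_tautomer_enumerator = None
_largest_fragment = None
_pains_catalog = None


def _scalar(x):
    if isinstance(x, (list, tuple)):
        return x[0] if x else None
    return x


def _ensure_list(x):
    if x is None:
        return []
    if isinstance(x, (list, tuple)):
        return list(x)
    return [x]


def _te():
    global _tautomer_enumerator
    if _tautomer_enumerator is None:
        # keep stereo through tautomer canonicalization: the unique key must
        # be stereo-sensitive (enantiomers distinct) yet tautomer-invariant
        params = rdMolStandardize.CleanupParameters()
        params.tautomerRemoveSp3Stereo = False
        params.tautomerRemoveBondStereo = False
        _tautomer_enumerator = rdMolStandardize.TautomerEnumerator(params)
    return _tautomer_enumerator


def _lfc():
    global _largest_fragment
    if _largest_fragment is None:
        _largest_fragment = rdMolStandardize.LargestFragmentChooser()
    return _largest_fragment


def _pains():
    global _pains_catalog
    if _pains_catalog is None:
        params = FilterCatalog.FilterCatalogParams()
        params.AddCatalog(FilterCatalog.FilterCatalogParams.FilterCatalogs.PAINS)
        _pains_catalog = FilterCatalog.FilterCatalog(params)
    return _pains_catalog


def unique_key(mol):
    """Stereo-aware canonical SMILES of the canonical tautomer."""
    canon = _te().Canonicalize(mol)
    return Chem.MolToSmiles(canon)


def _fix_aromatic_nh(mol):
    """Restore the H on a five-ring nitrogen left naked by a template
    application (e.g. removal of a carbamate from an indole-type nitrogen).
    Six-ring pyridine-type nitrogens carry no H and are left alone."""
    Chem.FastFindRings(mol)
    for atom in mol.GetAtoms():
        if (atom.GetAtomicNum() == 7 and atom.GetIsAromatic()
                and atom.IsInRingSize(5)
                and atom.GetDegree() == 2 and atom.GetNumExplicitHs() == 0
                and atom.GetFormalCharge() == 0):
            atom.SetNumExplicitHs(1)


def _sanitize_product(mol):
    probe = Chem.Mol(mol)
    try:
        Chem.SanitizeMol(probe)
        return Chem.MolToSmiles(probe)
    except Exception:  # noqa: BLE001 - retry with the N-H fixup
        fixed = Chem.Mol(mol)
        _fix_aromatic_nh(fixed)
        Chem.SanitizeMol(fixed)
        return Chem.MolToSmiles(fixed)


def task_standardize(payload):
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        rec = {"ok": False, "error": None, "smiles_std": None, "key": None,
               "n_fragments": None, "has_isotope": None, "has_metal": None,
               "complexity": None, "heavy_atoms": None}
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            rec["error"] = "parse_error"
            out.append(rec)
            continue
        try:
            rec["n_fragments"] = len(Chem.GetMolFrags(mol))
            frag = _lfc().choose(mol)
            frag = rdMolStandardize.Cleanup(frag)
            rec["smiles_std"] = Chem.MolToSmiles(frag)
            rec["key"] = unique_key(frag)
            rec["has_isotope"] = any(a.GetIsotope() != 0 for a in frag.GetAtoms())
            rec["has_metal"] = any(a.GetSymbol() not in ALLOWED_ELEMENTS
                                   for a in frag.GetAtoms())
            rec["complexity"] = GraphDescriptors.BertzCT(frag)
            rec["heavy_atoms"] = frag.GetNumHeavyAtoms()
            rec["ok"] = True
        except Exception as exc:  # noqa: BLE001 - report, never abort the batch
            rec["error"] = "standardize_failed: %s" % exc
        out.append(rec)
    return {"records": out}


def task_keys(payload):
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        out.append(None if mol is None else unique_key(mol))
    return {"keys": out}


def task_canonical(payload):
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        out.append(None if mol is None else Chem.MolToSmiles(mol))
    return {"smiles": out}


def task_parse_check(payload):
    smarts_res = []
    for s in _ensure_list(payload.get("smarts")):
        ok = Chem.MolFromSmarts(s) is not None
        smarts_res.append({"pattern": s, "ok": ok})
    smirks_res = []
    for s in _ensure_list(payload.get("smirks")):
        try:
            rxn = AllChem.ReactionFromSmarts(s)
            ok = rxn is not None
            err = None
        except Exception as exc:  # noqa: BLE001
            ok, err = False, str(exc)
        smirks_res.append({"pattern": s, "ok": ok, "error": err})
    return {"smarts": smarts_res, "smirks": smirks_res}


def task_match(payload):
    """sites[i][j]: number of distinct matched atom sets of pattern i in
    molecule j (RDKit uniquify collapses order-only duplicate matches)."""
    patterns = []
    for p in _ensure_list(payload.get("patterns")):
        q = Chem.MolFromSmarts(p)
        if q is None:
            return {"error": "invalid pattern: %s" % p}
        patterns.append(q)
    mols = [Chem.MolFromSmiles(s) if isinstance(s, str) else None
            for s in _ensure_list(payload.get("smiles"))]
    sites = []
    for q in patterns:
        row = []
        for m in mols:
            if m is None:
                row.append(None)
            else:
                row.append(len(m.GetSubstructMatches(q, uniquify=True)))
        sites.append(row)
    return {"sites": sites}


def task_match_all(payload):
    """All raw substructure matches (no uniquify) as atom-index tuples;
    used by test oracles that re-derive site counts independently."""
    out = []
    q = Chem.MolFromSmarts(_scalar(payload["pattern"]))
    if q is None:
        return {"error": "invalid pattern"}
    for smi in _ensure_list(payload.get("smiles")):
        m = Chem.MolFromSmiles(smi)
        if m is None:
            out.append(None)
        else:
            out.append([list(t) for t in m.GetSubstructMatches(q, uniquify=False,
                                                               maxMatches=10000)])
    return {"matches": out}


def task_smirks_info(payload):
    out = []
    for s in _ensure_list(payload.get("smirks")):
        try:
            rxn = AllChem.ReactionFromSmarts(s)
            reactant_maps, n_react_atoms = set(), 0
            templ_atoms = []
            for i in range(rxn.GetNumReactantTemplates()):
                t = rxn.GetReactantTemplate(i)
                templ_atoms.append(t.GetNumAtoms())
                n_react_atoms += t.GetNumAtoms()
                for a in t.GetAtoms():
                    if a.GetAtomMapNum():
                        reactant_maps.add(a.GetAtomMapNum())
            carried, added = 0, 0
            for i in range(rxn.GetNumProductTemplates()):
                t = rxn.GetProductTemplate(i)
                for a in t.GetAtoms():
                    if a.GetAtomMapNum() and a.GetAtomMapNum() in reactant_maps:
                        carried += 1
                    else:
                        added += 1
            out.append({"ok": True,
                        "n_reactant_templates": rxn.GetNumReactantTemplates(),
                        "reactant_template_atoms": templ_atoms,
                        "dropped_atoms": n_react_atoms - carried,
                        "added_atoms": added})
        except Exception as exc:  # noqa: BLE001
            out.append({"ok": False, "error": str(exc)})
    return {"records": out}


def task_react(payload):
    rxn = AllChem.ReactionFromSmarts(_scalar(payload["smirks"]))
    out = []
    for pair in _ensure_list(payload.get("pairs")):
        a, b = pair
        ma, mb = Chem.MolFromSmiles(a), Chem.MolFromSmiles(b)
        if ma is None or mb is None:
            out.append({"ok": False, "error": "parse_error", "products": []})
            continue
        try:
            prods = rxn.RunReactants((ma, mb))
        except Exception:  # noqa: BLE001
            out.append({"ok": False, "error": "reaction_failed", "products": []})
            continue
        if not prods:
            out.append({"ok": False, "error": "no_product", "products": []})
            continue
        # products that are tautomers of each other (two template
        # orientations on an unsymmetric reactant) are one compound:
        # deduplicate on the tautomer-invariant key
        good, sanit_fail = {}, False
        for ptuple in prods:
            try:
                smi_p = _sanitize_product(ptuple[0])
                key = unique_key(Chem.MolFromSmiles(smi_p))
                if key not in good or smi_p < good[key]:
                    good[key] = smi_p
            except Exception:  # noqa: BLE001
                sanit_fail = True
        if good:
            out.append({"ok": True, "error": None,
                        "products": sorted(good.values())})
        else:
            out.append({"ok": False,
                        "error": "sanitization_failed" if sanit_fail else "no_product",
                        "products": []})
    return {"records": out}


def _pg_rxns(pgs):
    parsed = []
    for pg in pgs:
        q = Chem.MolFromSmarts(pg["smarts"])
        rxn = AllChem.ReactionFromSmarts(pg["removal_smirks"])
        parsed.append((pg["label"], q, rxn))
    return parsed


def task_detect_pgs(payload):
    parsed = _pg_rxns(payload["pgs"])
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        m = Chem.MolFromSmiles(smi)
        if m is None:
            out.append(None)
            continue
        hits = []
        for label, q, _ in parsed:
            # attachment atom = query atom carrying map number 1
            anchor = next((a.GetIdx() for a in q.GetAtoms() if a.GetAtomMapNum() == 1), 0)
            for match in m.GetSubstructMatches(q, uniquify=True):
                hits.append({"label": label, "site": match[anchor]})
        out.append(hits)
    return {"records": out}


def task_deprotect(payload):
    parsed = _pg_rxns(payload["pgs"])
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        m = Chem.MolFromSmiles(smi)
        if m is None:
            out.append({"ok": False, "error": "parse_error",
                        "smiles_free": None, "removed": []})
            continue
        removed, err = [], None
        changed = True
        iters = 0
        while changed and iters < 50:
            changed = False
            iters += 1
            for label, q, rxn in parsed:
                if not m.HasSubstructMatch(q):
                    continue
                prods = rxn.RunReactants((m,))
                nxt = None
                for ptuple in prods:
                    try:
                        smi_p = _sanitize_product(ptuple[0])
                        nxt = Chem.MolFromSmiles(smi_p)
                        break
                    except Exception:  # noqa: BLE001
                        continue
                if nxt is None:
                    err = "removal_failed:%s" % label
                    break
                m = nxt
                removed.append(label)
                changed = True
            if err:
                break
        if err:
            out.append({"ok": False, "error": err, "smiles_free": None,
                        "removed": removed})
        else:
            out.append({"ok": True, "error": None,
                        "smiles_free": Chem.MolToSmiles(m), "removed": removed})
    return {"records": out}


def task_descriptors(payload):
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        try:
            qp = QED.properties(mol)
            out.append({
                "ok": True,
                "mw": Descriptors.MolWt(mol),
                "logp": Crippen.MolLogP(mol),
                "tpsa": rdMolDescriptors.CalcTPSA(mol),
                "fsp3": rdMolDescriptors.CalcFractionCSP3(mol),
                "rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(mol),
                "hbd": rdMolDescriptors.CalcNumLipinskiHBD(mol),
                "hba": rdMolDescriptors.CalcNumLipinskiHBA(mol),
                "heavy_atoms": mol.GetNumHeavyAtoms(),
                "ring_count": rdMolDescriptors.CalcNumRings(mol),
                "net_charge": Chem.GetFormalCharge(mol),
                # inputs of the QED desirability model (its own HBA/HBD defs)
                "qed_mw": qp.MW, "qed_alogp": qp.ALOGP, "qed_hba": qp.HBA,
                "qed_hbd": qp.HBD, "qed_psa": qp.PSA, "qed_rotb": qp.ROTB,
                "qed_arom": qp.AROM, "qed_alerts": qp.ALERTS,
            })
        except Exception as exc:  # noqa: BLE001
            out.append({"ok": False, "error": str(exc)})
    return {"records": out}


def task_pains(payload):
    cat = _pains()
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append({"ok": False, "count": None, "entries": []})
            continue
        matches = cat.GetMatches(mol)
        out.append({"ok": True, "count": len(matches),
                    "entries": [e.GetDescription() for e in matches]})
    return {"records": out}


def task_qed_reference(payload):
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        out.append(None if mol is None else QED.qed(mol))
    return {"qed": out}


def task_ring_systems(payload):
    """Ring systems = connected components of ring atoms/bonds (fused and
    spiro systems are one unit); exocyclic atoms are excluded."""
    out = []
    for smi in _ensure_list(payload.get("smiles")):
        mol = Chem.MolFromSmiles(smi) if isinstance(smi, str) else None
        if mol is None:
            out.append(None)
            continue
        ri = mol.GetRingInfo()
        ring_bonds = set()
        for br in ri.BondRings():
            ring_bonds.update(br)
        if not ring_bonds:
            out.append([])
            continue
        # union-find over ring atoms connected by ring bonds
        parent = {}

        def find(x):
            while parent[x] != x:
                parent[x] = parent[parent[x]]
                x = parent[x]
            return x

        def union(x, y):
            parent.setdefault(x, x)
            parent.setdefault(y, y)
            rx, ry = find(x), find(y)
            if rx != ry:
                parent[rx] = ry

        for bidx in ring_bonds:
            b = mol.GetBondWithIdx(bidx)
            union(b.GetBeginAtomIdx(), b.GetEndAtomIdx())
        comps = {}
        for bidx in ring_bonds:
            b = mol.GetBondWithIdx(bidx)
            root = find(b.GetBeginAtomIdx())
            comps.setdefault(root, {"atoms": set(), "bonds": []})
            comps[root]["atoms"].update([b.GetBeginAtomIdx(), b.GetEndAtomIdx()])
            comps[root]["bonds"].append(bidx)
        systems = []
        for comp in comps.values():
            smi_sys = Chem.MolFragmentToSmiles(mol, atomsToUse=sorted(comp["atoms"]),
                                               bondsToUse=comp["bonds"],
                                               canonical=True)
            systems.append(smi_sys)
        out.append(sorted(systems))
    return {"records": out}


def task_write_sdf(payload):
    writer = Chem.SDWriter(_scalar(payload["path"]))
    n = 0
    for rec in _ensure_list(payload.get("records")):
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            continue
        if rec.get("id"):
            mol.SetProp("_Name", str(rec["id"]))
        for k, v in (rec.get("props") or {}).items():
            mol.SetProp(str(k), "" if v is None else str(v))
        writer.write(mol)
        n += 1
    writer.close()
    return {"written": n}


TASKS = {
    "standardize": task_standardize,
    "keys": task_keys,
    "canonical": task_canonical,
    "parse_check": task_parse_check,
    "match": task_match,
    "match_all": task_match_all,
    "smirks_info": task_smirks_info,
    "react": task_react,
    "detect_pgs": task_detect_pgs,
    "deprotect": task_deprotect,
    "descriptors": task_descriptors,
    "pains": task_pains,
    "qed_reference": task_qed_reference,
    "ring_systems": task_ring_systems,
    "write_sdf": task_write_sdf,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chem_backend.py <task> <in.json> <out.json>\n")
        return 2
    task = argv[1]
    if task not in TASKS:
        sys.stderr.write("unknown task: %s\n" % task)
        return 2
    with open(argv[2]) as fh:
        payload = json.load(fh)
    result = TASKS[task](payload)
    with open(argv[3], "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
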