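"""Batch chemistry backend: reaction application, canonicalization and
descriptors via RDKit.  Invoked as

    python chem_backend.py <request.json> <response.json>

Request: {"op": "react"|"canonicalize"|"descriptors", ...}.  All results
are returned positionally, one entry per input; per-item failures are
reported in-band, never as a nonzero exit.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")

DESCRIPTORS = {
    "mw": Descriptors.MolWt,
    "heavy_atoms": lambda m: m.GetNumHeavyAtoms(),
    "ring_count": lambda m: Chem.rdMolDescriptors.CalcNumRings(m),
    "logp": Descriptors.MolLogP,
    "tpsa": Descriptors.TPSA,
    "hbd": Descriptors.NumHDonors,
    "hba": Descriptors.NumHAcceptors,
}


def parse(smiles):
    return Chem.MolFromSmiles(smiles) if smiles else None


def canonical(mol):
    return Chem.MolToSmiles(mol)


def op_canonicalize(req):
    out = []
    for smi in req["smiles"]:
        mol = parse(smi)
        out.append({"smiles": canonical(mol) if mol else None,
                    "error": None if mol else f"unparsable SMILES: {smi!r}"})
    return out


def op_descriptors(req):
    names = req["descriptors"]
    unknown = [n for n in names if n not in DESCRIPTORS]
    if unknown:
        return {"fatal": f"unknown descriptor(s): {', '.join(unknown)}; "
                         f"known: {', '.join(sorted(DESCRIPTORS))}"}
    out = []
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            out.append({"error": f"unparsable SMILES: {smi!r}"})
        else:
            out.append({n: DESCRIPTORS[n](mol) for n in names})
    return out


def op_react(req):
    rxn_cache = {}
    out = []
    for task in req["tasks"]:
        smirks = task["smirks"]
        if smirks == "identity":
            mol = parse(task["lhs"])
            out.append({"smiles": canonical(mol) if mol else None,
                        "n_products": 1,
                        "error": None if mol else f"unparsable SMILES: {task['lhs']!r}"})
            continue
        if smirks not in rxn_cache:
            try:
                rxn = AllChem.ReactionFromSmarts(smirks)
                if rxn is None or rxn.GetNumReactantTemplates() != 2:
                    raise ValueError("transform must take exactly two reactants")
                rxn_cache[smirks] = rxn
            except Exception as exc:  # noqa: BLE001 - report any parse failure
                return {"fatal": f"unparsable transform {smirks!r}: {exc}"}
        rxn = rxn_cache[smirks]
        lhs, rhs = parse(task["lhs"]), parse(task["rhs"])
        if lhs is None or rhs is None:
            bad = task["lhs"] if lhs is None else task["rhs"]
            out.append({"smiles": None, "n_products": 0,
                        "error": f"unparsable SMILES: {bad!r}"})
            continue
        products = set()
        for prod_tuple in rxn.RunReactants((lhs, rhs)):
            for prod in prod_tuple:
                try:
                    Chem.SanitizeMol(prod)
                    products.add(canonical(prod))
                except Exception:  # noqa: BLE001 - skip unsanitizable products
                    pass
        if not products:
            out.append({"smiles": None, "n_products": 0,
                        "error": "no product: reactants do not match the transform"})
        else:
            # deterministic: first product in canonical-SMILES order
            out.append({"smiles": sorted(products)[0],
                        "n_products": len(products), "error": None})
    return out


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    op = {"react": op_react, "canonicalize": op_canonicalize,
          "descriptors": op_descriptors}[req["op"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(op(req), fh)


if __name__ == "__main__":
    main()
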