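"""RDKit bridge for the chemcheck R package.

Reads a JSON request from the file named in argv[1] and writes a JSON
response to the file named in argv[2].  The request is a list of ops, each a
dict with an "op" key; the response is a list of result dicts in the same
order.  All atom indices exchanged with R are 1-based.

Molecules arrive as V2000 molblocks.  They are loaded without sanitization
and then sanitized with the PROPERTIES (valence check) and CLEANUP steps
disabled: records under validation are frequently valence-invalid on
purpose, and CLEANUP would rewrite as-drawn hypervalent nitrogens
(N#N=N, N(=O)=O) into charge-separated forms, hiding exactly the depictions
the dictionary rules look for.  Aromaticity perception and kekulization do
run, so SMARTS aromaticity semantics behave normally.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, inchi

RDLogger.DisableLog("rdApp.*")

SANITIZE_FLAGS = (
    Chem.SANITIZE_ALL ^ Chem.SANITIZE_PROPERTIES ^ Chem.SANITIZE_CLEANUP
)


def load_molblock(molblock):
    """Return (mol, error_string). mol is None on hard parse failure."""
    mol = Chem.MolFromMolBlock(molblock, sanitize=False, removeHs=False)
    if mol is None:
        return None, "molblock parse failed"
    try:
        mol.UpdatePropertyCache(strict=False)
        Chem.SanitizeMol(mol, SANITIZE_FLAGS)
    except Exception as exc:  # kekulization / aromaticity failure
        return None, "%s: %s" % (type(exc).__name__, exc)
    return mol, None


def op_analyze(req):
    """Match a list of SMARTS patterns and optionally generate an InChI."""
    out = {"ok": True, "error": None, "matches": {}, "inchi": None,
           "inchi_error": None}
    mol, err = load_molblock(req["molblock"])
    if mol is None:
        out["ok"] = False
        out["error"] = err
        return out
    for pattern in req.get("patterns", []):
        query = Chem.MolFromSmarts(pattern)
        if query is None:
            out["matches"][pattern] = {"ok": False, "hits": []}
            continue
        hits = mol.GetSubstructMatches(query, uniquify=True, maxMatches=2000)
        out["matches"][pattern] = {
            "ok": True,
            "hits": [[i + 1 for i in hit] for hit in hits],
        }
    if req.get("want_inchi", False):
        try:
            val = inchi.MolToInchi(mol, treatWarningAsError=False)
            if not val:
                out["inchi_error"] = "InChI generation returned empty string"
            else:
                out["inchi"] = val
        except Exception as exc:
            out["inchi_error"] = "%s: %s" % (type(exc).__name__, exc)
    return out


def op_smiles_to_molblock(req):
    mol = Chem.MolFromSmiles(req["smiles"])
    if mol is None:
        return {"ok": False, "molblock": None, "error": "SMILES parse failed"}
    try:
        molblock = Chem.MolToMolBlock(mol, kekulize=True)
    except Exception as exc:
        return {"ok": False, "molblock": None,
                "error": "%s: %s" % (type(exc).__name__, exc)}
    return {"ok": True, "molblock": molblock, "error": None}


def op_validate_smarts(req):
    return {"ok": [Chem.MolFromSmarts(p) is not None
                   for p in req["patterns"]]}


def op_validate_smirks(req):
    results = []
    for s in req["smirks"]:
        try:
            rxn = AllChem.ReactionFromSmarts(s)
            results.append(rxn is not None)
        except Exception:
            results.append(False)
    return {"ok": results}


def _query_charge(atom):
    """Formal charge demanded by a query atom.  GetFormalCharge() is only
    set for simple charge primitives; composite queries like [N;H;-] need a
    walk of the query tree (DescribeQuery lists AtomFormalCharge nodes)."""
    import re
    desc = atom.DescribeQuery()
    hits = re.findall(r"AtomFormalCharge (-?\d+)", desc)
    if hits:
        return int(hits[0])
    return atom.GetFormalCharge()


def op_query_charge_diff(req):
    """Positions (1-based, pattern atom order) where the formal charge of
    the acid and base SMARTS differ.  Used to locate the proton-bearing atom
    of an acid/base pair."""
    acid = Chem.MolFromSmarts(req["acid"])
    base = Chem.MolFromSmarts(req["base"])
    if acid is None or base is None:
        return {"ok": False, "error": "SMARTS parse failed", "positions": []}
    if acid.GetNumAtoms() != base.GetNumAtoms():
        return {"ok": False, "error": "acid/base atom counts differ",
                "positions": []}
    positions = []
    for i in range(acid.GetNumAtoms()):
        ca = _query_charge(acid.GetAtomWithIdx(i))
        cb = _query_charge(base.GetAtomWithIdx(i))
        if ca != cb:
            positions.append({"pos": i + 1, "acid_charge": ca,
                              "base_charge": cb})
    return {"ok": True, "error": None, "positions": positions}


def op_stereocenters(req):
    """Potential/assigned tetrahedral stereocenters (independent oracle for
    the R-side symmetry analysis; used by the test suite)."""
    mol = Chem.MolFromMolBlock(req["molblock"], sanitize=True)
    if mol is None:
        return {"ok": False, "centers": []}
    centers = Chem.FindMolChiralCenters(
        mol, includeUnassigned=True, useLegacyImplementation=False)
    return {"ok": True,
            "centers": [{"atom": idx + 1, "label": lab}
                        for idx, lab in centers]}


def op_version(req):
    import rdkit
    return {"rdkit": rdkit.__version__,
            "inchi": inchi.INCHI_AVAILABLE and "standard (RDKit bundled)"}


HANDLERS = {
    "analyze": op_analyze,
    "smiles_to_molblock": op_smiles_to_molblock,
    "validate_smarts": op_validate_smarts,
    "validate_smirks": op_validate_smirks,
    "query_charge_diff": op_query_charge_diff,
    "stereocenters": op_stereocenters,
    "version": op_version,
}


def main():
    with open(sys.argv[1]) as fh:
        ops = json.load(fh)
    results = []
    for op in ops:
        handler = HANDLERS.get(op.get("op"))
        if handler is None:
            results.append({"ok": False,
                            "error": "unknown op %r" % op.get("op")})
            continue
        try:
            results.append(handler(op))
        except Exception as exc:
            results.append({"ok": False,
                            "error": "%s: %s" % (type(exc).__name__, exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
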