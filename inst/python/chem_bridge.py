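"""Batched chemistry backend for the ic50net R package.

Reads a JSON request {op, smiles: [...], options: {...}} from argv[1] and
writes a JSON list (one entry per input SMILES) to argv[2].  All chemistry
goes through RDKit; every entry carries ok/error so one bad molecule never
aborts a batch.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

BOND_TYPE_CODE = {
    Chem.BondType.SINGLE: 1,
    Chem.BondType.DOUBLE: 2,
    Chem.BondType.TRIPLE: 3,
    Chem.BondType.AROMATIC: 4,
}

# Fixed physicochemical descriptor registry: 32 names, fixed order.
PHYSCHEM = [
    ("MW", lambda m: Descriptors.MolWt(m)),
    ("LogP", lambda m: Descriptors.MolLogP(m)),
    ("TPSA", lambda m: Descriptors.TPSA(m)),
    ("HBD", lambda m: Descriptors.NumHDonors(m)),
    ("HBA", lambda m: Descriptors.NumHAcceptors(m)),
    ("RotB", lambda m: Descriptors.NumRotatableBonds(m)),
    ("ArR", lambda m: Descriptors.NumAromaticRings(m)),
    ("AlR", lambda m: Descriptors.NumAliphaticRings(m)),
    ("SatR", lambda m: Descriptors.NumSaturatedRings(m)),
    ("Rings", lambda m: Descriptors.RingCount(m)),
    ("FCsp3", lambda m: Descriptors.FractionCSP3(m)),
    ("HA", lambda m: Descriptors.HeavyAtomCount(m)),
    ("SC", lambda m: rdMolDescriptors.CalcNumAtomStereoCenters(m)),
    ("FC", lambda m: Chem.GetFormalCharge(m)),
    ("Het", lambda m: Descriptors.NumHeteroatoms(m)),
    ("Ve", lambda m: Descriptors.NumValenceElectrons(m)),
    ("MR", lambda m: Descriptors.MolMR(m)),
    ("Kappa1", lambda m: Descriptors.Kappa1(m)),
    ("Kappa2", lambda m: Descriptors.Kappa2(m)),
    ("Kappa3", lambda m: Descriptors.Kappa3(m)),
    ("BertzCT", lambda m: Descriptors.BertzCT(m)),
    ("BHA", lambda m: rdMolDescriptors.CalcNumBridgeheadAtoms(m)),
    ("Spiro", lambda m: rdMolDescriptors.CalcNumSpiroAtoms(m)),
    ("ArHet", lambda m: Descriptors.NumAromaticHeterocycles(m)),
    ("SatHet", lambda m: Descriptors.NumSaturatedHeterocycles(m)),
    ("AlHet", lambda m: Descriptors.NumAliphaticHeterocycles(m)),
    ("AmideB", lambda m: rdMolDescriptors.CalcNumAmideBonds(m)),
    ("HallKierAlpha", lambda m: Descriptors.HallKierAlpha(m)),
    ("LabuteASA", lambda m: Descriptors.LabuteASA(m)),
    ("BalabanJ", lambda m: Descriptors.BalabanJ(m)),
    ("Chi0v", lambda m: Descriptors.Chi0v(m)),
    ("Chi1v", lambda m: Descriptors.Chi1v(m)),
]

PHYSCHEM_NAMES = [name for name, _ in PHYSCHEM]

FP_BITS = 512
FP_RADIUS = 2


def parse(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparsable SMILES: %r" % smiles)
    return mol


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) == 1:
        return mol, 1
    best = max(frags, key=lambda f: f.GetNumHeavyAtoms())
    return best, len(frags)


def op_canonicalize(smiles, options):
    mol = parse(smiles)
    n_frags = 1
    if options.get("largest_fragment", False):
        mol, n_frags = largest_fragment(mol)
    return {"ok": True, "canonical": Chem.MolToSmiles(mol), "n_frags": n_frags}


def smallest_ring_size(ring_info, idx):
    sizes = [len(r) for r in ring_info.AtomRings() if idx in r]
    return min(sizes) if sizes else 0


def op_featurize(smiles, options):
    mol = parse(smiles)
    if mol.GetNumHeavyAtoms() == 0:
        raise ValueError("molecule has no heavy atoms: %r" % smiles)

    physchem = []
    for name, fn in PHYSCHEM:
        try:
            physchem.append(float(fn(mol)))
        except Exception as exc:  # noqa: BLE001 - reported upward by name
            raise ValueError("descriptor %s failed on %r: %s" % (name, smiles, exc))
    fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(mol, FP_RADIUS, nBits=FP_BITS)

    # CIP assignment rewrites stereo perception state, so it runs after the
    # descriptor block
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    ring_info = mol.GetRingInfo()

    element, hyb, feats = [], [], []
    for atom in mol.GetAtoms():
        element.append(atom.GetSymbol())
        hyb.append(str(atom.GetHybridization()))
        cip = atom.GetPropsAsDict().get("_CIPCode", "")
        feats.append([
            atom.GetAtomicNum(),
            atom.GetDegree(),
            atom.GetFormalCharge(),
            atom.GetTotalNumHs(),
            int(atom.GetIsAromatic()),
            int(atom.IsInRing()),
            int(cip == "R"),
            int(cip == "S"),
            smallest_ring_size(ring_info, atom.GetIdx()),
            atom.GetTotalValence(),
        ])

    src, dst, bfeat = [], [], []
    for bond in mol.GetBonds():
        src.append(bond.GetBeginAtomIdx())
        dst.append(bond.GetEndAtomIdx())
        bfeat.append([
            BOND_TYPE_CODE.get(bond.GetBondType(), 0),
            int(bond.GetIsConjugated()),
            int(bond.IsInRing()),
            int(bond.GetIsAromatic()),
            int(bond.GetStereo()),
        ])

    mol_size = sum(a.GetAtomicNum() for a in mol.GetAtoms())

    return {
        "ok": True,
        "canonical": Chem.MolToSmiles(mol),
        "element": element,
        "hybridization": hyb,
        "node_feats": feats,
        "bond_src": src,
        "bond_dst": dst,
        "bond_feats": bfeat,
        "physchem_names": PHYSCHEM_NAMES,
        "physchem": physchem,
        "fp_on_bits": list(fp.GetOnBits()),
        "mol_size": mol_size,
    }


OPS = {"canonicalize": op_canonicalize, "featurize": op_featurize}


def main(argv):
    with open(argv[1]) as fh:
        request = json.load(fh)
    op = OPS[request["op"]]
    options = request.get("options", {}) or {}
    out = []
    for smi in request["smiles"]:
        try:
            out.append(op(smi, options))
        except Exception as exc:  # noqa: BLE001
            out.append({"ok": False, "error": str(exc)})
    with open(argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv)
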