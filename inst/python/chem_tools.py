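"""Batched RDKit helper invoked by the s4clm R package.

Reads SMILES (one per line) from the input file, writes one tab-separated
result line per input to the output file. Protocol is line-aligned: line i of
the output always corresponds to line i of the input, failures included, so
the R side never has to reconcile orderings.

Subcommands:
  canon      <in> <out> [--strip-stereo] [--strip-charge] [--strip-salts]
  descript   <in> <out>
  fingerprint <in> <out> [--radius 3] [--nbits 2048]
  scaffold   <in> <out>
  substruct  <in> <out> --smarts SMARTS
  sanitize   <in> <out>          # parse/valence diagnostics for taxonomy
  fragments  <in> <out> [--radius 2]   # Morgan fragment ids for NP/SA scores
"""

import sys
import argparse

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdMolDescriptors, Crippen, QED
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import rdmolops

RDLogger.DisableLog("rdApp.*")

NEUTRALIZE = Chem.MolFromSmarts("[+1!h0!$([*]~[-1,-2,-3,-4]),-1!$([*]~[+1,+2,+3,+4])]")

# common counter-ions / salt fragments, matched as whole fragments
SALT_SMILES = [
    "[Na+]", "[K+]", "[Li+]", "[Ca+2]", "[Mg+2]", "[Zn+2]", "[NH4+]",
    "[Cl-]", "[Br-]", "[I-]", "[F-]", "O", "[OH-]", "[H+]",
    "OS(=O)(=O)O", "[O-]S(=O)(=O)[O-]", "OC(=O)C(F)(F)F", "CC(=O)O",
    "OC(=O)O", "N", "Cl", "Br", "I", "OC(=O)C=CC(=O)O", "OS(=O)(=O)C",
]


def _canon_frag(s):
    m = Chem.MolFromSmiles(s)
    return Chem.MolToSmiles(m) if m is not None else s


SALT_SET = {_canon_frag(s) for s in SALT_SMILES}


def neutralize(mol):
    """Remove trivial charges by protonation-state adjustment (in place)."""
    mol = Chem.RWMol(mol)
    changed = False
    for atom in mol.GetAtoms():
        ch = atom.GetFormalCharge()
        if ch == 0:
            continue
        hs = atom.GetTotalNumHs()
        if ch > 0 and hs >= ch:
            atom.SetFormalCharge(0)
            atom.SetNumExplicitHs(hs - ch)
            changed = True
        elif ch < 0:
            atom.SetFormalCharge(0)
            atom.SetNumExplicitHs(hs - ch)
            changed = True
    if changed:
        Chem.SanitizeMol(mol, catchErrors=True)
    return mol.GetMol()


def cmd_canon(args, lines, out):
    for s in lines:
        s = s.strip()
        mol = Chem.MolFromSmiles(s) if s else None
        if mol is None:
            out.write("0\t\t0\n")
            continue
        if args.strip_salts:
            frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
            if len(frags) > 1:
                keep = [f for f in frags if Chem.MolToSmiles(f) not in SALT_SET]
                if len(keep) != 1:
                    # nothing left, or a genuine multi-fragment entry
                    out.write("0\t\t1\n")
                    continue
                mol = keep[0]
        n_frag_flag = 0
        if args.strip_stereo:
            Chem.RemoveStereochemistry(mol)
        if args.strip_charge:
            mol = neutralize(mol)
            if any(a.GetFormalCharge() != 0 for a in mol.GetAtoms()):
                out.write("0\t\t2\n")  # charge not trivially removable
                continue
        try:
            can = Chem.MolToSmiles(mol)
            mol2 = Chem.MolFromSmiles(can)
            if mol2 is None:
                out.write("0\t\t0\n")
                continue
            out.write("1\t%s\t%d\n" % (can, n_frag_flag))
        except Exception:
            out.write("0\t\t0\n")


def largest_fused_ring_system(mol):
    ri = mol.GetRingInfo()
    rings = [set(r) for r in ri.AtomRings()]
    if not rings:
        return 0
    # union-find over rings sharing atoms -> fused systems; size = ring count
    parent = list(range(len(rings)))

    def find(i):
        while parent[i] != i:
            parent[i] = parent[parent[i]]
            i = parent[i]
        return i

    for i in range(len(rings)):
        for j in range(i + 1, len(rings)):
            if rings[i] & rings[j]:
                pi, pj = find(i), find(j)
                if pi != pj:
                    parent[pi] = pj
    sizes = {}
    for i in range(len(rings)):
        r = find(i)
        sizes[r] = sizes.get(r, 0) + 1
    return max(sizes.values())


def cmd_descript(args, lines, out):
    hdr = ["ok", "mw", "logp", "qed", "bertz", "n_sp3_c", "n_aliphatic_rings",
           "n_spiro", "n_heavy", "fused_ring_size", "n_rings", "n_stereo",
           "n_macro", "n_atoms_in_rings"]
    out.write("\t".join(hdr) + "\n")
    for s in lines:
        mol = Chem.MolFromSmiles(s.strip()) if s.strip() else None
        if mol is None:
            out.write("0" + "\tNA" * (len(hdr) - 1) + "\n")
            continue
        try:
            n_sp3_c = sum(1 for a in mol.GetAtoms()
                          if a.GetAtomicNum() == 6
                          and a.GetHybridization() == Chem.HybridizationType.SP3)
            ri = mol.GetRingInfo()
            n_macro = sum(1 for r in ri.AtomRings() if len(r) > 8)
            vals = [1,
                    Descriptors.MolWt(mol),
                    Crippen.MolLogP(mol),
                    QED.qed(mol),
                    Descriptors.BertzCT(mol),
                    n_sp3_c,
                    rdMolDescriptors.CalcNumAliphaticRings(mol),
                    rdMolDescriptors.CalcNumSpiroAtoms(mol),
                    mol.GetNumHeavyAtoms(),
                    largest_fused_ring_system(mol),
                    ri.NumRings(),
                    len(Chem.FindMolChiralCenters(mol, includeUnassigned=True)),
                    n_macro,
                    sum(1 for a in mol.GetAtoms() if a.IsInRing())]
            out.write("\t".join(str(v) for v in vals) + "\n")
        except Exception:
            out.write("0" + "\tNA" * (len(hdr) - 1) + "\n")


def _fp_hex(mol, radius, nbits):
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    bv = gen.GetFingerprint(mol)
    return bv.ToBitString()


def cmd_fingerprint(args, lines, out):
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=args.radius,
                                                    fpSize=args.nbits)
    for s in lines:
        mol = Chem.MolFromSmiles(s.strip()) if s.strip() else None
        if mol is None:
            out.write("0\t\n")
            continue
        bv = gen.GetFingerprint(mol)
        out.write("1\t" + bv.ToBitString() + "\n")


def cmd_scaffold(args, lines, out):
    for s in lines:
        mol = Chem.MolFromSmiles(s.strip()) if s.strip() else None
        if mol is None:
            out.write("0\t\n")
            continue
        try:
            sc = MurckoScaffold.GetScaffoldForMol(mol)
            out.write("1\t" + Chem.MolToSmiles(sc) + "\n")
        except Exception:
            out.write("0\t\n")


def cmd_substruct(args, lines, out):
    patt = Chem.MolFromSmarts(args.smarts)
    if patt is None:
        sys.exit("invalid SMARTS: " + args.smarts)
    for s in lines:
        mol = Chem.MolFromSmiles(s.strip()) if s.strip() else None
        if mol is None:
            out.write("NA\n")
        else:
            out.write("1\n" if mol.HasSubstructMatch(patt) else "0\n")


def cmd_sanitize(args, lines, out):
    # parse_ok (no sanitization) \t sanitize_ok
    for s in lines:
        s = s.strip()
        mol = Chem.MolFromSmiles(s, sanitize=False) if s else None
        if mol is None:
            out.write("0\t0\n")
            continue
        try:
            err = Chem.SanitizeMol(mol, catchErrors=True)
            ok = 1 if err == Chem.SanitizeFlags.SANITIZE_NONE else 0
        except Exception:
            ok = 0
        out.write("1\t%d\n" % ok)


def cmd_fragments(args, lines, out):
    # Morgan environment hashes up to `radius`, one space-separated id list
    # per molecule (with multiplicity), plus the heavy-atom count.
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=args.radius)
    for s in lines:
        mol = Chem.MolFromSmiles(s.strip()) if s.strip() else None
        if mol is None:
            out.write("0\t0\t\n")
            continue
        sfp = gen.GetSparseCountFingerprint(mol)
        items = []
        for k, v in sfp.GetNonzeroElements().items():
            items.extend([str(k)] * v)
        out.write("1\t%d\t%s\n" % (mol.GetNumHeavyAtoms(), " ".join(items)))


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("cmd", choices=["canon", "descript", "fingerprint",
                                    "scaffold", "substruct", "sanitize",
                                    "fragments"])
    ap.add_argument("infile")
    ap.add_argument("outfile")
    ap.add_argument("--strip-stereo", action="store_true")
    ap.add_argument("--strip-charge", action="store_true")
    ap.add_argument("--strip-salts", action="store_true")
    ap.add_argument("--radius", type=int, default=3)
    ap.add_argument("--nbits", type=int, default=2048)
    ap.add_argument("--smarts", default="")
    args = ap.parse_args()

    with open(args.infile) as fh:
        lines = fh.readlines()
    with open(args.outfile, "w") as out:
        {"canon": cmd_canon, "descript": cmd_descript,
         "fingerprint": cmd_fingerprint, "scaffold": cmd_scaffold,
         "substruct": cmd_substruct, "sanitize": cmd_sanitize,
         "fragments": cmd_fragments}[args.cmd](args, lines, out)


if __name__ == "__main__":
    main()
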