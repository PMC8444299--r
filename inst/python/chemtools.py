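"""RDKit backend for the clsnap R package.

Invoked as a subprocess by the R side; all I/O is tab/comma separated
text so the bridge stays language-neutral.  Modes:

  parse <in.tsv> <out.tsv>
      in: id<TAB>smiles.  out: id, ok(0/1), canonical_smiles,
      heavy_atoms, mol_weight, error.
  descriptors <in.tsv> <out.csv>
      Full RDKit 2D descriptor list (~210 named numeric columns).
  embed <in.tsv> <coords.tsv> <bonds.tsv> <status.tsv> --seed N
      Seeded ETKDG embedding + MMFF (fallback UFF) optimisation,
      hydrogens explicit, coordinates centred at the geometric
      centroid.  coords: id, element, x, y, z (atom order);
      bonds: id, i, j, order (1-based); status: id, ok(0/1), error.
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors

RDLogger.DisableLog("rdApp.*")


def read_tsv(path):
    rows = []
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            parts = line.split("\t")
            rows.append((parts[0], parts[1] if len(parts) > 1 else ""))
    return rows


def mode_parse(inp, out):
    with open(out, "w") as fh:
        fh.write("id\tok\tcanonical_smiles\theavy_atoms\tmol_weight\terror\n")
        for mid, smi in read_tsv(inp):
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                fh.write("%s\t0\t\t0\tnan\tunparsable SMILES\n" % mid)
            else:
                fh.write("%s\t1\t%s\t%d\t%.6f\t\n" % (
                    mid, Chem.MolToSmiles(mol), mol.GetNumHeavyAtoms(),
                    Descriptors.MolWt(mol)))


def mode_descriptors(inp, out):
    rows = read_tsv(inp)
    names = None
    with open(out, "w") as fh:
        for mid, smi in rows:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                sys.stderr.write("descriptor failure: %s\n" % mid)
                sys.exit(3)
            vals = Descriptors.CalcMolDescriptors(mol)
            if names is None:
                names = list(vals.keys())
                fh.write("id," + ",".join(names) + "\n")
            fh.write(mid + "," + ",".join(repr(float(vals[k])) for k in names) + "\n")


def mode_embed(inp, out_coords, out_bonds, out_status, seed):
    co = open(out_coords, "w")
    bo = open(out_bonds, "w")
    co.write("id\telement\tx\ty\tz\n")
    bo.write("id\ti\tj\torder\n")
    with open(out_status, "w") as st:
        st.write("id\tok\terror\n")
        for mid, smi in read_tsv(inp):
            try:
                mol = Chem.MolFromSmiles(smi)
                if mol is None:
                    raise ValueError("unparsable SMILES")
                mol = Chem.AddHs(mol)
                params = AllChem.ETKDGv3()
                params.randomSeed = int(seed)
                conf_id = AllChem.EmbedMolecule(mol, params)
                if conf_id < 0:
                    # fall back to random coordinates for hard cases
                    params.useRandomCoords = True
                    conf_id = AllChem.EmbedMolecule(mol, params)
                if conf_id < 0:
                    raise ValueError("embedding failed")
                try:
                    if AllChem.MMFFHasAllMoleculeParams(mol):
                        AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
                    else:
                        AllChem.UFFOptimizeMolecule(mol, maxIters=500)
                except Exception:
                    pass
                pos = mol.GetConformer().GetPositions()
                centroid = pos.mean(axis=0)
                for i, atom in enumerate(mol.GetAtoms()):
                    x, y, z = pos[i] - centroid
                    co.write("%s\t%s\t%.6f\t%.6f\t%.6f\n" % (
                        mid, atom.GetSymbol(), x, y, z))
                for b in mol.GetBonds():
                    bo.write("%s\t%d\t%d\t%d\n" % (
                        mid, b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                        int(b.GetBondTypeAsDouble())))
                st.write("%s\t1\t\n" % mid)
            except Exception as exc:  # noqa: BLE001 - reported upstream
                st.write("%s\t0\t%s\n" % (mid, str(exc).replace("\t", " ")))
    co.close()
    bo.close()


def main(argv):
    mode = argv[1]
    if mode == "parse":
        mode_parse(argv[2], argv[3])
    elif mode == "descriptors":
        mode_descriptors(argv[2], argv[3])
    elif mode == "embed":
        seed = 0
        if "--seed" in argv:
            seed = int(argv[argv.index("--seed") + 1])
        mode_embed(argv[2], argv[3], argv[4], argv[5], seed)
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        sys.exit(2)


if __name__ == "__main__":
    main(sys.argv)
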