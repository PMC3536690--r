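"""Deterministic single-conformer 3D embedding backend.

Reads a tab-separated file of (id, smiles, seed) rows, embeds each molecule
with seeded ETKDGv3 distance geometry (explicit hydrogens), relaxes it with
MMFF94 (UFF fallback), and writes a multi-record V2000 SDF. Identical input
and seed give identical coordinates. Used by the R package as a subprocess;
no other functionality lives on the Python side.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


# The C5 ring atom of the dihydropyrazole core is a racemic stereocenter in
# the series; a single consistent tetrahedral configuration is imposed so the
# whole series shares one ring pucker for alignment (racemate represented by
# one enantiomer; no stereo enumeration).
CORE_C5 = Chem.MolFromSmarts("[#6]N1N=C(-[#6])CC1[#6]")


def embed_one(cid, smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparsable SMILES for compound %s: %s" % (cid, smiles))
    match = mol.GetSubstructMatch(CORE_C5)
    if match:
        c5 = mol.GetAtomWithIdx(match[6])
        if c5.GetChiralTag() == Chem.ChiralType.CHI_UNSPECIFIED:
            c5.SetChiralTag(Chem.ChiralType.CHI_TETRAHEDRAL_CCW)
    mol = Chem.AddHs(mol)
    ok = -1
    for attempt in range(3):  # bounded retries, still deterministic
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed) + 100000 * attempt
        ok = AllChem.EmbedMolecule(mol, params)
        if ok == 0:
            break
    if ok != 0:
        raise ValueError("3D embedding failed for compound %s" % cid)
    try:
        status = AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
        if status == -1:
            AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    except Exception:
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    mol.SetProp("_Name", cid)
    mol.SetProp("embed_seed", str(seed))
    return mol


def main(in_path, out_path):
    writer = Chem.SDWriter(out_path)
    writer.SetKekulize(True)
    with open(in_path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smiles, seed = line.split("\t")
            try:
                writer.write(embed_one(cid, smiles, seed))
            except Exception as exc:
                sys.stderr.write("EMBED_ERROR\t%s\t%s\n" % (cid, exc))
                writer.close()
                sys.exit(2)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
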