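"""Seeded distance-geometry conformer embedding.

Reads one SMILES (first token of the first line), embeds `n_confs`
conformers with ETKDG at the given random seed, prunes by heavy-atom RMSD,
and writes a multi-record SDF. Atom order in the output equals the order
of appearance in the SMILES (explicit atoms first, remaining hydrogens
appended), which the calling code relies on for atom-role bookkeeping.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def main(smi_file, out_file, n_confs, seed, prune_rms):
    params = Chem.SmilesParserParams()
    params.removeHs = False
    smi = open(smi_file).read().strip().split()[0]
    mol = Chem.MolFromSmiles(smi, params)
    if mol is None:
        sys.stderr.write("parse failure\n")
        return 2
    mol = Chem.AddHs(mol)
    etkdg = AllChem.ETKDGv3()
    etkdg.randomSeed = int(seed)
    etkdg.pruneRmsThresh = float(prune_rms)
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=int(n_confs),
                                     params=etkdg)
    if len(ids) == 0:
        etkdg.useRandomCoords = True
        ids = AllChem.EmbedMultipleConfs(mol, numConfs=int(n_confs),
                                         params=etkdg)
    if len(ids) == 0:
        sys.stderr.write("embedding failure\n")
        return 3
    with open(out_file, "w") as fh:
        for cid in ids:
            fh.write(Chem.MolToMolBlock(mol, confId=cid))
            fh.write("$$$$\n")
    return 0


if __name__ == "__main__":
    sys.exit(main(*sys.argv[1:6]))
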