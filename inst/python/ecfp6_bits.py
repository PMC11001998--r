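"""Compute folded binary Morgan fingerprints (radius 3, ECFP6) for SMILES.

stdin/argv: a TSV with columns molecule_id <TAB> smiles (no header).
stdout: molecule_id <TAB> OK <TAB> space-separated on-bit indices
        or molecule_id <TAB> ERR <TAB> message
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main(path, n_bits=2048, radius=3):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            mol_id, _, smi = line.partition("\t")
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                print(f"{mol_id}\tERR\tunparseable SMILES: {smi}")
                continue
            frags = Chem.GetMolFrags(mol)
            note = "multifragment" if len(frags) > 1 else ""
            bits = " ".join(str(b) for b in gen.GetFingerprint(mol).GetOnBits())
            print(f"{mol_id}\tOK\t{bits}\t{note}")


if __name__ == "__main__":
    nb = int(sys.argv[2]) if len(sys.argv) > 2 else 2048
    rad = int(sys.argv[3]) if len(sys.argv) > 3 else 3
    main(sys.argv[1], nb, rad)
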