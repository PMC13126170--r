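"""Batch ECFP (Morgan) fingerprint helper.

Reads a TSV of ``id<TAB>smiles`` from the file given as argv[1], writes
``id<TAB>OK<TAB>comma-separated on-bit indices`` (0-based) or
``id<TAB>ERROR<TAB>message`` per line to stdout. Radius and bit count come
from argv[2] and argv[3]. Molecules are canonicalised by parsing, so any
SMILES spelling of the same molecule yields the same bits.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main() -> None:
    path, radius, n_bits = sys.argv[1], int(sys.argv[2]), int(sys.argv[3])
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=n_bits)
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                print(f"{ident}\tERROR\tunparseable SMILES: {smiles}")
                continue
            bits = gen.GetFingerprint(mol).GetOnBits()
            print(f"{ident}\tOK\t{','.join(str(b) for b in bits)}")


if __name__ == "__main__":
    main()
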