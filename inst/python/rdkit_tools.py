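"""Batched RDKit primitives for the ChemFusion R package.

Usage: python rdkit_tools.py <command> <infile> [args...]

Reads one SMILES per line from <infile>, writes one tab-separated result
line per input line to stdout.  A line whose computation fails starts with
the literal token ``ERROR`` followed by a message; the R side turns these
into per-compound reports.  Commands:

  canon  <infile>                 canonical SMILES
  desc   <infile> <panelfile>     descriptor values for the pinned panel
  fp     <infile> <maccs|ecfp4>   fingerprint as a 0/1 string
  props  <infile>                 MW, logP, HBD, HBA, rotatable bonds, charge
  enum   <infile> <n> <seed>      randomized SMILES variants (deduplicated)
"""
import sys
import random

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, MACCSkeys, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

DESC_FUN = dict(Descriptors._descList)


def read_smiles(path):
    with open(path) as fh:
        return [line.rstrip("\n") for line in fh]


def mol_or_none(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def cmd_canon(lines):
    for smi in lines:
        mol = mol_or_none(smi)
        if mol is None:
            yield "ERROR\tunparseable SMILES: %s" % smi
        else:
            yield Chem.MolToSmiles(mol)


def cmd_desc(lines, panel):
    funs = [DESC_FUN[name] for name in panel]
    for smi in lines:
        mol = mol_or_none(smi)
        if mol is None:
            yield "ERROR\tunparseable SMILES: %s" % smi
            continue
        vals = []
        for f in funs:
            try:
                vals.append(repr(float(f(mol))))
            except Exception:
                vals.append("nan")
        yield "\t".join(vals)


def cmd_fp(lines, kind):
    for smi in lines:
        mol = mol_or_none(smi)
        if mol is None:
            yield "ERROR\tunparseable SMILES: %s" % smi
            continue
        if kind == "maccs":
            # RDKit MACCS has a dummy bit 0; drop it for the 166-key vector
            bits = MACCSkeys.GenMACCSKeys(mol).ToBitString()[1:]
        else:
            bits = AllChem.GetMorganFingerprintAsBitVect(
                mol, radius=2, nBits=2048).ToBitString()
        yield bits


def cmd_props(lines):
    for smi in lines:
        mol = mol_or_none(smi)
        if mol is None:
            yield "ERROR\tunparseable SMILES: %s" % smi
            continue
        vals = [
            Descriptors.MolWt(mol),
            Crippen.MolLogP(mol),
            rdMolDescriptors.CalcNumHBD(mol),
            rdMolDescriptors.CalcNumHBA(mol),
            rdMolDescriptors.CalcNumRotatableBonds(mol),
            Chem.GetFormalCharge(mol),
        ]
        yield "\t".join(repr(float(v)) for v in vals)


def cmd_enum(lines, n, seed):
    rng = random.Random(seed)
    for smi in lines:
        mol = mol_or_none(smi)
        if mol is None:
            yield "ERROR\tunparseable SMILES: %s" % smi
            continue
        seen = []
        tries = 0
        # retry cap: molecules with few distinct forms return fewer variants
        while len(seen) < n and tries < 20 * n:
            tries += 1
            order = list(range(mol.GetNumAtoms()))
            rng.shuffle(order)
            variant = Chem.MolToSmiles(
                Chem.RenumberAtoms(mol, order), canonical=False)
            if variant not in seen:
                seen.append(variant)
        yield "\t".join(seen)


def main(argv):
    cmd, infile = argv[1], argv[2]
    lines = read_smiles(infile)
    if cmd == "canon":
        out = cmd_canon(lines)
    elif cmd == "desc":
        panel = read_smiles(argv[3])
        out = cmd_desc(lines, panel)
    elif cmd == "fp":
        out = cmd_fp(lines, argv[3])
    elif cmd == "props":
        out = cmd_props(lines)
    elif cmd == "enum":
        out = cmd_enum(lines, int(argv[3]), int(argv[4]))
    else:
        raise SystemExit("unknown command: %s" % cmd)
    w = sys.stdout.write
    for line in out:
        w(line)
        w("\n")


if __name__ == "__main__":
    main(sys.argv)
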