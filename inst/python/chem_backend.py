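"""RDKit backend for the hitsieve R package.

Batch subcommands over tab-separated files so a whole compound library is
processed in a single interpreter start:

  fingerprint IN OUT         1024-bit Morgan (ECFP4, radius 2) fingerprints
  pains       IN OUT [CAT]   PAINS substructure matches (default: the
                             480-entry catalog shipped with RDKit; CAT is an
                             optional user catalog TSV of smarts<TAB>name)
  canon       IN OUT         canonical SMILES (parse check + dedup support)
  catalog     OUT            dump the bundled PAINS catalog as name<TAB>smarts

IN lines are ``id<TAB>smiles``. Unparseable structures are reported with the
sentinel value ``*PARSE_ERROR*`` so the caller can apply the discard rule.
"""

import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import rdMolDescriptors
from rdkit.Chem.FilterCatalog import FilterCatalog, FilterCatalogParams

RDLogger.DisableLog("rdApp.*")

PARSE_ERROR = "*PARSE_ERROR*"


def read_input(path):
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smiles = line.split("\t", 1)
            yield ident, smiles


def cmd_fingerprint(inp, out):
    with open(out, "w") as fh:
        for ident, smiles in read_input(inp):
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                fh.write(f"{ident}\t{PARSE_ERROR}\n")
                continue
            fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(mol, 2, nBits=1024)
            fh.write(f"{ident}\t{fp.ToBitString()}\n")


def cmd_canon(inp, out):
    with open(out, "w") as fh:
        for ident, smiles in read_input(inp):
            mol = Chem.MolFromSmiles(smiles)
            can = PARSE_ERROR if mol is None else Chem.MolToSmiles(mol)
            fh.write(f"{ident}\t{can}\n")


def default_catalog():
    params = FilterCatalogParams()
    params.AddCatalog(FilterCatalogParams.FilterCatalogs.PAINS)
    return FilterCatalog(params)


def user_catalog(path):
    """Build a FilterCatalog-like matcher from a smarts<TAB>name TSV.

    Hydrogen query atoms are merged into their neighbours, mirroring what
    RDKit's own PAINS catalog construction does, so the explicit-[#1]
    idiom of the published SMARTS matches implicit-H molecules.
    """
    entries = []
    with open(path) as fh:
        for lineno, line in enumerate(fh, 1):
            line = line.rstrip("\n")
            if not line:
                continue
            smarts, name = line.split("\t", 1)
            patt = Chem.MolFromSmarts(smarts)
            if patt is None:
                sys.exit(f"catalog parse failure at line {lineno}: {name}")
            try:
                patt = Chem.MergeQueryHs(patt)
            except Exception:
                pass
            entries.append((name, patt))
    return entries


def cmd_pains(inp, out, catalog_path=None):
    builtin = catalog_path is None
    cat = default_catalog() if builtin else user_catalog(catalog_path)
    with open(out, "w") as fh:
        for ident, smiles in read_input(inp):
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                fh.write(f"{ident}\t{PARSE_ERROR}\n")
                continue
            if builtin:
                names = [e.GetDescription() for e in cat.GetMatches(mol)]
            else:
                names = [n for n, p in cat if mol.HasSubstructMatch(p)]
            fh.write(f"{ident}\t{'|'.join(names)}\n")


def cmd_catalog(out):
    import csv
    import os

    src = os.path.join(RDConfig.RDDataDir, "Pains", "wehi_pains.csv")
    with open(src) as fh, open(out, "w") as oh:
        for smarts, tag in csv.reader(fh):
            name = tag.strip()
            if name.startswith("<regId="):
                name = name[len("<regId="):].rstrip(">")
            oh.write(f"{name}\t{smarts}\n")


def main(argv):
    if not argv:
        sys.exit("usage: chem_backend.py {fingerprint|pains|canon|catalog} ...")
    cmd, args = argv[0], argv[1:]
    if cmd == "fingerprint":
        cmd_fingerprint(*args)
    elif cmd == "pains":
        cmd_pains(*args)
    elif cmd == "canon":
        cmd_canon(*args)
    elif cmd == "catalog":
        cmd_catalog(*args)
    else:
        sys.exit(f"unknown subcommand: {cmd}")


if __name__ == "__main__":
    main(sys.argv[1:])
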