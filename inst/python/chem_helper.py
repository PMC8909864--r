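#!/usr/bin/env python
"""Batched chemistry primitives for the molgen R package.

Every subcommand reads newline-separated input on stdin (unless noted),
writes tab-separated output on stdout, one line per input line, and never
aborts on a bad molecule: failures yield empty/NA fields so row alignment
with the caller is preserved.
"""

import sys
import os
import argparse

from rdkit import Chem, RDLogger
from rdkit import RDConfig

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))


def _mol(smi):
    if not smi:
        return None
    return Chem.MolFromSmiles(smi)


def _canon(smi):
    m = _mol(smi)
    return None if m is None else Chem.MolToSmiles(m)


def cmd_canon(args, lines):
    for s in lines:
        c = _canon(s)
        print("" if c is None else c)


def cmd_maccs(args, lines):
    from rdkit.Chem import MACCSkeys
    for s in lines:
        m = _mol(s)
        if m is None:
            print("")
            continue
        fp = MACCSkeys.GenMACCSKeys(m)
        # rdkit MACCS is 167 bits with bit 0 always unset; keys are 1..166
        print(fp.ToBitString()[1:])


def cmd_desc(args, lines):
    from rdkit.Chem import Descriptors, Crippen, rdMolDescriptors, QED
    import sascorer
    for s in lines:
        m = _mol(s)
        if m is None:
            print("\t".join(["NA"] * 6))
            continue
        try:
            vals = [
                Descriptors.MolWt(m),
                rdMolDescriptors.CalcTPSA(m),
                Crippen.MolMR(m),
                Crippen.MolLogP(m),
                sascorer.calculateScore(m),
                QED.qed(m),
            ]
            print("\t".join("%.6f" % v for v in vals))
        except Exception:
            print("\t".join(["NA"] * 6))


def cmd_substruct(args, lines):
    # a SMILES query gets aromaticity perception (so an indole written in
    # Kekule form matches aromatic targets); fall back to raw SMARTS
    patt = Chem.MolFromSmiles(args.query)
    if patt is None:
        patt = Chem.MolFromSmarts(args.query)
    if patt is None:
        sys.stderr.write("bad query pattern\n")
        sys.exit(2)
    for s in lines:
        m = _mol(s)
        if m is None:
            print("NA")
        else:
            print(1 if m.HasSubstructMatch(patt) else 0)


def cmd_sites(args, lines):
    """One scaffold SMILES as --query; emits atom_index, element, n_h."""
    m = _mol(args.query)
    if m is None:
        sys.stderr.write("unparseable scaffold\n")
        sys.exit(2)
    for a in m.GetAtoms():
        print("%d\t%s\t%d" % (a.GetIdx(), a.GetSymbol(), a.GetTotalNumHs()))


def _add_methyl(smi, idx):
    """Graph-edit construction of scaffold + methyl at atom idx (canonical)."""
    m = _mol(smi)
    if m is None or idx < 0 or idx >= m.GetNumAtoms():
        return None
    rw = Chem.RWMol(m)
    a = rw.GetAtomWithIdx(idx)
    if a.GetTotalNumHs() < 1:
        return None
    if a.GetNumExplicitHs() > 0:
        a.SetNumExplicitHs(a.GetNumExplicitHs() - 1)
    c = rw.AddAtom(Chem.Atom(6))
    rw.AddBond(idx, c, Chem.BondType.SINGLE)
    mm = rw.GetMol()
    try:
        Chem.SanitizeMol(mm)
    except Exception:
        return None
    return Chem.MolToSmiles(mm)


def cmd_addmethyl(args, lines):
    """stdin lines: smiles<TAB>atom_index; emits canonical methylated SMILES."""
    for line in lines:
        parts = line.split("\t")
        c = _add_methyl(parts[0], int(parts[1])) if len(parts) == 2 else None
        print("" if c is None else c)


def _root_token_end(t):
    """Index just past the first atom token plus its ring-closure digits."""
    i, n = 0, len(t)
    if t[i] == "[":
        i = t.index("]", i) + 1
    else:
        i += 1
        if i < n and t[i] in "lr":  # Cl / Br
            i += 1
    while i < n and (t[i].isdigit() or t[i] == "%"):
        i += 3 if t[i] == "%" else 1
    return i


def _branch_wrap(mol, site):
    """Spelling rooted AT `site` with every substituent in parentheses, so a
    token appended to the string bonds to `site`."""
    t = Chem.MolToSmiles(mol, rootedAtAtom=site, canonical=True,
                         kekuleSmiles=True)
    i = _root_token_end(t)
    root, rest = t[:i], t[i:]
    out, depth, seg = [], 0, ""
    for ch in rest:
        if ch == "(":
            if depth == 0 and seg:
                out.append("(" + seg + ")")
                seg = ""
            depth += 1
            seg += ch
        elif ch == ")":
            depth -= 1
            seg += ch
            if depth == 0:
                out.append(seg)
                seg = ""
        else:
            seg += ch
    if seg:
        out.append("(" + seg + ")")
    return root + "".join(out)


def _attach_atom(spelling, out_order):
    """Original-mol index of the atom a token appended to `spelling` bonds to,
    or None if the methyl-extended string does not sanitize."""
    probe = _mol(spelling + "C")
    if probe is None:
        return None
    added = probe.GetNumAtoms() - 1
    nbrs = probe.GetAtomWithIdx(added).GetNeighbors()
    if len(nbrs) != 1:
        return None
    pos = nbrs[0].GetIdx()  # write order == parse order for heavy atoms
    if pos >= len(out_order):
        return None
    return out_order[pos]


def cmd_rooted(args, lines):
    """One scaffold SMILES as --query; emits atom_index<TAB>rooted_smiles for
    every H-bearing heavy atom (empty second field when no spelling found)."""
    smi = args.query
    m = _mol(smi)
    if m is None:
        sys.stderr.write("unparseable scaffold\n")
        sys.exit(2)
    sites = [a.GetIdx() for a in m.GetAtoms() if a.GetTotalNumHs() >= 1]
    csc = Chem.MolToSmiles(m)
    mk = Chem.Mol(m)
    Chem.Kekulize(mk, clearAromaticFlags=True)

    def order_of(mol):
        return list(map(int, mol.GetProp("_smilesAtomOutputOrder")
                        .strip("[]").split(",")))

    refs = {a: _add_methyl(smi, a) for a in sites}
    found = {}

    def consider(s, order):
        at = _attach_atom(s, order)
        if at is None or at in found or at not in sites:
            return
        if _canon(s) != csc:
            return
        if _canon(s + "C") == refs[at] and refs[at] is not None:
            found[at] = s

    # pass 1: canonical spellings rooted at each atom (their DFS often ends
    # at a ring atom we want); pass 2: random spellings widen coverage
    for b in range(m.GetNumAtoms()):
        s = Chem.MolToSmiles(mk, rootedAtAtom=b, canonical=True,
                             kekuleSmiles=True)
        consider(s, order_of(mk))
        if len(found) == len(sites):
            break
    rng_tries = int(args.extra or 300)
    for _ in range(rng_tries):
        if len(found) == len(sites):
            break
        s = Chem.MolToSmiles(mk, doRandom=True, canonical=False,
                             kekuleSmiles=True)
        consider(s, order_of(mk))
    # pass 3: deterministic branch-wrapped construction for cut-vertex atoms
    for a in sites:
        if a in found:
            continue
        s = _branch_wrap(mk, a)
        consider(s, order_of(mk))

    for a in sites:
        print("%d\t%s" % (a, found.get(a, "")))


def cmd_tsne(args, lines):
    """stdin: one row per line, tab-separated standardized features."""
    import numpy as np
    from sklearn.manifold import TSNE
    x = np.array([[float(v) for v in ln.split("\t")] for ln in lines])
    emb = TSNE(n_components=2, perplexity=float(args.perplexity),
               random_state=int(args.seed), init="pca",
               method="exact").fit_transform(x)
    for row in emb:
        print("%.8f\t%.8f" % (row[0], row[1]))


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("command")
    ap.add_argument("--query", default=None)
    ap.add_argument("--extra", default=None)
    ap.add_argument("--seed", default="1")
    ap.add_argument("--perplexity", default="30")
    args = ap.parse_args()
    lines = [ln.rstrip("\n") for ln in sys.stdin] \
        if args.command not in ("sites", "rooted") else []
    {
        "canon": cmd_canon,
        "maccs": cmd_maccs,
        "desc": cmd_desc,
        "substruct": cmd_substruct,
        "sites": cmd_sites,
        "rooted": cmd_rooted,
        "addmethyl": cmd_addmethyl,
        "tsne": cmd_tsne,
    }[args.command](args, lines)


if __name__ == "__main__":
    main()
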