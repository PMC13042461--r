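"""Seeded distance-geometry conformer embedding with MMFF94 strain energies.

Reads a two-column SMILES file (smiles, id), embeds up to `n_confs`
conformers per molecule with ETKDGv3 under a fixed random seed, minimizes
each with MMFF94 (UFF fallback when MMFF parameters are missing), and
writes a JSON map id -> {status, energies (kcal/mol), coords (heavy atoms,
Angstrom)}.  Heavy-atom order matches the input SMILES atom order.

Usage: python embed_conformers.py in.smi out.json n_confs seed
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed(smiles, n_confs, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"status": "parse_error"}
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    # no embed-time pruning: raw embeddings of distinct rotamer basins can
    # sit within 0.5 A before minimization; de-duplication happens on the
    # minimized geometries downstream
    params.pruneRmsThresh = -1.0
    cids = list(AllChem.EmbedMultipleConfs(molh, numConfs=n_confs, params=params))
    if not cids:
        return {"status": "embed_error"}
    if AllChem.MMFFHasAllMoleculeParams(molh):
        res = AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=500)
    else:
        res = AllChem.UFFOptimizeMoleculeConfs(molh, maxIters=500)
    heavy = [a.GetIdx() for a in molh.GetAtoms() if a.GetAtomicNum() > 1]
    energies, coords = [], []
    for cid, (_, energy) in zip(cids, res):
        conf = molh.GetConformer(cid)
        energies.append(energy)
        coords.append([[conf.GetAtomPosition(i).x,
                        conf.GetAtomPosition(i).y,
                        conf.GetAtomPosition(i).z] for i in heavy])
    return {"status": "ok", "energies": energies, "coords": coords}


def main():
    in_smi, out_json, n_confs, seed = sys.argv[1:5]
    out = {}
    with open(in_smi) as fh:
        for line in fh:
            parts = line.split()
            if len(parts) < 2:
                continue
            out[parts[1]] = embed(parts[0], int(n_confs), int(seed))
    with open(out_json, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
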