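"""Geometry backend: ETKDG embedding and UFF optimization/energies.

Reads a JSON job file and writes a JSON result file. Each job:
  {"id": str, "smiles": str, "n_confs": int, "seed": int,
   "optimize": bool, "max_iters": int, "coords": null | [[x,y,z], ...]}

When "coords" is given, a single conformer is built from those positions
(atom order: heavy atoms in SMILES order, then hydrogens in AddHs order)
and optimized/evaluated instead of embedding.

Output per job:
  {"id": str, "ok": bool, "error": str|None,
   "elements": [...], "h_parent": [-1 or 0-based heavy index],
   "conformers": [{"energy": float, "optimized": bool, "coords": [[...]]}]}
"""
import json
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def run_job(job):
    mol = Chem.MolFromSmiles(job["smiles"])
    if mol is None:
        return {"id": job["id"], "ok": False, "error": "SMILES parse failed"}
    mol = Chem.AddHs(mol)
    elements = [a.GetSymbol() for a in mol.GetAtoms()]
    h_parent = []
    for a in mol.GetAtoms():
        if a.GetSymbol() == "H":
            h_parent.append(a.GetNeighbors()[0].GetIdx())
        else:
            h_parent.append(-1)

    max_iters = int(job.get("max_iters", 500))
    optimize = bool(job.get("optimize", True))

    if job.get("coords"):
        conf = Chem.Conformer(mol.GetNumAtoms())
        for i, (x, y, z) in enumerate(job["coords"]):
            conf.SetAtomPosition(i, (float(x), float(y), float(z)))
        conf.SetId(0)
        mol.RemoveAllConformers()
        mol.AddConformer(conf, assignId=True)
        cids = [0]
    else:
        params = AllChem.ETKDGv2()
        params.randomSeed = int(job["seed"])
        cids = list(AllChem.EmbedMultipleConfs(mol, int(job["n_confs"]), params))
        if not cids:
            params.useRandomCoords = True
            cids = list(AllChem.EmbedMultipleConfs(mol, int(job["n_confs"]), params))
        if not cids:
            return {"id": job["id"], "ok": False, "error": "embedding failed"}

    conformers = []
    for cid in cids:
        try:
            ff = AllChem.UFFGetMoleculeForceField(mol, confId=cid)
        except Exception as exc:  # UFF typing failure
            return {"id": job["id"], "ok": False, "error": "UFF setup failed: %s" % exc}
        if ff is None:
            return {"id": job["id"], "ok": False, "error": "UFF setup failed"}
        if optimize:
            ff.Minimize(maxIts=max_iters)
        energy = ff.CalcEnergy()
        conf = mol.GetConformer(cid)
        coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                   conf.GetAtomPosition(i).z] for i in range(mol.GetNumAtoms())]
        conformers.append({"energy": energy, "optimized": optimize, "coords": coords})

    return {"id": job["id"], "ok": True, "error": None, "elements": elements,
            "h_parent": h_parent, "conformers": conformers}


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    results = []
    for job in payload["jobs"]:
        try:
            results.append(run_job(job))
        except Exception as exc:  # noqa: BLE001 - report, never abort the batch
            results.append({"id": job.get("id"), "ok": False, "error": str(exc)})
    with open(sys.argv[2], "w") as fh:
        json.dump({"jobs": results}, fh)


if __name__ == "__main__":
    main()
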