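# molprep

Prepare small-molecule libraries for structure-based virtual screening:
convert 1D/2D representations (SMILES strings, flat SDF) into bounded sets
of docking-ready 3D models that enumerate **ionization**, **tautomeric**,
**chiral**, **cis/trans-isomeric**, and **non-aromatic-ring-conformational**
forms, with provenance recorded on every output model.

Who it is for: anyone assembling a ligand set for docking (AutoDock
Vina-style flexible-ligand engines) who needs the forms a binding pocket
might stabilize, not just the single form written in the library file.

## The method in brief

For each input record the pipeline runs:

```
desalt -> ionize (pH window + pKa table; |q - q0| <= 2 charge pruning)
       -> tautomerize (1,3 proton shifts + plausibility filters)
       -> enumerate unspecified R/S centers -> enumerate unspecified E/Z bonds
       -> [after each stage] prune: sample m*t forms, embed one conformer each,
          single-point UFF energies, keep the m best
       -> ring conformers: embed m*t models (ETKDG + UFF), fingerprint
          f_m = ( RMSD(c_m_r, c_1_r) )_{r=1..R} over the R non-aromatic rings,
          k-means cluster, keep medoid models
       -> final UFF optimization -> SDF (+ optional PDB / HTML)
```

where `m = max_variants_per_compound` (default 5), `t = thoroughness`
(default 3), and RMSD is the least-squares Kabsch superposition. Without
pruning, two options in each of the five state categories would already
give 2^5 = 32 forms per molecule — 320,000 dockings for a 10,000-compound
screen.

Embedding and force-field work run through a pluggable geometry backend;
the default adapter drives RDKit (ETKDG + UFF) via a batched `python`
subprocess. The molecular-graph kernel (SMILES, kekulization, aromaticity,
canonical keys, substructure matching) is pure R inside this package.

## Worked example

```r
library(molprep)

cfg  <- pipeline_config(min_ph = 7.4, max_ph = 7.4, seed = 7,
                        backend = rdkit_backend())
rec  <- molecule_record("butan-2-one", "CCC(C)=O", 0L)
res  <- run_pipeline(list(rec), cfg)
for (v in res$results[[1]]$variants)
  cat(write_smiles(v$graph), " E =", round(v$energy, 2), "\n")
```

prints (seed 7):

```
C(CC)(C)=O  E = 2.1
C(=C\C)(\C)O  E = 4.73
C(=C\C)(/C)O  E = 5.03
```

— the ketone plus the two geometric isomers of its internal enol,
but-2-en-2-ol, each with its UFF energy in kcal/mol; the implausible
terminal-alkene enol is filtered out. Each model carries a `Genealogy`
data field in the output SDF recording the steps that produced it.

Command line over a whole library:

```sh
Rscript -e 'molprep::molprep_cli()' -- \
  --source library.smi --output_folder out \
  --min_ph 7.4 --max_ph 7.4 --thoroughness 3 \
  --max_variants_per_compound 5 --job_manager multiprocessing \
  --num_processors 4 --seed 1 --add_html_output
```

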