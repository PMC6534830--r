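---
title: "Preparing small-molecule libraries: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing small-molecule libraries: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Structure-based virtual screening docks 3D small-molecule models into a
protein pocket. Compound libraries, however, usually arrive as SMILES
strings or flat SDF files: one ionization state, one tautomer, often with
unspecified stereocenters, and no coordinates. A binding pocket can
stabilize a form that is rare in bulk solution, so docking only the form
written in the library file loses real binders. `molprep` expands each
input compound into a small, bounded set of 3D models that enumerate five
independent state categories -- ionization, tautomer, tetrahedral
chirality, double-bond cis/trans configuration, and non-aromatic ring
conformation -- and writes them to SDF with per-model provenance.

Full enumeration is intractable: with just two options in each of the five
categories a molecule yields 2^5 = 32 forms, and a 10,000-compound screen
would need 320,000 dockings. The pipeline therefore prunes after every
stage (see *Bounding the explosion*).

## Pipeline and models

Stages run in a fixed order per input record:

1. **Desalting.** Multi-fragment records keep the fragment with the most
   heavy atoms (ties: molecular weight, then canonical key -- determinism
   over chemistry; the remaining ambiguity is immaterial for real salts).
2. **Ionization.** Ionizable sites are found by substructure patterns from
   a curated table (packaged as `inst/extdata/ionizable_sites.json`,
   user-overridable) carrying literature mean pKa values and spreads in the
   style of substructure/pKa ionizers. Over a window `[min_ph, max_ph]`
   with precision `d`, a site is emitted deprotonated when
   `pKa - d < max_ph` and protonated when `pKa + d > min_ph`; both forms
   when both hold. The Cartesian product over sites is deduplicated.
   Highly charged combinations are removed relative to the form whose net
   charge `q0` is closest to zero: a form survives iff `|q - q0| <= 2`
   (the strict reading of "deviates by 3 e or more is eliminated"; a
   baseline tie between +q and -q resolves to the more negative candidate,
   chosen once for determinism).
3. **Tautomers** (skippable via `skip_making_tautomers`). A generic 1,3
   proton shift `H-D-Y=A -> D=Y-A-H` with at least one of D, A a
   heteroatom (N, O, S) is closed over repeated application up to a cap of
   64 forms. This single rule realizes keto/enol, imine/enamine,
   amide/iminol, nitroso/oxime and aromatic-heterocycle shifts; shifts
   between two carbons are excluded as chemically meaningless here.
   Filters then reject candidates that change the aromatic-ring count or
   the chiral-center count, and candidates matching a packaged blacklist:
   terminal-alkene enols, geminal vinyl diols (including their
   deprotonated diolate forms, which arise because ionization precedes
   tautomer enumeration), and carbanions. Double bonds whose order changed
   in any tautomer lose their cis/trans annotation and are re-enumerated
   downstream -- intentional behavior mirrored from the upstream
   normalizer this stage emulates.
4. **Chirality and cis/trans.** Unspecified tetrahedral centers (atoms
   whose four substituents fall in pairwise-distinct refinement symmetry
   classes) are varied over both parities; unspecified stereogenic double
   bonds over cis and trans. Assigned stereo is never touched. Meso
   duplicates collapse via canonical keys. Double bonds inside rings of
   fewer than 8 atoms are never enumerated (geometrically forced cis);
   medium rings of 8+ are enumerated, a cutoff chosen once -- trans-cyclooctene
   is isolable, trans-cycloheptene is not at room temperature.
5. **Ring conformations.** For molecules with non-aromatic SSSR rings,
   `m x t` 3D models are embedded (ETKDG) and force-field optimized (UFF).
   Each model `m` is reduced to a ring-conformation fingerprint `f_m`: the
   vector whose r-th entry is the least-squares superposition RMSD (Kabsch,
   closed form via SVD) between ring r's coordinates in model m and in
   model 1; `f_1` is the zero vector by construction. k-means clustering
   (k = min(max_variants_per_compound, number of distinct fingerprints))
   groups the fingerprints and only cluster-medoid models are retained.
6. **Final optimization.** Any model not already optimized in stage 5 is
   UFF-optimized; the per-molecule output is capped at
   `max_variants_per_compound` by energy.

### Bounding the explosion

After each enumeration stage, if more than `m = max_variants_per_compound`
forms are live, `min(n, m*t)` of them are sampled without replacement
(`t = thoroughness`), one conformer is embedded per sampled form and scored
with a single-point UFF energy (no optimization, for speed), and the `m`
best-energy forms survive. Energy ties break by canonical key. With
defaults `m = 5, t = 3` and 32 live forms, exactly 15 are embedded and 5
retained.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_ph`, `max_ph` | 6.4, 8.4 | pH | ionization window around physiological pH |
| `pka_precision` | 1.0 | pH | symmetric +/- window around each site pKa |
| `thoroughness` (t) | 3 | -- | sampling multiplier before energy ranking |
| `max_variants_per_compound` (m) | 5 | -- | output bound per input molecule |
| `skip_making_tautomers` | FALSE | -- | e.g. for amide-rich libraries where iminol forms would balloon the output |
| `job_manager`, `num_processors` | serial, 1 | -- | execution mode |
| `seed` | 1 | -- | global seed; all stage RNGs derive from (seed, record, stage) |

## Numerical and design choices

* **One aromaticity model.** Aromaticity is perceived once (simple Hueckel
  4n+2 count over SSSR rings of size >= 5, with exocyclic-double-bond atoms
  contributing zero electrons and lone-pair heteroatoms two) and the
  tautomer ring-count filter compares parent and candidate under this one
  model -- the filter is meaningless if perception differs between the two.
  Fused pyridinone-type rings count as aromatic, matching mainstream
  toolkits on the fixture set.
* **Canonical keys** (used for all deduplication) serialize the graph under
  Morgan-refinement canonical ranks with branching tie-breaks, label
  perceived-aromatic bonds as aromatic rather than by Kekule order (so the
  key is independent of the Kekule assignment), and re-express tetrahedral
  parities and cis/trans references relative to the canonical order.
* **Chirality representation.** Graphs store SMILES-style parity relative
  to a recorded neighbor order; R/S labels are derived with atomic-number +
  Morgan-rank substituent priorities. This is a CIP approximation: exact
  for the fixture molecules, potentially wrong for centers whose priorities
  hinge on CIP's duplicated-atom rules. Enumeration and deduplication only
  need parity, not labels.
* **Geometry backend contract.** Embedding and force-field work is
  delegated to a pluggable backend (`embed(graph, n, seed)`,
  `optimize(graph, coords)`); the default adapter drives RDKit's ETKDG and
  UFF through a batched python subprocess (one interpreter start per job
  batch, not per molecule). A deterministic pure-R stub backend exists for
  tests that exercise sampling/ranking contracts where geometric realism is
  irrelevant; stub geometries are random and chemically meaningless, which
  is exactly why the ring-conformation and Fig-style behavioral tests use
  the real backend.
* **k-means initialization** is k-means++ with 10 restarts (best inertia
  kept), seeds derived deterministically. Medoid ties resolve to the lowest
  model index. Ring-atom correspondence for the RMSD uses the fixed SSSR
  atom ordering; flip-equivalent ring orderings are not searched, so two
  mirror-image ring geometries can have nonzero fingerprint distance --
  acceptable because the fingerprint only needs to separate genuinely
  different conformers, not to be a true metric on conformer classes.
* **Determinism.** Every stochastic step (sampling, embedding seeds,
  k-means) derives its seed from (global seed, record identity, stage
  name), never from scheduling order; serial and multiprocessing runs are
  therefore identical per record, which the test suite asserts.
* **Even chunking.** Static load balancing splits n inputs over w workers
  into sizes that sum to n with max-min <= 1.

## What the synthetic library emulates

`synthetic_library()` builds benchmark-style inputs constructively from
small scaffold pools with exact user-specified fractions of ionizable
groups, unspecified stereocenters, non-aromatic rings and counterion
salts. It emulates the *shape* of a screening library (feature mix,
multi-fragment records) -- not its chemical diversity: molecules are small
(<= ~10 heavy atoms), contain no fused ring systems, macrocycles, or
bridged cages, and therefore cannot exercise embedding failure paths or
macrocycle torsion quality. A green test on the synthetic library
establishes pipeline contracts (bounds, determinism, serial/parallel
equivalence), not docking-relevant model quality.

## Known limitations

* Large macrocycles: the delegated distance-geometry embedder assigns
  macrocycle torsions from acyclic patterns; optimized geometries are
  valid but may miss the lowest-energy ring conformations.
* Bridged polycyclics can fail to embed; such molecules are flagged failed
  and reported, never aborting the batch.
* The SMILES kernel covers the organic subset plus bracket atoms, isotopes,
  charges, tetrahedral and double-bond stereo; it does not support allene
  (axial) chirality, atropisomers, or quadruple bonds.
* Flat SDF input ignores wedge bonds: stereo must come from SMILES input or
  be enumerated.
* The pKa table is coarse (one mean and spread per functional-group class);
  it is a pluggable data file, not a pKa predictor.
* The mpi job-manager flag is accepted and falls back to the
  multiprocessing chunking contract; true multi-node execution is out of
  scope.
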