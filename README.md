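# xlassemble

Integrative rigid-body assembly of multi-subunit complexes into cryo-EM
density maps under cross-link distance restraints, in R.

Cryo-EM maps of large flexible machines — the motivating case is the
nexin–dynein regulatory complex (N-DRC) that bridges the doublet
microtubules of motile cilia — often resolve overall shape at 6–10 Å
without letting individual subunits be traced. The established
integrative answer combines three kinds of evidence: rigid-body fitting
of predicted/deposited subunit models into the density, Cα–Cα distance
restraints from cross-linking mass spectrometry (DSSO implies ≤ 35 Å),
and orthogonal support such as tissue coexpression. `xlassemble`
implements that pipeline as a tested R package:

* **Fit libraries** (`build_fit_library`) — `n` random rigid placements
  per subunit (uniform SO(3) rotations; default 100,000 searches),
  local multi-scale refinement, a ≥ 60% envelope-coverage filter at a
  volume-based low-density threshold, and 5 Å RMSD clustering into a
  ranked library of alternative fits.
* **Global assembly** (`anneal`, `enumerate_configurations`) —
  simulated-annealing Monte Carlo choosing one library candidate per
  subunit, scored by

  `total = w_cc (1 − cc) + w_xl Σ min(((d − 35)₊/10)², cap) + w_clash n_clash`

  i.e. map correlation + truncated harmonic DSSO penalties (robust to
  false-positive links) + an inter-subunit Cα clash term, with an
  exhaustive oracle for small spaces and ensemble-precision analysis
  across seeds.
* **Validation** (`validation_report`, `map_crosslinks`,
  `pearson_ftest`, `assign_heptad_register`) — masked map–model
  correlation (CCmask), density-explained fraction, per-copy cross-link
  distances and satisfaction at 35 Å, clash counts, Pearson/F-test
  coexpression evidence, and coiled-coil heptad-register assignment
  with polar-inclusion and missense annotation.
* **Synthetic ground truth** (`make_toy_complex`,
  `simulate_crosslinks`, `make_fixture_bundle`) — rigid toy complexes
  with known placements, simulated maps at stated resolution, and
  cross-link tables of true links plus planted decoys, so the whole
  pipeline runs and is verified without any download.

I/O covers PDB/mmCIF coordinates, MRC/CCP4 mode-2 maps (axis-order
normalization included), CSV cross-link and nTPM tables, and JSON
transforms/fit libraries.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic system (3 rigid subunits × 60 residues, 8 Å map, 12 true
DSSO links + 20% decoys):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_libraries.R
Rscript analysis/03_assemble.R
Rscript analysis/04_validate.R
Rscript analysis/05_sequence_evidence.R
```

Step 2–4 output on this system:

```
S1: 10 candidates, top cc 0.999 (coverage 1.00)
S2: 10 candidates, top cc 0.999 (coverage 1.00)
S3: 10 candidates, top cc 0.999 (coverage 1.00)
...
seed 301: total 0.3009 (density 0.0009, xl 0.3000, 0 clashes)
S1: 1 placement mode(s), populations 1
S1: 0.16 A CA RMSD to ground truth
S2: 0.15 A CA RMSD to ground truth
S3: 0.17 A CA RMSD to ground truth
<validation_report> CCmask 0.995 | density explained 100.0% | 0 inter-subunit clash(es)
true links satisfied: 12/12; decoys satisfied: 0/3
```

Read: every subunit's fit library ranks the true placement first
(correlation ≈ 1); annealing recovers all three placements to ≈ 0.2 Å;
the residual score is exactly the three planted decoys at the 0.1
truncation (3 × 0.1); the assembled model explains the full analyzed
envelope and satisfies every true restraint at 35 Å while no decoy is
satisfied.
Step 5 prints the heptad register of the DRC4 segment 276–289
(`NKRLADPLQKAREE` → `abcdefgabcdefg`), flagging N276 as a polar
inclusion at core position `a` and annotating the N276K missense change
as a neutral→positive substitution at the coiled-coil core.

The methods vignette (`vignettes/integrative-assembly.Rmd`) documents
the density model, the objective and its truncation rationale, the
annealing schedule, and what the synthetic conditions do and do not
emulate.

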