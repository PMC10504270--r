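---
title: "Integrative rigid-body assembly into cryo-EM maps with cross-link restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative rigid-body assembly into cryo-EM maps with cross-link restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlassemble)
```

## The problem

Large flexible assemblies such as the nexin–dynein regulatory complex
(N-DRC) of motile cilia are resolved by cryo-EM at resolutions where
individual subunits cannot be traced de novo. A standard integrative
strategy localizes them anyway: predicted or deposited atomic models of
the candidate subunits are fitted as rigid bodies into the density, and
chemical cross-linking mass spectrometry (XL-MS) supplies residue-pair
distance restraints that discriminate between otherwise similar
placements. For the amine-reactive, MS-cleavable linker DSSO, a linked
lysine pair implies a Cα–Cα distance of at most 35 Å.

`xlassemble` implements that strategy end to end:

1. **Fit libraries** — for each subunit, many random rigid placements
   are proposed in the map, locally refined, filtered by envelope
   coverage, and clustered into a ranked library of alternative fits.
2. **Global assembly** — one candidate per subunit is chosen by
   simulated-annealing Monte Carlo under a composite score combining
   density agreement, cross-link satisfaction, and steric exclusion.
3. **Validation** — masked map–model correlation (CCmask), the
   fraction of the analyzed density the model explains, per-copy
   cross-link distances against the 35 Å bound, inter-subunit clash
   counts, tissue coexpression tests, and coiled-coil heptad-register
   analysis.
4. **Synthetic ground truth** — a generator produces rigid toy
   complexes, simulated maps, and cross-link tables with known answers,
   so every stage is testable without any external download.

## Density model and fitting

An atomic model is rasterized by placing an isotropic Gaussian at every
atom, with width

σ = resolution / (π · √2),

a common map-simulation convention that puts the first zero of the
corresponding Fourier kernel at the nominal resolution. Amplitudes are
proportional to atomic number; reduced Cα-only models therefore get
uniform weights. Gaussians are truncated at 4.5 σ, which keeps the
analytic mass–integral identity (total map sum × voxel volume ≈
Σ weights · (2π σ²)^{3/2}) accurate to better than 1%.

Voxel convention: coordinates are in Å throughout; voxel `(i, j, k)`
(0-based) is *centered* at `origin + voxel_size · (i, j, k)`; the
in-memory array always has world X fastest. MRC/CCP4 files with
permuted `MAPC/MAPR/MAPS` headers are re-indexed on read so that voxel
world coordinates never change.

### Fit-library generation

`build_fit_library()` proposes `n_searches` placements: rotations drawn
uniformly from SO(3) (normalized Gaussian quaternions) and subunit
centroids drawn uniformly over the bounding box of the map envelope.
Each proposal is refined by a greedy multi-scale pattern search —
±translations along the axes and ±rotations about the centroid, with
step halving from 1 voxel / 10° down to an eighth of that — on the
*density-overlap* objective (mean interpolated map value at atom
positions, the classic `fitmap`-style score). The overlap objective is
used during refinement because it costs microseconds per evaluation;
the reported score of each refined candidate is the masked model-to-map
correlation (Pearson over the candidate's own density footprint), which
is what the library is ranked by. The exposed `refine_fit_local()`
defaults to refining the correlation itself, which is affordable for
individual placements.

The envelope filter follows the published protocol: a candidate is kept
only if at least 60% of its atoms lie inside the map envelope, defined
at a deliberately low density threshold. Because no specific threshold
value is recoverable for any given map, the default is volume-based:
the threshold whose super-level set encloses 1.5 × the nominal
molecular volume (1.21 Å³/Da) of the assembly. Survivors are
de-duplicated by leader clustering at 5 Å Cα RMSD (best-correlation
representative kept), and ties in correlation are broken by higher
coverage, then by lower proposal index, so library generation is
bit-reproducible for a fixed seed.

Defaults are `n_searches = 100000` and `coverage_min = 0.60`, matching
the full-scale protocol. The desk-scale analyses in `analysis/` and the
test suite use `n_searches = 2000`, which reliably lands dozens of
proposals in the correct basin for 60-residue subunits in maps of
roughly 10⁵ voxels; the resulting libraries hold the true placement as
their top-ranked candidate with sub-Å accuracy.

## Assembly objective

The optimizer picks one library candidate per subunit. A configuration
is scored (lower is better) by

total = w_cc · (1 − cc) + w_xl · Σ_links pen(d) + w_clash · n_clash

* `cc` — Pearson correlation between the target map and the sum of the
  chosen candidates' simulated maps, over the whole grid;
* `pen(d) = min( (max(0, d − 35)/s)² , xl_cap )` — a truncated harmonic
  upper-bound penalty on each link's Cα–Cα distance `d`, with softness
  `s = 10` Å; for multi-copy proteins `d` is the minimum over copies,
  mirroring how ambiguous links are evaluated in the reports;
* `n_clash` — the number of inter-subunit Cα pairs closer than 4 Å.

Defaults: `w = (1, 1, 0.1)`, `xl_cap = 0.1`.

**Why the truncation.** Real XL-MS restraint lists always contain false
positives, and the synthetic study conditions plant 20% decoys drawn
beyond 45 Å, which no correct model can satisfy. Under an untruncated
quadratic those unsatisfiable links dominate the objective even at the
ground truth — each decoy alone can contribute many times the density
term's entire range — so the optimum is pulled toward distorted
configurations that shorten decoy distances. Truncating each link's
penalty bounds the influence of any single restraint; the cap of 0.1,
a tenth of the density term's range, keeps one false link's leverage
below the density cost of misplacing a subunit, including
misplacements that largely reuse the subunit's own density. Setting
`xl_cap = Inf` restores the plain harmonic objective.

### Optimization

`anneal()` performs Metropolis Monte Carlo over candidate indices with
geometric cooling (default ratio 0.995 per step, 10,000 steps). Moves
are `resample_fit` (re-pick one subunit's candidate, probability 0.8)
and `swap_identical_copies` (exchange the placements of two copies of
the same protein, 0.2) — placements themselves stay frozen after the
library stage. The starting temperature is calibrated automatically so
that about half of 100 random uphill moves from the initial
configuration would be accepted. After cooling, a deterministic
best-response polish sweeps single-subunit candidate changes until none
improves the score, so the returned configuration is always a
coordinate-wise local optimum; ties are broken by lexicographic
candidate indices, and the whole run is reproducible from its seed.
`enumerate_configurations()` provides the exact exhaustive optimum for
spaces up to 10⁶ configurations and serves as the oracle in the tests.

`ensemble_analysis()` clusters per-subunit placements across
independent seeds (leader clustering, 3 Å default) and reports mode
counts, populations, and spreads — the layer that flags genuinely
ambiguous subunits that fit two positions equally well.

## Validation metrics

* **CCmask** — Pearson correlation between map and model-simulated
  density over voxels within 3 Å of any atom. External refinement
  suites define the mask with atom-specific radii and grid dilation, so
  agreement with published CCmask values is approximate by design.
* **Density explained** — fraction of voxels at or above a threshold
  lying within a mask radius of any model atom. The default radius
  scales with resolution (0.75 × resolution, at least 4 Å) because
  simulated density at resolution R extends roughly that far beyond
  atom centers. Note this quantity need not be monotone in the
  threshold for arbitrary models; it is reported at the analysis
  envelope threshold only.
* **Clash count** — inter-subunit Cα pairs under 4 Å, cell-list
  accelerated; a coarse excluded-volume check, not an all-atom
  clashscore.
* **Coexpression** — Pearson r between two genes' nTPM vectors across
  tissues, with the two-tailed P from `F = r²(n−2)/(1−r²)` on
  `(1, n−2)` degrees of freedom, exactly the F test on the slope of the
  simple linear regression (equivalently the two-sided t test). The
  bundled `synthetic_ntpm.csv` is generated data for demonstration, not
  Human Protein Atlas measurements.
* **Heptad registers** — all seven phases of the `abcdefg` repeat are
  scored by the fraction of hydrophobic residues ({A,V,L,I,M,F,W,Y};
  G, C, P excluded) at the core `a`/`d` positions; the maximal phase
  wins, ties report all maximal phases with the lowest index primary.
  Polar residues at `a`/`d` are listed as polar inclusions — e.g. the
  asparagine at position 276 of the DRC4 segment below — and prolines
  there trigger a register-breaking warning rather than an error.

```{r heptad}
h <- assign_heptad_register("NKRLADPLQKAREE", start_number = 276)
h
map_missense_to_register(h,
  data.frame(residue_number = 276, from = "N", to = "K"))
```

## The synthetic ground truth

`make_toy_complex()` builds rigid Cα-only subunits either as ideal
α-helices (rise 1.5 Å/residue, radius 2.3 Å, 100°/residue twist) or as
self-avoiding random walks (3.8 Å steps, 3.5 Å exclusion), places them
with uniform random orientations so that inter-subunit Cα distances
stay above `min_separation` (8 Å default) while each subunit touches
the growing complex within a bounded gap (so informative inter-subunit
cross-links exist), and records the exact placement transforms.

The default study conditions — chosen once and used by `analysis/`, the
tests, and `scripts/acceptance.R` — are: 3 subunits × 60 residues,
random-walk geometry, an 8 Å map on 2 Å voxels, 12 true cross-links
drawn below 30 Å (a safety margin under the 35 Å DSSO bound) and 20%
decoys drawn above 45 Å (so every decoy unambiguously violates the
bound), with no voxel noise (uniform Gaussian noise is available via
`noise_sd` but off by default). Random-walk geometry is the default
because three identical-length ideal helices are indistinguishable
rods: their ground truth is ill-posed up to permutation and flip, a
property of that toy geometry rather than of the method. Helix geometry
and identical-copy groups (the two-copies-of-one-protein scenario,
where only cross-links and swap moves can assign labels) are exercised
in dedicated tests. Intramolecular link pairs closer than 5 residues in
sequence are excluded as trivially satisfiable.

What the generator does *not* emulate: CTF and solvent noise,
resolution anisotropy, B-factor heterogeneity, conformational
flexibility, and map–model numbering mismatches. Passing the recovery
tests therefore demonstrates the correctness and robustness of the
search and scoring machinery under idealized rigid-body conditions, not
performance on experimental maps.

## Numerical choices and degenerate inputs

* Correlations are undefined on constant inputs and raise errors rather
  than returning NA; empty masks, empty candidate lists, and empty
  libraries are errors or warnings naming the offender.
* An empty cross-link set (or one with nothing mappable) reports
  `fraction_satisfied = 1` with `n_mapped = 0` flagged — vacuous truth
  instead of a division by zero.
* Rotations are validated as proper orthogonal to 1e-8; long move
  chains are re-projected onto SO(3) by SVD.
* Atoms outside the grid interpolate as uncovered/zero rather than
  erroring; a model entirely off-grid is an error.
* Residue identity is `(chain, author number)`; insertion codes are
  rejected, and per-protein integer offsets handle numbering mismatches
  between cross-link tables and models.
* File formats: PDB I/O through bio3d; mmCIF written with the canonical
  `_atom_site` column set and read by a minimal loop parser
  (cross-checked against an independent parser in the tests); MRC mode
  2 with ORIGIN, NSTART fallback, and axis-permutation normalization.

## Problem sizes

The bundled analyses run the 3 × 60-residue system with 2000-proposal
fit searches, 2000-step anneals, and 10 independent recovery seeds;
fit-library generation takes seconds per subunit and a full recovery
run a few minutes on one CPU. The same code scales to the full-protocol
100,000 searches by changing one configuration value.

## Known limitations

* Rigid placements only: no flexible refinement, no symmetry-aware
  fitting, no FFT-exhaustive translational search.
* The composite-score weights are declared package defaults, not values
  recovered from any published optimization protocol.
* CCmask here will not match external packages digit for digit (mask
  construction differs in detail).
* Cross-link tables are taken as given; no FDR modeling of the
  underlying spectra.
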