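---
title: "Semi-empirical scoring of peptide-MHC binding: models and methods"
author: "groovescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-empirical scoring of peptide-MHC binding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovescore)
```

## The problem and the model

Peptides presented by Major Histocompatibility Complex (MHC) molecules
drive T-cell recognition; predicting which peptides bind a given MHC
allele, and how tightly, is central to epitope discovery and to
understanding autoimmune risk alleles such as HLA-DRB1\*1501.
`groovescore` implements a structure-based, semi-empirical route to this
prediction: the binding free energy of a modelled peptide-MHC complex is
approximated as a linear combination of five physicochemical interaction
terms (the Fresno functional form),

$$
\Delta G_{\mathrm{bind}} \;\approx\; \beta_0
 + \beta_1\,\mathrm{HB} + \beta_2\,\mathrm{LIPO} + \beta_3\,\mathrm{BP}
 + \beta_4\,\mathrm{ROT} + \beta_5\,\mathrm{DESOLV},
$$

whose coefficients are calibrated per dataset against experimental
affinities.  Experimental IC50 values from competition assays are
converted to free energies via $\Delta G = R\,T\,\ln(\mathrm{IC50})$
(IC50 in molar, $T$ in Kelvin, result in kJ/mol), valid when the bound
peptide concentration is low enough that IC50 approximates the
dissociation constant.

The five terms, computed on a complex with typed atoms and placed polar
hydrogens:

* **HB** — intermolecular hydrogen-bond quality: for every donor-H ...
  acceptor triple across the interface,
  $\mathrm{block}(|d_{HA}-1.85\,\text{Å}|;0.25,0.65)\times
   \mathrm{block}(|\theta_{DHA}-180^\circ|;30^\circ,80^\circ)$,
  where `block(x; x1, x2)` is the ChemScore-family ramp: 1 below `x1`,
  linear to 0 at `x2`.
* **LIPO** — lipophilic complementarity: $\mathrm{block}(d;R_1,R_1+3.0)$
  summed over MHC-lipophilic/peptide-lipophilic heavy-atom pairs, with
  $R_1 = r_i + r_j + 0.5$ Å.
* **BP** — the same kernel over mismatched pairs (polar against
  lipophilic, both directions): a penalty descriptor for buried polarity.
* **ROT** — side-chain rotatable bonds frozen on binding, a fixed
  per-residue count over the peptide sequence (0 for Ala/Gly/Pro up to 4
  for Lys/Arg); it depends only on the sequence, never on coordinates.
* **DESOLV** — desolvation:
  $G_{\mathrm{solv}}(\mathrm{complex})-G_{\mathrm{solv}}(\mathrm{MHC})
  -G_{\mathrm{solv}}(\mathrm{peptide})$, by default with
  $G_{\mathrm{solv}} = \sum_i \sigma(\mathrm{class}_i)\,\mathrm{SASA}_i$
  (probe 1.4 Å, per-class atomic solvation parameters).  A file-based
  hook accepts per-complex energies from an external continuum
  (Poisson-Boltzmann) solver for users who prefer that level of theory;
  within the linear model the calibration coefficient absorbs any linear
  rescaling between the two conventions.

Atom classes follow the ChemScore convention and are a pure function of
residue + atom name: *lipophilic* = C or S bonded only to C/S/H;
*donor* = N/O carrying hydrogen at standard protonation; *acceptor* = O,
or N without hydrogen; *donor_acceptor* = hydroxyl oxygens and both
histidine ring nitrogens; everything else *polar_neutral*.  Two
deliberate choices here: proline's backbone nitrogen is typed
`polar_neutral` (a tertiary amide nitrogen is neither a donor nor a
meaningful acceptor), and the **BP** "polar" side comprises the
donor/acceptor/donor_acceptor classes only — counting `polar_neutral`
carbons as polar would let backbone carbons dominate a term meant to
penalise genuinely polar burial.  Both are configurable
(`term_params(bp_polar_classes=)`).

Radii come from a bundled PARSE-style per-element table (C 1.70, N 1.50,
O 1.40, S 1.85, H 1.00 Å), overridable by file.

## Threading

To score a peptide without its own crystal structure, the sequence is
threaded onto the peptide backbone of a reference complex: backbone
N/CA/C/O coordinates are copied exactly, positions with an unchanged
residue keep their native side chains, and mutated positions are rebuilt
from idealised internal coordinates.  The built-in side-chain engine
scans every combination of canonical chi values ({-60, 60, 180} degrees
per rotatable chi), placing residues greedily from the N- to the
C-terminus and keeping the rotamer with the fewest steric clashes
(non-bonded heavy-atom pairs closer than $0.8(r_i+r_j)$, 1-2/1-3
neighbours excluded); ties fall to the smallest absolute chi sum, then
enumeration order, so the result is fully deterministic.  This is a
coarse but transparent stand-in for a dedicated side-chain packer; since
externally rebuilt models can be supplied as pre-threaded PDB files, a
SCWRL-class program can be dropped in without touching the rest of the
pipeline.  No post-threading energy minimisation is performed.  Only
peptides of exactly the reference length are threaded — the backbone is
never remodelled — which is also why binding tables are filtered by
length before training.

A genuinely open question in this design is whether identity positions
should keep native side chains or also be rebuilt; we keep them (the
native conformation is the best available sample of that rotamer), and
the choice is exposed via `thread_peptide(keep_identical=)` for
sensitivity analysis.

## Calibration and evaluation

Terms and affinities are joined into an $n\times 5$ descriptor matrix and
calibrated by PLS1 (NIPALS), with columns mean-centred and
unit-variance scaled by default (scaling is configurable; q2 is invariant
to affine rescaling of any column in the full-rank case, so this choice
mainly matters for rank-deficient data).  With as many components as the
descriptor rank, PLS reproduces ordinary least squares — asserted
numerically in the test suite — and with fewer it degrades gracefully on
the strongly collinear term sets that threaded models produce.  The
default component count is $\min(5, n-2)$; per-dataset selection by
minimal PRESS is available (`select_components()`).

Evaluation is leave-one-out cross-validation by an explicit refit loop
(no shortcut formulas): $\mathrm{PRESS}=\sum_i (y_i-\hat y_{(-i)})^2$,
$q^2 = 1-\mathrm{PRESS}/\sum_i (y_i-\bar y)^2$, and
$S_{\mathrm{press}} = \sqrt{\mathrm{PRESS}/n}$ (the RMSEP
cross-validation estimator).  Folds follow input order; the module
contains no randomness.

## Reference-set experiments

Because the descriptors are measured from a *modelled* geometry, the
choice of reference structure(s) matters.  `enumerate_reference_sets()`
builds every combination that uses one structure per shared native
peptide plus all unique-peptide structures (a Cartesian product over the
multi-structure groups; the bundled seventeen-entry HLA-A2 table gives
$4\times3\times7 = 84$ six-member sets).  `run_refset_experiment()`
scores each member in its own crystal structure ("native" mode),
cross-validates per set, and rank-correlates $q^2$ and
$S_{\mathrm{press}}$ against the set's mean pairwise RMSD (whole
structure, MHC only, peptide only; Kabsch superposition over shared
heavy atoms) and mean resolution.  Native mode is the default reading of
the experiment — the structure table supplies exactly one affinity per
native peptide — and a threaded mode can be assembled from the same
building blocks.  Structures with differing peptide lengths can only be
compared on the MHC selection; `superpose_structures()` matches atoms by
role, residue index and atom name, so insertions are not handled (none
occur among same-allele MHC frames).

## The synthetic-data generator

Real crystal structures cannot ship with the package, so the test suite
and the acceptance script rest on two generators:

* `make_toy_complex()` writes a minimal two-chain PDB whose interface
  realises an exact list of requested contact geometries.  Each
  engineered contact lives in an isolated "arena" 40 Å from everything
  else, so no unintended atom pair falls inside any kernel's support and
  the expected term vector is known in closed form (ramp formula for
  HB/LIPO/BP on the coordinate-rounded geometry, two-sphere spherical-cap
  areas for DESOLV, the residue table for ROT).  Probe atoms are
  deliberately detached from their residues' bonded geometry: these
  fixtures are scoring-kernel probes, not plausible proteins, and they
  exercise none of the cooperative packing, backbone strain or water
  structure of real interfaces — passing them validates the arithmetic
  of the terms, not the physics of the model.
* `simulate_binding()` draws term vectors uniformly from realistic
  ranges (HB 0-10, LIPO 10-80, BP 0-40, ROT 5-30, DESOLV -60-20) and
  generates affinities from a known linear model plus Gaussian noise
  (default sd 0.5 kJ/mol, 20 samples — chosen to mirror the size of a
  typical curated single-allele binding set).  Parameter recovery on
  these data validates the calibration path end to end.

Both generators are deterministic given their integer seed (the fixture
generator restores the caller's RNG state, so fixtures never perturb
surrounding simulations).

## Numerical choices and precision

* SASA is computed by Shrake-Rupley sampling on a fixed Fibonacci
  lattice (960 points/atom by default; hydrogens carry no surface).  The
  area quantum is $4\pi(r+1.4)^2/960 \approx 0.05$ Å$^2$, so DESOLV
  values agree with closed-form two-sphere references, and with
  themselves under rigid rotation, only to about 0.05 kJ/mol — the other
  four terms are exact to machine precision under rigid motion.  Tests
  assert HB/LIPO/BP/ROT at 1e-9 and DESOLV at this quadrature tolerance.
* Pairwise kernels have finite support (at most $R_1+3.0 \le$ ~7.1 Å),
  so the engines evaluate nothing beyond an 8 Å cutoff.
* Duplicate IC50 measurements for one peptide are resolved by policy:
  the default drops peptides whose values disagree by more than 10-fold
  (an operationalisation of discarding "inexplicably discrepant"
  entries) and merges the rest by geometric mean; `keep_first` and
  unconditional `geometric_mean` are available.  IC50 units are a
  mandatory per-file declaration — published tables are inconsistent
  about what a "nmol" column means, and a wrong guess silently shifts
  every free energy by a constant.
* Altloc resolution keeps the highest-occupancy conformer, ties to
  altloc A.  Missing side-chain atoms are tolerated in the MHC frame but
  residues must carry a complete backbone; beta-2-microglobulin (and any
  chain mapped to role `mhc`) contributes to the term sums.
* Hydrogen placement is geometric and idealised (amide H in-plane anti
  to the preceding carbonyl, sp2 ring/amide H in-plane, sp3 hydroxyl/
  ammonium H staggered; N-H 1.01 Å, O-H 0.96 Å, His epsilon tautomer).
  An optional heavy-atom hydrogen-bond mode
  (`term_params(hb_heavy_mode=TRUE)`, ideal D...A 2.85 Å) covers
  structures where protonation is unreliable.

## Problem sizes used in tests and the acceptance script

The bundled acceptance script regenerates everything it reports: the
IC50 conversions of the bundled 20-peptide table, the 84-combination
enumeration of the bundled 17-structure table, term-vs-expectation
deviations over 10 fixtures, coefficient recovery over 20 simulated
datasets of 20 samples, an 18-sample LOOCV against an independent
`lm()` refit loop, a 6-complex synthetic validation run, and a
24-point structural-perturbation experiment (8 noise levels x 3
replicate sets of 6 complexes) whose Spearman correlation between q2
and mean pairwise RMSD reproduces the negative direction of the
structural-similarity effect.  These sizes keep the full run to a few
seconds while leaving each statistic comfortably away from its decision
boundary.

## Limitations

* The crystal-structure benchmarks (the five-structure HLA-A2 validation
  study, the DR15/1YMM run, the 84-combination experiment on real
  structures) require the original PDB entries, which must be supplied
  locally; the package ships only their printed binding tables.
* The side-chain engine is a canonical-rotamer clash minimiser, not a
  rotamer-library packer; the SASA desolvation is a surface-area model,
  not Poisson-Boltzmann.  Both choices trade fidelity for determinism
  and replaceability, and both are behind interfaces that accept
  externally computed inputs.
* The linear five-term form inherits the known blind spots of
  semi-empirical scoring: no explicit water, no entropy beyond ROT, no
  polarisation, and coefficients that are only as transferable as the
  training set's structural homogeneity — which is precisely the effect
  the reference-set experiment quantifies.
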