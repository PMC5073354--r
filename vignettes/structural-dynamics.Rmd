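---
title: "Dissecting direct and allosteric protease inhibition from structures and ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting direct and allosteric protease inhibition from structures and ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopath)
```

## The scientific problem

Serine proteases of the chymotrypsin (S1) fold, such as the kallikrein-related
peptidase KLK4, can be switched off in two ways: directly, by a substrate-like
inhibitor occupying the active-site cleft (for example the 14-residue bicyclic
sunflower trypsin inhibitor SFTI-1, a Laskowski-mechanism inhibitor), and
indirectly, by effectors binding at an *exosite* — here a His25/Glu77 metal
site more than 20 Å from the catalytic triad — that bias the enzyme's
conformational ensemble toward inactive, zymogen-like states.

`allopath` implements the structural-dynamics toolbox needed to dissect both
mechanisms from crystal structures and conformational ensembles: interface
characterisation, ligand-associated conformational-change detection,
coarse-grained normal modes with ensemble projection, mode-based dynamical
cross-correlation, local energetic frustration networks with site-to-site
path tracing, and ensemble clash screening of a grafted inhibitor. Every
stage is exercised end-to-end by seeded synthetic generators, so the whole
pipeline is testable without downloading a single coordinate file.

## Structures, ensembles and superposition

Structures are flat atom tables (chain, residue number, insertion code,
residue and atom names, altloc, coordinates, occupancy, B-factor, element,
HETATM flag) read and written as fixed-column PDB; multi-model files become
`Ensemble` objects, the stand-in for MD snapshot sets. Numbering is taken
verbatim from the file — S1 proteases use chymotrypsin numbering (catalytic
triad His57/Asp102/Ser195) and renumbering would silently break site
definitions, so none is ever applied.

Design choices a maintainer should know:

* **Altlocs** default to highest occupancy, ties broken by label order
  ('A' first): deterministic and the common convention.
* **Atom matching** between structures uses
  (chain, residue number, insertion code, atom name) keys. Unmatched atoms
  are an *error* unless the caller passes `on_unmatched = "exclude"`;
  crystal structures with disordered loops (missing density) would otherwise
  be silently intersected, hiding exactly the flexible regions one is
  studying.
* **Superposition** is Kabsch via SVD, restricted to proper rotations
  (determinant +1): a reflection can fit mirror images of a chiral molecule
  and must never be returned. Degenerate (collinear) point sets are refused;
  the rotation would be arbitrary about the line.
* **B-factor normalisation** z-scores within a structure using the
  *population* standard deviation, so normalised values have mean 0 and
  standard deviation exactly 1 — the convention that makes flexibility
  comparable across structures refined at different resolutions.

## Interface characterisation

Solvent-accessible surface area uses the Shrake–Rupley construction: each
atom's sphere (van der Waals radius + probe, default probe 1.4 Å = water) is
sampled at `n_points` quasi-uniform golden-spiral points (default 960, ~1–2%
accuracy; the deterministic spiral keeps results bit-reproducible). Buried
area per residue is ΔASA = ASA(isolated side) − ASA(in complex), with
percent burial relative to the isolated side and each residue's fractional
contribution to its side's total. A residue's share of buried area is
implemented as its ΔASA share (not contact-area share) — the natural reading
when interfaces are summarised residue-by-residue.

Hydrogen bonds use heavy-atom criteria, since ~1 Å crystal structures still
carry no refined hydrogens: donor (N/O/S bearing an implicit H, from a
residue-typing table) to acceptor (N/O/S) distance ≤ 3.5 Å, and, when the
donor's bonded antecedent atom is present, an antecedent–donor–acceptor
angle ≥ 90°. Salt bridges pair basic nitrogens (Lys NZ, Arg guanidino,
optionally His imidazole) with acidic oxygens (Asp/Glu carboxylates,
C-terminal OXT) at ≤ 4.0 Å, deduplicated to one bridge per residue pair.
These thresholds reproduce common practice rather than any specific server's
undocumented criteria, and they are arguments, not constants — counts should
always be quoted together with the criteria that produced them.

## Ligand-associated conformational change

The comparison rule for deciding whether a structural difference is
associated with ligand binding:

1. one *global* backbone (N, CA, C, O) superposition over all shared
   residues — never over the candidate segment itself, which would be
   circular — then per-residue Cα–Cα deviation;
2. maximal runs of ≥ 3 consecutive residues all deviating > 0.5 Å
   (chain breaks and numbering gaps terminate runs, so disordered loops
   cannot bridge a segment);
3. each segment's deviations are compared against the same residues'
   deviations in a *third* structure with an unliganded active site, by a
   two-tailed Welch t-test. The verdict is `shared` when the control also
   exceeds the threshold over the segment, `ligand-associated` when
   p < 0.05 and the query deviates more than the control, otherwise
   `indeterminate`.

The choice of what enters the t-test (per-residue Cα deviations over the
segment, query-vs-reference against control-vs-reference, unequal-variance
two-tailed) is the smallest-assumption reading of a t-test on deviation
values; it is exposed via `classify_segments()` so alternatives can be
swapped in. No multiple-testing correction is applied by default — one test
per detected segment mirrors how such calls are made in practice — and the
0.5 Å / 3 residues / α = 0.05 defaults are plain arguments.

## Elastic-network modes, projections, population shifts

All mode-based analyses run on a Cα anisotropic elastic network model:
springs of uniform stiffness γ join every Cα pair within 15 Å, giving the
standard ANM Hessian whose 3×3 superelements are −γ (r̂ ⊗ r̂) per contact.
This deliberately replaces all-atom force-field normal modes: the
low-frequency subspaces of elastic-network and all-atom calculations overlap
strongly, no force field or minimisation stage is needed, and everything
computed downstream (variance fractions, projections, cross-correlations) is
model-generic. The price is that any all-atom variance figure (such as a
"first five modes carry ~68% of the dynamics" statement) becomes an
approximate target, which is why the acceptance tolerance on it is wide
(±15 percentage points).

Conventions and numerical choices:

* A connected network has exactly six zero-frequency rigid-body modes; the
  diagonalizer *verifies* this and errors otherwise (a disconnected network
  is reported with its component sizes rather than silently producing extra
  zero modes).
* **Modes are numbered including the six rigid-body modes**, so the first
  internal mode is mode 7 and "mode 8" is the second internal mode —
  matching the numbering used when discussing collective motions of
  proteins.
* Variance fractions and fluctuations weight internal modes by 1/λ (thermal
  amplitudes, uniform masses); equal weighting is available via a flag.
* Ensemble frames are Kabsch-superposed onto the mode reference before
  projection, removing rigid-body degrees of freedom; projecting the
  reference itself gives exactly zero on every mode.
* `population_shift()` reports, per mode, the difference of projection
  means, a pooled-SD effect size and a Welch p-value, ranking modes by
  |effect|. With Gaussian nulls the false-positive rate at α is α by
  construction; the acceptance suite verifies ≤ 5% (+3 binomial standard
  errors for a 200-rep estimate).

Dynamical cross-correlation is reconstructed from modes:
C(i,j) = Σₖ vₖ(i)·vₖ(j)/λₖ, normalised by the marginal fluctuations so the
diagonal is exactly 1. The number of modes (40 and 100 are both conventional
for whole-protein maps) is a parameter with no privileged value; DCC is
invariant to uniform γ rescaling, which the tests assert.

## Local frustration

Frustration asks, contact by contact, whether the native residue pair is
energetically better than typical alternatives: decoys re-assign the two
identities uniformly over the 20 amino-acid types at fixed geometry, and

F = (⟨E_decoy⟩ − E_native) / sd(E_decoy).

**Sign convention:** larger F = native more favourable than decoys =
*minimally* frustrated; F ≤ −1 marks *highly* frustrated contacts, F ≥ +0.78
minimal, in between neutral (the published frustratometer thresholds;
configurable). Contacts use Cβ centres (Cα for glycine), 9.5 Å cutoff,
sequence separation ≥ 3.

The pairwise energy function is a deliberately simple stand-in for the
transferable coarse-grained potentials used by frustration servers: a
hydrophobic-burial term (product of positive Kyte–Doolittle hydropathies)
plus an electrostatic term (product of formal charges), modulated by a
cosine distance switch (full weight ≤ 6.5 Å, zero ≥ 9.5 Å). What the package
preserves *exactly* is the decoy/z-score machinery and classification logic
that define mutational frustration; absolute F values are model-dependent
everywhere and are not comparable across potentials. Because the distance
switch scales native and decoy energies identically, F is independent of it
— a useful invariant the tests exploit.

A note on Monte-Carlo error: the sampled-decoy estimator of F is a ratio of
two estimated moments of a discrete, skewed 400-value distribution, so its
standard error is appreciably larger than the naive 1/√n (empirically 2–2.5×
at n = 10⁴). The test suite therefore checks sampled-vs-exhaustive agreement
against the *empirical* per-contact SE over independent replicates, at 3.5
SEs to cover taking the maximum over all contacts.

`frustration_path()` views the highly frustrated contacts as a graph
(nodes = residues) and returns the fewest-edge path between two sites,
breaking ties in favour of the largest summed |F| — the most strongly
frustrated route — which is the natural candidate for an
exosite-to-active-site communication channel.

## Ensemble clash screening

To ask whether receptor motions would obstruct substrate binding, the
crystallographic inhibitor is grafted onto every ensemble frame by
superposing the reference receptor onto the frame (whole receptor backbone
by default) and applying that rigid transform to the ligand — its internal
geometry is untouched by construction. A receptor–ligand atom pair clashes
when its distance is below the van der Waals sum minus 0.4 Å (the standard
steric-overlap convention; configurable). The crystallographic interface
itself must not self-report, so a whitelist of native contact pairs (within
vdW sum + 0.5 Å in the reference complex) is built once at grafting time;
frame 0 of an unperturbed ensemble is then clash-free by construction.
Detection is an exact brute-force pair scan — at desk scale there is nothing
to gain from spatial hashing, and the tests pin the implementation to an
independent double-loop oracle anyway.

## What the synthetic generators do and do not emulate

The generators produce the *statistical situations* the analyses must
recognise, with machine-readable planted truth alongside:

* `make_helix()` — ideal α-helix backbone (100°/residue, 1.5 Å rise) with
  Cβ pseudo-atoms; geometrically regular, chemically approximate (no
  peptide-bond closure, minimal side chains).
* `make_deviation_triple()` — a reference, a copy with a residue segment
  rigidly displaced (the "liganded" structure), and a noisy control
  (sd 0.1 Å, a typical coordinate-precision scale for well-refined
  structures).
* `make_mode_ensemble()` — frames displaced along a chosen elastic-network
  mode with Gaussian amplitudes plus isotropic noise: the population-shift
  situation.
* `make_interface_complex()` — a hand-placed two-chain complex in which
  exactly three donor–acceptor pairs satisfy H-bond geometry and one
  Lys–Asp pair forms a salt bridge at 3.2 Å, plus a rigid helix anchor
  domain that stabilises whole-receptor superpositions the way the bulk of
  a real protease does.
* `make_clash_trajectory()` — receptor copies in which one residue
  translates into the ligand volume during a known frame window.

A green test on these fixtures establishes that the *machinery* is correct:
geometry, statistics, graph logic, bookkeeping. It does not establish
force-field realism, water structure, side-chain packing, or that any
particular protein behaves like the fixture — conclusions about a real
system still require its real coordinates and ensembles. All generators are
seed-deterministic (bit-identical re-runs), and recovery tests consume the
emitted truth rather than re-stating expected values.

## Reproducing published measurements

The deposited-structure measurements the package is designed to reproduce
(backbone RMSDs between liganded forms, interface bond counts, per-residue
burial shares, exosite-to-active-site distances, mean B-factors, mode
variance fractions) are implemented in `tests/testthat/test-acceptance.R`
and in `scripts/acceptance.R`. They require the deposited PDB entries
(4K8Y, 2BDG, 4KGA, 1SFI, 3P8F) under `inst/extdata/pdb/`; in an offline
build those two test blocks fail with an explanatory message rather than
being skipped — the download-free property battery runs everywhere.

## Known limitations

* PDB fixed-column format only; mmCIF, structure factors and maps are out
  of scope.
* The elastic network uses uniform node masses and spring constants; no
  secondary-structure-aware stiffening.
* The frustration potential is a two-term toy: adequate for planted-truth
  recovery and for the z-score machinery, not for quantitative comparison
  with server-computed frustration indices.
* H-bond detection has no protonation-state logic (His tautomers, low-pH
  carboxylates) and treats S weakly-polar atoms permissively.
* Segment classification tests each detected segment once; enable the
  Bonferroni option when scanning many structures.
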