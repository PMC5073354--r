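# allopath

Structural-dynamics analysis of direct (active-site) and indirect
(exosite/allosteric) inhibition of serine proteases, for structural
biologists and protein-dynamics researchers working with crystal structures
and conformational ensembles.

Chymotrypsin-fold (S1) proteases such as KLK4 are inhibited directly by
substrate-like inhibitors (e.g. the bicyclic peptide SFTI-1 in the S1
pocket) and indirectly by effectors at remote exosites — such as a
His25/Glu77 metal site > 20 Å from the catalytic triad His57/Asp102/Ser195 —
that shift the conformational ensemble toward inactive states. `allopath`
implements the analyses needed to dissect both mechanisms:

- **Structure I/O & superposition** — fixed-column PDB reader/writer
  (multi-model files become ensembles; metals survive as HETATM), altloc
  resolution, Kabsch superposition (proper rotations only), RMSD with loud
  handling of unmatched atoms, per-residue and normalized B-factors.
- **Interface characterisation** — Shrake–Rupley SASA (probe 1.4 Å),
  per-residue buried area ΔASA = ASA_isolated − ASA_complex and percent
  burial, geometric hydrogen bonds (heavy-atom: d ≤ 3.5 Å, antecedent angle
  ≥ 90°) and salt bridges (basic N ⋯ acidic O ≤ 4.0 Å).
- **Ligand-associated conformational change** — global backbone alignment,
  per-residue Cα deviation, maximal runs of ≥ 3 consecutive residues
  > 0.5 Å, and a two-tailed Welch t-test against a third (unliganded)
  structure to classify each segment as ligand-associated / shared /
  indeterminate.
- **Elastic-network modes** — Cα anisotropic network model (cutoff 15 Å),
  Hessian `H_ij = −γ (r̂_ij ⊗ r̂_ij)`, exactly six rigid-body modes verified,
  modes numbered from 7 for the first internal mode; 1/λ-weighted variance
  fractions and fluctuations; projection of superposed ensembles onto modes;
  per-mode population-shift statistics (effect size + Welch p);
  mode-based dynamical cross-correlation
  `C(i,j) = Σ_k v_k(i)·v_k(j)/λ_k / √(MSF_i MSF_j)`.
- **Local frustration** — decoy-based mutational frustration
  `F = (⟨E_decoy⟩ − E_native)/sd(E_decoy)` per contact (Cβ centres, 9.5 Å,
  |i−j| ≥ 3), classes minimal (F ≥ 0.78) / neutral / high (F ≤ −1), and
  shortest-path tracing through highly frustrated contacts between two
  sites (ties favour the most frustrated route).
- **Ensemble clash screening** — graft a reference-complex ligand onto each
  ensemble frame by receptor superposition, report vdW overlaps ≥ 0.4 Å
  excluding whitelisted native contacts, and time-resolve which receptor
  residues clash with which ligand positions.
- **Synthetic data** — seeded generators for every fixture class (ideal
  helices, planted deviation triples, mode-displaced ensembles, planted
  interface bonds, planted clash windows) emitting machine-readable truth.

## Worked example

```r
library(allopath)

## 1. detect a planted ligand-associated segment
tr <- make_deviation_triple(n_res = 60, segment = 20:24, shift = 1.0, seed = 1)
out <- compare_structures(tr$query, tr$reference, tr$third)
out$calls
#  chain start end length  mean_dev   max_dev mean_dev_third      p_value
#      A    20  24      5 0.8925072 0.9108625      0.2075615 4.485308e-05
#            verdict
#  ligand-associated
```

The planted 5-residue, 1 Å displacement is recovered exactly (the global
fit absorbs ~0.1 Å of the shift); the control structure deviates only at
its 0.1 Å noise floor, so the Welch test calls the segment
ligand-associated.

```r
## 2. modes, planted population shift along mode 8
h <- make_helix(30)
m <- enm_modes(build_enm(h, cutoff = 15), n_modes = 50)
variance_fraction(m, 5)
# [1] 0.6090398

apo  <- make_mode_ensemble(h, mode_index = 8, amplitude_mean = 0, n_frames = 100, seed = 2)
holo <- make_mode_ensemble(h, mode_index = 8, amplitude_mean = 2, n_frames = 100, seed = 3)
population_shift(project_ensemble(apo$ensemble,  m, 7:11),
                 project_ensemble(holo$ensemble, m, 7:11))[1:3, ]
#  mode   mean_a   mean_b mean_shift effect_size  p_value
#     8 -0.02371  2.00898    2.03269       4.004 5.65e-69
#    10  0.00563 -0.00149   -0.00712      -0.131 3.55e-01
#    11 -0.00119  0.00482    0.00601       0.120 3.97e-01
```

Mode 8 (the second internal mode) carries the planted 2 Å mean shift with
effect size ≈ 4; all other modes stay at the origin.

```r
## 3. interface bonds on the planted two-chain complex
ic <- make_interface_complex()
nrow(find_hbonds(ic$complex, sel(chain = "A"), sel(chain = "I")))        # 3
nrow(find_salt_bridges(ic$complex, sel(chain = "A"), sel(chain = "I")))  # 1
```

## Command line

A thin CLI wraps the library (see `inst/cli/allopath`):

```sh
allopath rmsd --mobile a.pdb --target b.pdb --select backbone
allopath interface --pdb complex.pdb --side-a "chain A" --side-b "chain I" --probe 1.4
allopath compare --query holo.pdb --ref other.pdb --third apo.pdb
allopath modes --pdb protein.pdb --cutoff 15 --n-modes 100
allopath frustration --pdb protein.pdb --site-a "77,25" --site-b "57,102,195" --seed 1
allopath clash --ensemble traj.pdb --complex complex.pdb --overlap 0.4
allopath fixtures --kind mode_ensemble --seed 1 --out fixtures/
allopath run --config run.cfg
```

See `vignettes/structural-dynamics.Rmd` for the models, parameter choices,
what the synthetic generators do and do not emulate, and known limitations.
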