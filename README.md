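# ligaff

Contact-based prediction of protein–ligand binding affinity in R.

Scoring functions for ranking ligands against a receptor often need
structure preparation, force fields and surface calculations. ligaff
implements a deliberately simple alternative for virtual screening and
docking-pose ranking: count the intermolecular atomic contacts of a
complex, type them by element, add a shifted-Coulomb electrostatic term,
and feed them to a linear model

```
dG_score = 0.343794·E_elec − 0.037597·AC_CC + 0.138738·AC_NN
         + 0.160043·AC_OO − 3.088861·AC_XX + 187.011384
```

where `AC_kk` is the number of receptor–ligand atom pairs within 10.5 Å
between atoms of class k (C, N, O; X = all other heavy atoms and polar
hydrogens) and `E_elec` is the intermolecular Coulomb energy (dielectric
10, 8.5 Å cutoff, shift `(1−(r/rc)²)²`), in kcal/mol. Lower scores mean
stronger predicted binding: the coefficients were trained on free energies
`ΔG = RT·ln(Ki)`. Ligands are ranked by the score averaged over their top
docked poses.

The package is aimed at computational chemists and structural
bioinformaticians who want a fast, transparent ranking score, the machinery
to retrain it on their own affinity tables, and the standard evaluation
metrics for the result. It provides:

* **I/O** — PDB/PQR complexes (`read_complex`, ligand auto-detection,
  altloc and water handling, sidecar charge tables), SD/MOL V2000 molecule
  graphs (`read_sdf`), model JSON.
* **Scoring** — `count_contacts`, `e_elec`, `dg_score`,
  pose averaging (`score_poses`) and ranking (`rank_ligands`), plus the
  refinement-stage combiner `haddock_it1_score`.
* **Retraining** — `ki_to_dg`, OLS (`fit_affinity`), AIC stepwise selection
  (`aic_stepwise`), repeated k-fold `cross_validate`.
* **Ligand-based companion** — Carhart atom-pair fingerprints
  (`atom_pair_fingerprint`), Tanimoto kernels (`similarity_matrix`),
  ε-SVR on the precomputed kernel (`fit_ap_svr`), and
  `most_similar_reference` for similarity-guided receptor selection.
* **Evaluation** — `kendall_tau` (tau-b), `pearson`, PPV/enrichment curves
  (`ppv_curve`, `evaluate_ranking`), ligand RMSD after receptor-backbone
  superposition (`ligand_rmsd`), top-N `success_rate`.
* **Toy-data generators** with built-in brute-force oracles
  (`make_toy_complex`, `make_training_table`, `make_molecule_set`).

## Worked example

```r
library(ligaff)

tc   <- make_toy_complex(fixture_spec(seed = 7))   # toy complex, 50 + 10 atoms
prof <- count_contacts(tc$complex)                 # ACs at 10.5 A
prof
#> Contact profile (cutoff 10.5 A): 50 receptor x 10 ligand atoms
#>  CC  CN  CO  CX  NN  NO  NX  OO  OX  XX
#> 120  86  19   8   4   2   1   0   0   0

ee <- e_elec(tc$complex)                           # 0.7239 kcal/mol
dg_score(feature_vector(prof, ee))
#> [1] 183.3036
```

120 carbon–carbon and 4 nitrogen–nitrogen contacts plus a slightly
repulsive electrostatic term give a score of 183.30 — about 3.7 score units
below the model's intercept (187.01), i.e. this toy pocket looks marginally
better than an empty interface. Screening ranks ligands by the mean score
over their top 10 poses:

```r
poses <- lapply(1:10, function(i) make_toy_complex(fixture_spec(seed = i))$complex)
score_poses(poses, ligand_id = "LIG-1")
#> Pose score LIG-1: mean 186.1691 over 10 pose(s)
```

Retraining on a synthetic table drawn from the shipped coefficients with
1.5 kcal/mol noise recovers them, and AIC stepwise selection finds exactly
the five generating features:

```r
gen <- make_training_table(200, seed = 42)
aic_stepwise(gen$table)
#> Affinity model fit (n = 200 ):
#>      e_elec       ac_cc       ac_nn       ac_oo       ac_xx (Intercept)
#>    0.348885   -0.038848    0.187388    0.087208   -3.130603  188.905771
#> RSS 375.4874  AIC 137.9815

cross_validate(gen$table, k = 4, repeats = 5, seed = 42, method = "ols")
#> 4-fold cross-validation, 5 repeat(s)
#>   pearson_r    0.9915 +/- 0.0002
#>   kendall_tau  0.9113 +/- 0.0012
#>   rmse         1.4703 +/- 0.0205
```

The held-out RMSE (1.47 kcal/mol) sits at the injected noise floor, as it
should when the model family matches the generator.

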