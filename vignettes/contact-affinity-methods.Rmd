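---
title: "Contact-based affinity scoring: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-based affinity scoring: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligaff)
```

## The scoring model

ligaff predicts relative protein–ligand binding affinity from the simplest
structural signal available in a docked or crystallographic complex: the
number of intermolecular atomic contacts, typed by the elements involved.
An atomic contact (AC) is a receptor-atom/ligand-atom pair within 10.5 Å.
Atoms are grouped into four classes — C, N, O, and X for every other heavy
element together with polar hydrogens — and the score is a linear
combination of the homogeneous class-pair counts plus an intermolecular
electrostatic energy term:

$$
\Delta G_{\mathrm{score}} = 0.343794\,E_{\mathrm{elec}}
 - 0.037597\,\mathrm{AC}_{CC} + 0.138738\,\mathrm{AC}_{NN}
 + 0.160043\,\mathrm{AC}_{OO} - 3.088861\,\mathrm{AC}_{XX} + 187.011384
$$

The shipped coefficients (`default_affinity_model()`) were obtained by
training against free energies derived from inhibition constants,
$\Delta G = RT\ln K_i$, so lower scores mean stronger predicted binding and
`rank_ligands()` sorts ascending. The magnitude of the score is only
meaningful relative to the training regime; the package's primary use is
ranking.

Assumptions worth keeping in mind:

* The contact counts are taken on the coordinates as given. No refinement or
  minimisation is performed, so scores for structures prepared outside the
  refinement protocol the coefficients were trained under are approximate —
  in particular the electrostatic term, which is sensitive to the charge
  scheme.
* Partial charges are *inputs* (PQR files or a sidecar `serial<TAB>charge`
  table), never assigned internally, because charge assignment is
  scheme-dependent. When a pose arrives without charges, `score_poses()`
  scores it with $E_{\mathrm{elec}} = 0$ and warns rather than failing: the
  contact terms dominate at screening time.
* Pose-averaged scoring (`score_poses()`, default top 10, file order =
  docking rank) deliberately trades pose accuracy for robustness: averaging
  over a heterogeneous pose ensemble is less sensitive to the exact ligand
  orientation than scoring the single top pose.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| contact cutoff | 10.5 | Å | the radius the shipped coefficients were optimised at; counts grow monotonically with it, so it must match the model in use |
| electrostatics cutoff | 8.5 | Å | pair cutoff of the refinement convention; the shift takes the energy smoothly to 0 there |
| dielectric | 10 | – | screening constant of the same convention |
| Coulomb constant | 332.0636 | kcal·Å/(mol·e²) | unit conversion for charges in elementary-charge units |
| polar-H threshold | 1.3 | Å | geometric covalent-bond cutoff; CONECT records are too unreliable to infer bonding from |
| pose average `top_n` | 10 | poses | averaging window; 10 empirically beats 1 on heterogeneous ensembles |
| success cutoff | 2.5 | Å | ligand-RMSD threshold for a "good" pose |

The shifting function defaults to the standard potential shift
$S(r) = (1 - (r/r_c)^2)^2$. The refinement engine the training data came
from documents *that* a shift is applied but not its closed form, so the
form is pluggable (`elec_params(shift = ...)`); any smooth function
vanishing at the cutoff preserves the continuity contract.

## Contact-class edge cases

Two readings of the X class are defensible: strictly X–X pairs, or every
pair that is not CC/NN/OO. `feature_vector()` implements both
(`xx_mode = "strict"` vs `"fold_hetero"`), with strict as the default; the
heterogeneous counts (CN, CO, …) are always carried in the
`contact_profile` either way. The distance boundary is inclusive
(`d <= cutoff`); the toy-data generator keeps all distances at least
$10^{-3}$ Å away from the standard cutoffs so this convention can never
flip a test outcome. Non-polar hydrogens are excluded from counting
entirely, consistent with united-atom practice; unknown elements are
flagged, classed `NONE`, and excluded rather than silently guessed.

## Retraining

`fit_affinity()` is ordinary least squares (`stats::lm`); `aic_stepwise()`
is greedy AIC selection (`stats::step`) under the Gaussian convention
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2(p+1)$, which is exactly the scale
`extractAIC` uses for linear models — constant offsets cancel in every
comparison, so the selection path is identical to common stepwise practice.
Direction defaults to `"both"` starting from the full model. The Ki
conversion uses $T = 298.15$ K and $R = 0.0019872$ kcal/(mol·K) by default
(both arguments). `cross_validate()` assigns folds uniformly at random from
an explicit seed — no stratification, matching the plain k-fold protocol —
and pools held-out predictions within a repeat before computing Pearson r,
Kendall tau-b and RMSE. There is no hidden RNG state anywhere: every
stochastic entry point takes a seed, and the generators restore the
caller's `.Random.seed`.

One caveat documented rather than solved: AIC is a liberal selector. With
~10 candidate features an irrelevant feature enters with probability
roughly 0.16, so on pure-noise targets the selected set is rarely *empty* —
it is merely small and explains almost nothing. The null-behaviour tests
therefore check held-out correlation and selected-model R² rather than
demanding the intercept-only model.

## The ligand-based companion

The ligand-side predictor assumes similar ligands of one target bind with
similar affinity. Molecules are read from SD/MOL V2000 records into
heavy-atom graphs; `atom_pair_fingerprint()` implements the Carhart atom
pair descriptor — for every heavy-atom pair, `(type_i, type_j, d)` with
type = (element, heavy-neighbour count, π-electron count) and d the
shortest-path bond distance — and fingerprints are compared with the
multiset Tanimoto ratio Σmin/Σmax. The typing scheme is the published
Carhart definition; numerical parity with any particular cheminformatics
package's atom-pair variant (distance caps, type encodings differ between
implementations) is not claimed. SMILES input is out of scope — SD files
avoid embedding a SMILES parser and the same data is available in both
forms in practice.

`fit_ap_svr()` trains ε-SVR on the precomputed Tanimoto kernel
(solver: kernlab). The min/max kernel is positive semi-definite in exact
arithmetic; a 1e-8 diagonal jitter guards against round-off. Targets are
`ln(IC50)` by convention; constant unit offsets shift the bias term only
and leave rankings unchanged. `most_similar_reference()` reuses the same
fingerprints to pick, for a query ligand, the reference ligand (and hence
receptor conformation) most similar to it; ties resolve to the first
reference in input order.

## Evaluation metrics

* `kendall_tau()` is tau-b (tie-corrected). Experimental IC50 lists contain
  ties in practice, so the tie-corrected variant is the right default; it
  is cross-checked in the tests against an O(n²) pair-counting oracle.
* `ppv_curve()` treats a compound as a true positive at depth N when it is
  in the top N of both rankings: PPV(N) = |topN(pred) ∩ topN(exp)|/N, with
  the random baseline RP(N) = N/n and enrichment EF(N) = PPV(N)/RP(N).
  PPV is not monotone in N and the package does not pretend it is; the
  invariants tested are EF(N) ≤ n/N and PPV(n) = 1.
* `ligand_rmsd()` superposes model onto reference by least squares (Kabsch)
  over backbone atoms (N, CA, C, O) paired by chain/residue/name, then
  measures RMSD over ligand heavy atoms paired by name (file-order fallback
  with a warning). No graph-symmetry correction is applied — a documented
  limitation: symmetric ligands can score up to their symmetry-equivalent
  RMSD too high.
* `success_rate()` uses strict `<` against the 2.5 Å cutoff by default
  (configurable), counting a target as solved when any of its first top-N
  poses beats the cutoff.

## What the generators emulate — and what they do not

`make_toy_complex()` places receptor atoms on a spherical shell and ligand
atoms in the enclosed pocket, with elements drawn from a composition typical
of binding sites and uniform partial charges. That exercises every geometric
code path (cutoffs, classes, polarity, charges) but is *not* protein-like:
no covalent structure, no realistic charge distribution, no correlation
between element and position. `make_training_table()` draws features
independently at magnitudes typical of drug-sized ligands at the 10.5 Å
cutoff (hundreds of CC contacts, tens of heteroatom contacts,
negative-skewed electrostatics) with Gaussian noise of sd 1.5 kcal/mol — a
realistic residual scale for affinity prediction — but real contact counts
are mutually correlated, which would inflate coefficient variance relative
to these tests. `make_molecule_set()` produces random heavy-atom *trees*;
rings and aromatic systems appear only in hand-built test fixtures. Passing
tests therefore demonstrate algorithmic correctness against brute-force
oracles, not predictive performance on real complexes, which depends on
data the package does not ship.

Problem sizes used by the test-suite simulations — 100 seeded toy complexes
for the contact oracle, 100 training tables of n = 200 for coefficient
recovery, 1000 permutations of n = 102 for the PPV null, 20 molecule sets
for the fingerprint oracle — were chosen so each check has clear
statistical resolution while the whole suite stays quick to run.

## Known limitations

* Scores transfer across preparation protocols only approximately (no
  internal refinement; charge-scheme sensitivity).
* Ligand identification defaults to "all non-water HETATM", which mistakes
  cofactors for ligand atoms in files that carry both — pass an explicit
  residue-name selector there. Ions are retained in the receptor set;
  waters are always dropped.
* Element inference from atom names alone is heuristic for exotic HETATM
  names; unresolvable names are flagged, never guessed.
* l-RMSD is not symmetry-corrected.
* The atom-pair fingerprint has no distance cap; for very large molecules
  the descriptor set grows quadratically.
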