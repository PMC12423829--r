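---
title: "Models and methods behind kmosar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kmosar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kmosar is an end-to-end structure–activity modeling pipeline for small-molecule
enzyme inhibitors, built around human kynurenine 3-monooxygenase (hKMO)
inhibitor series. This vignette is the package's own account of the models it
implements, the parameters that matter, the synthetic data it validates
against, and the design choices that were genuinely open.

## Activity data and curation

Input is a ChEMBL-style table (`molecule_id`, `smiles`, `ic50_nM`). Potency is
expressed as pIC50 = −log10(IC50 in molar); a compound is an "active" when
pIC50 ≥ 7.6 (about 25 nM), the cutoff used throughout.

`curate()` removes rows with missing IC50, ranged qualifiers (">", "<", or an
interval — these encode censoring, not a measurement), and SMILES that the
toolkit cannot parse. Structure identity is the OpenBabel canonical SMILES.
When the same structure appears with several IC50 values the package keeps one
record with the geometric mean of the measurements if they agree within one
log unit, and drops the structure entirely when they disagree by more — a
declared choice: merging discordant censored assays manufactures precision
that is not there. Every removal is logged with its reason.

## Physicochemical profile

Eight descriptors summarize each compound: Crippen-type LogP, molecular
weight, ring count (SSSR), aromatic ring count, H-bond acceptors and donors,
rotatable bonds and TPSA. LogP/MW/TPSA/HBA/HBD come from the OpenBabel
property engine (version recorded in the output); rotatable bonds are counted
from the connection table as acyclic single bonds between non-terminal heavy
atoms — a deliberately simple convention, stated here because rotor counts
differ across toolkits. Pearson correlations against pIC50 (constant columns
excluded, since their correlation is undefined) provide the usual
collinearity picture.

## Classifier

The activity classifier is a bagged ensemble of CART trees with per-tree
feature subsampling, exposing the four standard tree-ensemble
hyperparameters: number of trees (10–100), maximum depth (2–32; depths above
30 are clamped to the tree library's limit, indistinguishable at these sample
sizes), minimum samples to split (2–16) and minimum samples per leaf (1–16).
A seeded random search over that box is scored by stratified 5-fold CV
accuracy and the winner refit on all training data. The ensemble was authored
in-package rather than delegated because no installed forest implementation
exposes all four hyperparameters *and* the per-node training counts that the
exact Shapley explainer needs.

Before training, features pass two gates: pretreatment (non-numeric, missing
and quasi-constant columns dropped; quasi-constant means the modal value
covers > 99% of rows — the category is standard, the threshold is ours) and a
two-stage selection: equal-frequency-binned mutual information (keep features
above the median of the positive MI scores), then normalized Gini importance
from a random forest, cutoff 0.120. The MI estimator is a plug-in binned
estimate in bits — adequate for ranking, not for unbiased MI estimation.

The train/test split (28 test compounds by default) is random but redrawn
until every k-means cluster (k = 5, seed 42) of the 2-component PCA embedding
of the fingerprint Tanimoto similarity matrix contains at least one training
compound, so no chemical-space region is represented only in the test set.
PCA runs on the similarity matrix rather than raw fingerprint bits — with
1024 sparse bits, similarity space is the better-conditioned object. The
embedding uses ChemmineR atom-pair fingerprints (the circular fingerprints
common in this role are not available in the installed stack; the fingerprint
type is a parameter).

Interpretation: `partial_dependence()` clamps a feature to each of 50 grid
values spanning its observed range and averages predictions over the training
rows; `explain()` computes **exact** Shapley attributions of the predicted
class-1 probability by full coalition enumeration (2^p subsets, capped at 16
features) with the path-dependent value function — features outside the
coalition are marginalized using each tree's training cover. Additivity
(base value + contributions = prediction) is exact by construction and
asserted to 1e-6 across a 100-molecule run in the tests. The class
probability cutoff is 0.5.

## Applicability domain

Leverage h = xᵀ(XᵀX)⁻¹x over the selected descriptor panel, threshold
h\* = 3p/n. With no intercept augmentation, p = 8 descriptors and n = 109
training compounds give the familiar h\* = 0.220; the intercept-augmented
convention (3·9/109 = 0.248) does not, which is why the package pins the
un-augmented form. Columns enter unscaled by default (an autoscale toggle is
provided); training leverages sum to p, which the tests assert as an exact
linear-algebra identity.

## Chemical space network

Nodes are compounds; an edge joins two compounds when the Tanimoto
coefficient of their 1024-bit OpenBabel FP2 path fingerprints is ≥ 0.68.
Connected components are numbered by decreasing size; greedy modularity
communities are computed on the thresholded graph; edges carry display tiers
(thick Tc ≥ 0.9, medium 0.7 < Tc < 0.9, thin Tc ≤ 0.7 — an edge at exactly
0.7 is "thin", a reading we fixed because the tier bands overlap the edge
threshold between 0.68 and 0.7). Spring layouts are exported with a fixed
seed.

## Conformer ensembles

The field engine consumes aligned conformer ensembles with per-atom Gasteiger
charges and Lennard-Jones parameters (a compact element table at generic
force-field magnitudes). `embed_and_sample()` is a declared stand-in for a
molecular-dynamics conformational ensemble profile: the seeded RDKit
distance-geometry embedder (ETKDG, MMFF-cleaned, driven through the installed
`python`) provides the base geometry — the only embedder in the stack that
accepts an explicit random seed, which the reproducibility contract of the
ensemble requires — and additional conformers
are drawn by setting every rotatable bond to a random staggered basin
(−60°/180°/+60° plus 10° jitter) under a fixed seed. This reproduces the
*dispersion* of an ensemble, not its Boltzmann weights: conformers are not
re-minimized or energy-weighted, so tests passing on these ensembles show the
descriptor machinery is correct, not that MD-grade ensembles would give the
same QSAR. Alignment to a reference (in a real series, the most active
compound) is least-squares rigid superposition via the Kabsch SVD, with the
proper-rotation determinant correction; `bio3d::fit.xyz` serves as the
independent cross-check in the tests.

## Field descriptors

A rectangular grid (default 1.0 Å spacing, 4.0 Å margin — common field-QSAR
practice) covers all aligned ensembles. At each point a probe — by default an
sp³-carbon-like site with +1 e charge, ε = 0.1094 kcal/mol, σ = 3.4 Å —
accumulates two energies over atoms: Lennard-Jones
4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶] with Lorentz–Berthelot combination, and Coulomb
k·q_i·q_probe/r with k = 332.0636 kcal·Å·mol⁻¹·e⁻². Both are clamped to
±30 kcal/mol (configurable) to tame the r⁻¹² singularity at atom positions.
3D mode evaluates one designated conformer; 4D mode takes the arithmetic mean
over the ensemble, which the tests pin as exactly the mean of per-conformer
3D matrices. Column pruning removes grid points with variance below 1e-4 and,
within groups correlated above |r| = 0.99, keeps the column most correlated
with the response (recording the surviving twin of every pruned column so
planted locations remain traceable). Coefficient fields export as Gaussian
cube files.

## PLS and validation statistics

Regression is single-response NIPALS PLS. X and y are centered; autoscaling
is off by default because field columns share physical units. Statistics
follow the classical chemometrics suite: R², RMSEC = √(SSE/n),
SEC = √(SSE/(n−a−1)) and F = [(SSY−SSE)/a]/[SSE/(n−a−1)] with a the number of
latent variables counted as model degrees of freedom (a pinned convention —
reported SEC/F values in the literature rarely state theirs); leave-one-out
PRESS, Q² = 1 − PRESS/SSY and RMSECV (leave-N-out available as an option);
external R²pred against the training-set mean. The number of latent variables
is chosen as the LOO-Q² maximizer up to 10. Validation safeguards:
y-randomization (50 permutations by default) and correlation-ranked forward
variable selection scored by LOO Q². At maximal latent variables PLS
reproduces the least-squares solution, which the tests assert against `lm()`
to 1e-8; the LOO loop is asserted equal to an explicit n-refit enumeration.

## Synthetic data: what it emulates and what it does not

`generate_activity_table()` draws ~137 compounds from five structurally
distinct scaffold families (benzamide, aryl sulfonamide, urea-ether, furoate
ester, thiazolyl-piperazine urea; all asymmetric so R1/R2 swaps cannot
collide) decorated at two positions from a halogen/methyl/methoxy/CF3/
carboxyl vocabulary. pIC50 is family baseline + planted per-substituent
increments + N(0, 0.3) noise, clamped to [3, 11]; baselines (6.6–7.3) and
increments (−0.6 to +1.1, para halogens largest) were chosen once to span
pIC50 ≈ 5.8–9.5 with roughly balanced classes at the 7.6 cutoff, mirroring the
halogen-driven SAR of hydrophobic enzyme pockets. 5% duplicate rows, 5%
missing-IC50 rows and 2% ranged rows are injected so curation is exercised
without being dominated. The scaffold cores were picked so that cross-family
FP2 Tanimoto stays below the 0.68 network threshold while families stay
internally connected — the property the network analysis assumes of a
"structurally coherent family". With noise 0, regression on the planted
indicator matrix recovers the increments to 1e-9 (a generator self-check).

For field-QSAR validation, `synthetic_congeneric_ensembles()` builds a
24-member congeneric series on a rigid planar ring with pseudo-substituents
of varying size/depth/charge at the para and meta positions, conformers being
seeded 0.1 Å jitters in a common frame; `plant_field_response()` then makes
pIC50 a linear function (plus N(0, 0.3)) of three well-separated computed
field columns. Because the truth is planted *in descriptor space*, recovery
tests (Q² ≥ 0.8, every planted coefficient sign recovered at its grid
location or its > 0.99-correlated surviving twin) validate the
pruning-fitting machinery, not any claim about real binding physics. None of
the synthetic chemistry attempts to mimic real hKMO pharmacophores; families
are structural, not biological.

## Problem sizes and numerical choices

The shipped analyses and tests run at deliberate desk scale: 137 compounds
for the tabular pipeline, 24-member series × 5 conformers on a ~2 000-point
grid for the field stage, 20–50 permutations/seeds for the property checks.
Tie-breaks and degenerate inputs are pinned: zero-variance vectors give NA
correlations (never 0), two empty fingerprints have Tanimoto 0 with a
warning, grid points within 1e-6 Å of an atom take the clamped energy, a
constant response yields zero PLS coefficients with the mean as intercept,
and NIPALS stops early when the residual response is exhausted.

## Known limitations

Published per-dataset statistics of the original hKMO study (its exact
descriptor values, Table-1 metrics, or Table-S7 PLS numbers) are reproducible
only with its dataset, DFT geometries, MD ensembles and undocumented
grid/probe settings; this package validates the *machinery* against planted
ground truth and closed-form oracles instead. Gasteiger charges and a
single-site probe are coarse relative to QM-derived charges; the conformer
generator ignores energy weighting; LogP and rotor conventions are
toolkit-specific. All of these are parameters or documented stand-ins rather
than hidden assumptions.
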