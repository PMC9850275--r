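---
title: "An orientational backbone potential for stability-change prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An orientational backbone potential for stability-change prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orientddg)
```

## The model

`orientddg` scores residue–residue interactions with a coarse-grained,
side-chain-independent statistical potential. Each residue contributes
only its three backbone atoms N, C$\alpha$ and C, from which an
orthonormal local frame is built (`build_frame()`): the first axis points
from C$\alpha$ to C, the third is the unit cross product of that axis
with the C$\alpha\to$N direction, and the second completes a
right-handed basis. The relative placement of two residues $i,j$ is then
a six-dimensional descriptor (`pair_descriptor()`):

* $r_{ij}$ — the C$\alpha$–C$\alpha$ distance,
* $(\theta_i,\phi_i)$ and $(\theta_j,\phi_j)$ — polar and azimuthal
  angles of the inter-residue direction in each residue's frame (side
  $j$ uses the reversed direction),
* $\omega_{ij}$ — the signed torsion of the two third axes about the
  inter-residue axis.

The descriptor is invariant under global rigid motions and swaps sides
under $i \leftrightarrow j$ exchange, with $r$ and $\omega$ preserved —
both properties are enforced by randomized tests at $10^{-9}$ tolerance.

The energy of a configuration is obtained by Boltzmann inversion
(`derive_potential()`):

$$E_{ab}(\mathbf{x}) = -RT\,
  \ln\frac{P^{\mathrm{obs}}_{ab}(\mathbf{x})}{P^{\mathrm{ref}}(\mathbf{x})},$$

where $P^{\mathrm{obs}}_{ab}$ is the binned frequency of amino-acid pair
$(a,b)$ over a structure set and $P^{\mathrm{ref}}$ pools all pair types,
cancelling residue-blind geometric preferences. Uniform counts therefore
invert to exactly zero energy, and a bin observed at twice the reference
frequency scores $-RT\ln 2 \approx -0.411$ kcal/mol at $RT = 0.593$
kcal/mol — both identities are asserted in the test suite.

### Stability changes upon mutation

A point mutation at site $m$ is scored on the *native* backbone — an
identity swap with no remodelling (`predict_ddg()`):

$$\Delta\Delta G \;=\; \sum_{i \in \mathcal{C}(m)}
  w_{a_i} w_{\mathrm{mut}}\, E_{a_i,\mathrm{mut}}(\mathbf{x}_i)
  \;-\; \sum_{i \in \mathcal{C}(m)}
  w_{a_i} w_{\mathrm{wt}}\, E_{a_i,\mathrm{wt}}(\mathbf{x}_i),$$

where $\mathcal{C}(m)$ is the set of residues in contact with the site
(within the distance window, at or beyond the minimum sequence
separation) and $w$ are non-negative amino-acid weights. $\Delta G$ is
the unfolding free energy, so **positive $\Delta\Delta G$ means
stabilizing**. Because both sums run over the same contacts and
descriptors, scoring the reverse substitution on the same structure
gives the exact negation: the predictor is anti-symmetric *by
construction* to machine precision, and deviations between direct and
reverse predictions on a wild-type/mutant structure pair measure only
genuine backbone differences. This is the property that
`predict_reverse()` and the `antisymmetry()` diagnostics
($r^{\mathrm{Sym}}$, $\delta$) expose.

### The 12-group weighting scheme

Rather than one weight per amino acid (available via `n_groups = 20`),
chemically similar residues share a weight: negative (D, E), small
hydrophobic (V, I, L), large hydrophobic (F, Y), polar uncharged (S, T,
N, Q), positive (K, H), and singleton weights for G, A, C, M, P, W and
R — 12 parameters in all. Fewer parameters limit overfitting on the few
thousand experimental measurements available. Weights are constrained to
$[0, 5]$: non-negativity removes the global sign degeneracy of the
product form ($(-w)(-w') = ww'$), and the upper bound is a generous
superset of the fitted range observed in practice ($\sim$0.7–2.5).

## Binning

The bin geometry travels with every potential file; maps and predictors
can never mix conventions. Defaults (`bin_geometry()`):

| parameter | default | meaning |
|---|---|---|
| $r$ window | $[3, 16)$ Å, 13 bins | contact definition, 1 Å resolution |
| $\theta$ | 6 bins, uniform in $\theta$ | polar angle per side |
| $\phi$ | 8 bins | azimuth per side |
| $\omega$ | 8 bins | torsion |
| min. seq. separation | 2 | excludes bonded neighbours |

All bins are half-open $[lo, hi)$ with the final bin closed, so every
in-window descriptor maps to exactly one bin. At the polar singularity
($|\cos\theta| = 1$) the azimuth is undefined; it is set to 0 by
convention so binning stays deterministic. Sequence separation uses
author residue numbering, so chain gaps from unresolved residues keep
their true separations.

Two further conventions make the energy exchange-symmetric, as the
pooled counting demands: amino-acid order is canonicalized
alphabetically (counting and lookup agree), and for same-type pairs the
two side-angle bin tuples are ordered lexicographically. Descriptors are
always computed with the lower-sequence-position residue as side $i$
before this canonicalization.

The desk-scale test and acceptance runs use a reduced angular geometry
($3 \times 4$ per side, 4 torsion bins) so energy tensors stay small;
this is a problem-size choice of the package's own test design — the
derivation code is geometry-agnostic and the full default geometry is
exercised identically, just over more bins.

A pseudo-count $\lambda = 1$ per bin (configurable) keeps energies
finite where statistics are sparse; at desk scale most bins are empty
and would otherwise produce infinite energies. Any overall energy-scale
error from $RT$ or $\lambda$ is absorbed by the fitted weights, which is
why $RT$ is simply fixed at 0.593 kcal/mol (298 K).

## Dataset curation

`curate()` composes the filters in a fixed order, with exact
bookkeeping (input = removals + survivors at every stage):

1. **Condition window** — keeps 10 °C ≤ T ≤ 40 °C and 5 ≤ pH ≤ 9, both
   inclusive; records missing either value are dropped by default.
2. **Replicate merging** — per mutation, groups whose mean absolute
   pairwise $\Delta\Delta G$ difference exceeds 1 kcal/mol are excluded
   entirely; otherwise the record closest to standard conditions (25 °C,
   pH 7) is kept. "Closest" uses the normalized L1 distance
   $|T-25|/15 + |\mathrm{pH}-7|/2$ — the window half-widths make the two
   axes commensurate, since no metric is canonical here.
3. **Range trimming** — keeps $-7 \le \Delta\Delta G \le 5$ kcal/mol
   (inclusive; only strictly outside values are outliers).
4. **Structure screen** — resolution ≤ 2.5 Å, monomeric annotation,
   backbone-complete mutation site. The oligomeric state is an upstream
   annotation (biological-assembly judgement is not recomputed).
5. **Ligand proximity** — a record is discarded when any heavy atom of
   the mutated residue lies strictly within 5 Å of a ligand heavy atom
   (waters excluded). With backbone-only parsing the residue's heavy
   atoms are N, C$\alpha$, C — a documented approximation, flagged in
   the stage metadata. The strict `<` comparison carries a $10^{-9}$ Å
   guard so exact boundary placements are classified deterministically.
6. **Blacklist** — exact (id, chain, position, wt, mut) exclusion, for
   keeping training data disjoint from benchmark sets.
7. **Balancing** — caps each ordered (wt, mut) class at 15 records,
   removing by priority: destabilizing mutations involving alanine
   first (alanine-scanning experiments over-represent them), then other
   destabilizing records, then seeded-random picks. "Involving alanine"
   means wild-type *or* mutant alanine. A candidate that is the last
   surviving record of its protein family is spared while any
   alternative remains in the class, so balancing never silently erases
   a family.

Homology clustering (`cluster_families()`) uses greedy centroid
clustering at 25% global identity (Needleman–Wunsch, BLOSUM62; identity
= matches / alignment length including gaps), processing sequences by
decreasing length. An externally computed clustering can be supplied
verbatim. Cross-validation folds partition *clusters*, never records
(`make_splits()`), so no fold shares a homolog between training and
validation.

## Weight fitting

`fit_weights()` minimises the mean absolute error between predicted and
experimental $\Delta\Delta G$. The MAE surface is piecewise smooth
(kinked wherever a residual crosses zero), so a derivative-free,
bound-constrained pattern search (Hooke–Jeeves, via pracma) is used; it
is monotone — the result is never worse than the start — and
deterministic, with the search's internal coordinate shuffling pinned to
a fixed local RNG state that leaves the caller's random stream
untouched. Termination is by step-size tolerance ($10^{-6}$) or an
evaluation budget. Because each record's prediction is bilinear in the
weights, the fit precomputes per-record group-summed energy matrices
once; each objective evaluation is then two $n \times 12$
matrix–vector products, and a 500-record fit takes well under a second.

Identifiability is verified by parameter recovery: on noise-free
synthetic datasets (500 mutations over 5 structures) the fitted weights
match the generating truth within 5% relative error and the training
MAE falls below $10^{-3}$ kcal/mol; under $\sigma = 0.5$ kcal/mol
Gaussian noise the training MAE lands at the theoretical
$\mathbb{E}|N(0,\sigma^2)| = \sigma\sqrt{2/\pi} \approx 0.399$ within
sampling error. Scaling the true weights by $c$ scales predictions by
$c^2$, and fits on rescaled data recover rescaled weights — the scale is
pinned by the data, not by a normalisation convention.

`cross_validate()` repeats cluster-disjoint $k$-fold fitting; the
protocol default is 100 repetitions to stabilise the mean performance
estimate, while tests and the acceptance script use 2 repetitions (the
estimator is unchanged, only its variance differs). Per-fold weights are
retained so weight-stability statistics (standard deviation across
folds and repeats) can be reported.

## Evaluation

`eval_report()` collects: RMSE, MAE, Pearson correlation; sensitivity,
specificity, PPV, NPV, accuracy and Matthews correlation (binary
threshold at 0 kcal/mol by default — stabilizing vs not — and exposed
as a parameter, since the ±1 convention is also defensible); ROC and
precision–recall curves swept over all distinct score cuts with ties
grouped, with trapezoidal AUCs (the ROC AUC equals the concordance
probability with half credit for ties — asserted against a brute-force
pairwise count); the three-state classification (destabilizing
$\le -1$, stabilizing $\ge +1$, neutral between, boundaries assigned to
the non-neutral classes) reported as same-class / off-by-one /
off-by-two percentages that sum to 100 exactly; and the anti-symmetry
diagnostics $r^{\mathrm{Sym}}$ (absolute correlation of direct and
reverse predictions) and $\delta$ (mean of their sums). The PRC
baseline (prevalence) is reported alongside its AUC because
precision–recall is the more informative view on unbalanced data.
`cap_predictions()` floors runaway destabilizing values at $-8$
kcal/mol; it is off in every internal pipeline and exists for comparing
external predictors.

MCC is defined as 0 when a confusion-matrix marginal vanishes; Pearson
correlations on zero-variance vectors are reported as `NA` rather than
invented.

## Synthetic fixtures: what they do and do not show

`make_helix()` builds ideal backbones by internal-coordinate chain
extension (bond lengths N–C$\alpha$ 1.458 Å, C$\alpha$–C 1.525 Å, C–N
1.329 Å; $\varphi = -57^\circ$, $\psi = -47^\circ$ for the helix
template), with optional Gaussian coordinate jitter (0.25 Å in the
standard fixture set — enough to decorrelate descriptor bins between
fixture structures while keeping the geometry protein-like).
`make_synthetic_potential()` either derives a map from such helices
through the real counting path or fills the tensor with seeded Gaussian
energies of controlled magnitude (0.6 kcal/mol in the standard fixture
set, giving per-contact energies of realistic size).
`make_synthetic_ddg()` samples mutations uniformly over scoreable sites
and sets each "experimental" value to the model's own prediction under
a known weight set plus Gaussian noise; sites with empty contact sets
are skipped because they carry no signal by construction.

These fixtures make every stage runnable and falsifiable without
downloads, and they are generated *from the model*: passing the
recovery suite demonstrates that the fitting machinery inverts the
model faithfully, not that the model describes real proteins. Real
mutation data are heterogeneous across laboratories, methods and
conditions; real structures have side chains, ligands, oligomeric
interfaces and non-ideal geometry. None of that heterogeneity is
emulated, which is precisely why the curation module exists for real
inputs.

## Known limitations

* Backbone-only scoring: no side-chain repacking, minimisation,
  protonation modelling or disulfide detection; mutations whose effect
  is dominated by side-chain rearrangement are out of reach.
* The frame construction and torsion convention are fixed, documented
  choices stamped into every potential file; numerical equivalence with
  other implementations' maps is not claimed.
* Greedy identity clustering is a deliberate, dependency-free stand-in
  for dedicated clustering tools at desk scale; for thousands of
  sequences an external clustering should be supplied via
  `precomputed`.
* The pattern search finds a local MAE minimum; with the non-negativity
  bound and the bilinear structure this is well-behaved in practice
  (recovery tests pass from the all-ones start), but no global
  optimality is guaranteed.
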