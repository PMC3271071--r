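---
title: "Predicting backbone torsion angles with a two-level SVR cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting backbone torsion angles with a two-level SVR cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phipsi)
```

## The problem

A protein backbone is essentially determined by two dihedral angles per
residue: phi (about the N–Cα bond, atoms C(i−1)–N–Cα–C) and psi (about
the Cα–C bond, atoms N–Cα–C–N(i+1)); the peptide-bond angle omega sits
at ~180° and is not predicted.  Real-valued phi/psi predictions from
sequence are useful restraints for fold recognition and structure
refinement.  `phipsi` implements a regression pipeline for this task:
per-residue sequence profiles are encoded with a sliding window and fed
to an ε-support-vector-regression (ε-SVR) cascade, one independent model
pair per angle.

## The model

**Targets.**  Observed angles are computed from coordinates
(`compute_backbone_torsions()`) with the right-handed atan2
cross-product convention (cis = 0°, trans = 180°), and then mapped to a
unit scale for regression.  The mapping stores the training-set mean μ
and standard deviation σ per angle type and uses

v = 0.5 + (θ − μ) / (c · σ),

with span `c = 6` by default, so that angles within ±3σ of the mean land
in [0, 1].  Published descriptions of this normalization state only that
the mean and SD are used to bring "most" values into [0, 1]; the affine
form above is this package's concrete choice because it is invertible,
linear, and meets that intent exactly.  Predictions are denormalized and
*wrapped* into (−180°, 180°] rather than clamped, keeping values on the
legal circle.

**Features.**  Four per-residue tracks are supported, in the dialects of
the standard upstream tools: a PSI-BLAST ASCII PSSM (20 log-odds columns
divided by exactly 10, no clamping), PSIPRED ss2 three-state
probabilities (reordered internally to H, E, C), a two-state
exposed/buried accessibility track (one-hot, 2 columns) and a disorder
probability track (disordered/ordered, 2 columns).  A residue is encoded
by concatenating, position by position across a window of L = 2l + 1
residues, the track blocks of the chosen scheme in the fixed order
PSSM, SS, SA, DISO; positions outside the chain contribute exact zeros.
Scheme widths per residue are therefore 20 (`PB`), 23 (`PB+PP`),
25 (`PB+PP+SC`, `PB+PP+DISO`) and 27 (`PB+PP+SC+DISO`), i.e. 27L
feature columns at the full combination — 243 for L = 9.  The `ALL`
scheme appends a global block once at the end: 20 composition fractions,
the length scaled by 1/1000 (capped at 1) and the approximate molecular
weight (sum of average residue masses) scaled by 10⁻⁵.  The width of
that block is configurable (default 22) because published feature
counts imply a larger, undecomposed global block (e.g. 277 − 243 = 34
columns at L = 9); rather than guess its composition the package
documents its own 22-column definition and reports its true dimension.
The within-window layout (position-major, track blocks per position) is
likewise a documented package choice: any consistent order is
learnable, determinism is what matters.

**Cascade.**  Level 1 is an ε-SVR (RBF kernel) from the windowed
features to the normalized angle.  Level 2 takes, for each residue, the
window of L₂ neighbouring level-1 predictions along the chain
(zero-padded at the ends; L₂ defaults to the level-1 window length) and
outputs the refined normalized angle.  This second pass exploits the
strong local continuity of backbone conformation: neighbouring residues
in a helix or strand share near-identical angles, so smoothing level-1
output through a learned contextual model removes isolated outliers.
Both levels use the same fixed operating point C = 5.0, ε = 0.01,
γ = 0.01, a combination established for this task by prior parameter
selection on training data; the package treats it as the default, not
as something to re-tune.  Level 2 contains only the level-1 prediction
window — raw features are not re-concatenated (configurable designs are
out of scope; the pure-window form follows the two-level
solvent-accessibility precedents this architecture derives from).

Level-2 training uses in-sample level-1 predictions by default — the
simplest reading of a two-level design.  Because in-sample level-1
output is optimistically accurate, an optional chain-level k-fold
out-of-fold mode (`oof_folds`) is provided for users who want the
second level trained on realistic level-1 error; the default stays
in-sample.

**Per-angle models.**  phi and psi get fully independent model pairs,
with per-angle encoding schemes: phi defaults to `PB+PP` and psi to
`PB+PP+SC`, both at L = 9, the best per-angle operating points of the
scheme comparison this design follows (adding the accessibility track
helps psi but not phi; the disorder track helps neither).

## Evaluation

`evaluate_predictions()` computes Pearson correlation (on raw angle
values, the literal definition — an optional Fisher–Lee circular
variant is clearly labelled non-standard for this pipeline), MAE and
RMSE on both the raw (degrees) and normalized scales, pooled over
residues and stratified by amino acid, secondary structure, solvent
accessibility, 20°-wide observed-angle bin, and chain.  The chain-level
summary includes the fractions of chains with CC ≥ 0.5 and ≥ 0.6, and
both the mean of per-chain RMSEs and the pooled-residue RMSE (published
chain-level summaries rarely say which; both are emitted, labelled).

**Angle differences.**  Angles are periodic, so the package defaults to
the circular difference min(|a − b| mod 360, 360 − |a − b| mod 360) for
MAE/RMSE.  A `linear` mode (plain |a − b|) is provided because
published MAE definitions are usually written in that literal form, and
large reported errors in bins near ±180° suggest some published numbers
were computed without wrap-awareness.  Every report carries its mode.

**Null model.**  The amino-acid-specific random predictor assigns each
test residue an angle drawn uniformly from the training pool of its own
amino-acid type and averages the MAE over many repeats (default
10,000).  `expected_random_mae()` gives the exact limit of that
procedure in closed form — the mean over test residues of the mean
absolute difference to every pool angle — and the test suite checks the
sampled baseline against this oracle at three standard errors.  A
paired two-sided Wilcoxon signed-rank test over per-chain MAEs
(`compare_paired_mae()`, exact null up to n = 25, normal approximation
beyond) supports method comparisons.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the predictor
exploits, so the whole pipeline can be exercised with no external
predictors: secondary-structure segments (mean lengths H = 9, E = 6,
C = 5, coil separating the regular elements), SS-biased amino-acid
composition, and per-SS angle mixtures — helix φ ~ N(−63°, 8°),
ψ ~ N(−42°, 10°); strand φ ~ N(−120°, 20°), ψ ~ N(135°, 20°); coil
drawn from broad two-component mixtures giving one φ mode and a bimodal
ψ.  Proline φ is tight around −75° regardless of SS and glycine gets a
sign-symmetric widened φ in coil, mirroring the well-known
residue-specific behaviour.  These parameters are design defaults
chosen to mimic the familiar Ramachandran clusters qualitatively; they
are not fitted to any particular structure set.  Profile noise has four
knobs: PSSM signal strength (0.8), SS-probability confusion (0.15),
accessibility error (0.1) and disorder noise SD (0.05).

Chains carry angles sampled per residue, not built from coordinates, so
the generator does **not** reproduce chain geometry, excluded-volume
effects, angle autocorrelation beyond the segment structure, or real
PSSM column correlations.  Passing tests on synthetic data therefore
demonstrate that the machinery learns SS- and residue-conditioned angle
structure from noisy profiles and beats its own exact null model — they
do not certify accuracy on real proteins, which depends on upstream
predictor quality and on the much broader real coil distribution.

## Numerical and degenerate-input choices

* Dihedrals: atan2 of cross products; collinear or coincident points
  raise a typed error, which chain-level torsion computation converts
  to an undefined angle plus a warning.
* Terminal rule: angles whose defining atoms do not exist (phi of the
  first residue, psi of the last) are undefined; an `extra_trim`
  parameter (default 0) additionally excludes that many residues per
  terminus, since curated angle sets sometimes drop several terminal
  residues ("four residues in the N- and C-terminus" may be read as
  per-terminus or in total; the package makes it explicit and
  configurable rather than guessing).
* Ties in the SS-probability argmax resolve to coil.
* Constant regression targets: every target lies inside one ε-tube, so
  the optimal ε-SVR is the constant function and the solver returns no
  support vectors; the package short-circuits this degenerate case to
  an explicit constant fit.
* Kernel-SVR training cost is quadratic-to-cubic in rows, so
  `cap_rows` (default 20,000) subsamples the level-1 design with the
  run seed; raise it to train on everything.
* All randomness (generator, subsampling, baseline repeats) is governed
  by explicit integer seeds; training and prediction are deterministic
  given seed and input order.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full pipeline on
synthetic data at 30 training and 10 held-out chains of 50–120 residues
(roughly 2,500 training residues per angle) — large enough for the
cascade to beat the exact random baseline decisively for both angles
and to reproduce the helix-easier-than-coil stratification, small
enough to run comfortably on a single CPU.  The sampled-baseline oracle
check uses 50,000 repeats on a small fixture pool; the baseline default
of 10,000 repeats matches standard practice for this null model.

## Limitations

* No omega prediction, no reconstruction of 3-D coordinates from
  predicted angles.
* The `ALL` global block is a package definition (22 columns), so
  feature counts for `ALL` differ from published counts built on an
  undecomposed 34-column block.
* CC is reported on raw angles (the literal definition) and can be
  pessimistic near the ±180° wrap; the circular MAE/RMSE modes are the
  wrap-aware alternatives.
* Real-data accuracy depends on the upstream profile tools; the package
  parses their formats but does not run them.
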