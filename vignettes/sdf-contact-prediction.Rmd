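---
title: "Structure-derived features for inter-helical contact prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-derived features for inter-helical contact prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmhc)
```

## The problem

Alpha-helical transmembrane (TM) proteins fold as bundles of
membrane-spanning helices, and the map of which residues touch across
helices largely determines the fold. Following the convention of curated TM
contact datasets, two residues form a **contact** when they sit on different
TM helices, are at least 5 positions apart in sequence, and their closest
heavy (non-hydrogen) atoms are strictly less than 5.5 Å apart. Only
inter-helical candidate pairs satisfying the separation rule are scored;
roughly 2% of them are contacts, so the task is a heavily imbalanced binary
classification over ranked pairs.

This package predicts that contact map from a 3D structure — experimentally
determined or computationally predicted — rather than from sequence
features. The working hypothesis is that a structure predictor's output,
even when imperfect, carries enough geometry to be "bootstrapped" into a
better contact map than the one read directly off the predicted coordinates.

## Features

For a candidate pair $(i, j)$ the classifier never sees the pair itself;
instead it receives the 8 surrounding positions of the $3\times3$
sequence-window $(i\pm1, j\pm1)$, centre excluded, so the label-defining
distance of $(i,j)$ is not an input. Each window position contributes five
**structure-derived features** (SDFs):

* $D_1$ — the mean Euclidean distance over all $M \times N$ cross pairs of
  the two residues' heavy atoms;
* $SD_{D_1}$ — the population standard deviation (divisor $MN$) of those
  distances;
* $D_\alpha$ — the C$\alpha$–C$\alpha$ distance;
* $\delta$ — the angle between the two residue-plane normals, each plane
  spanned by C$\alpha\!\to$N and C$\alpha\!\to$C;
* $\theta$ — the tilt angle between the two helix axes, each axis the
  renormalized mean of the O$(i)\to$N$(i{+}4)$ hydrogen-bond-partner
  vectors over the helix.

That yields a 40-dimensional vector ($8 \times 5$). All five quantities are
invariant under rigid motion of the chain — the property that lets a model
trained on deposited structures transfer to predicted structures, which
arrive in arbitrary coordinate frames with correlated errors.

The **coordinates-as-features** (CF) baseline replaces the five geometric
values by the raw $x,y,z$ of four atoms (N, C$\alpha$, O, C$\beta$) of both
residues — $8 \times 24 = 192$ values — deliberately *not* rigid-invariant.

Angles are reported in $[0, 180]^\circ$ without folding: parallel and
antiparallel helix packing are biologically distinct, so $\theta = 170^\circ$
must not collapse onto $10^\circ$ (folding is available via
`tilt_angle(..., fold = TRUE)`). Per-residue axis vectors are normalized
before averaging so each helical turn carries equal weight. Arc-cosine
arguments are clamped to $[-1, 1]$ to avoid NaN from rounding. Window
positions that fall off the chain (or lack the backbone atoms a quantity
needs) contribute a zero block plus a validity flag rather than dropping the
pair, keeping row counts equal to candidate counts; a neighbour outside
every annotated helix inherits the central residue's helix axis so the tilt
stays defined at helix boundaries. Glycine has no C$\beta$; in the CF
encoding its C$\beta$ slot repeats C$\alpha$ (an ideal tetrahedral virtual
C$\beta$ is available via `gly_cb = "virtual"`).

The within-block feature order, the row-major neighbour order and these
boundary rules are this package's conventions; any fixed order is learnable
by the network.

## Classifier

`contact_net()` trains a feed-forward network with 6 leaky-ReLU hidden
layers (default widths 512–256–128–64–32–16, negative slope 0.01), a
sigmoid output and binary cross-entropy loss, optimized by Adam at learning
rate $10^{-4}$ in mini-batches of 256 for 400 epochs by default, with
weights initialized Xavier-uniform and gradients clipped elementwise to
$[-1, 1]$. SDF inputs pass first through a *static* fully connected
40→192 projection — frozen at its Xavier initialization and excluded from
optimization — so one architecture serves both feature sets. "Static" is
read as non-trainable (it is the natural contrast with the trained layers);
`projection_trainable = TRUE` exposes the other reading. Class imbalance is
left untouched: no re-weighting or resampling.

Features are scaled to $[-1,1]$ by per-column min–max parameters **fitted on
training data only** and stored in the model; validation/test values may
fall outside $[-1,1]$, and constant columns map to $-1$. Fitting the scaler
on the training fold avoids leaking test statistics into training.

Everything is deterministic given `config$seed`: initialization, the
per-epoch mini-batch shuffles, and therefore the final weights, bit for bit.

## Evaluation protocol

Metrics are computed per sequence and then averaged across sequences (the
pooled variant exists but is not the default):

* **Average precision**, $\sum_n (R_n - R_{n-1}) P_n$ over descending
  grouped score thresholds — the area under the precision–recall curve.
  When the "scores" are a 0/1 contact map read off a predicted structure
  there is a single threshold and AP reduces to $P \times R$.
* **AUC-ROC** by the trapezoidal rule over the grouped sweep.
* **Top-$k$ precision/recall** at $k = \max(1, \lfloor L f \rfloor)$ for
  $f \in \{1, \tfrac12, \tfrac15, \tfrac1{10}\}$, where $L$ is the combined
  TM helix length of the chain; ties are broken lexicographically by
  $(i, j)$ for determinism.

Sequences with no positive label (for AP) or single-class labels (for AUC)
are excluded from that metric's average with a warning; zero predicted
positives give binary precision 0 (pessimistic). `crossvalidate()` splits
**by sequence, never by pair**, k folds × r repeats with per-repeat seeds
(defaults 5 × 5, seeds 0..4, always reported), fitting the scaler and the
model on the training chains of each fold only. Passing noisy twins as
`test_chains` evaluates each validation chain's twin while labels stay with
the clean structure.

## The synthetic generator

`make_bundle()` builds ideal poly-alanine α-helices from internal
coordinates ($\phi = -57^\circ$, $\psi = -47^\circ$, standard bond lengths
and angles; ~1.5 Å rise and ~100° twist per residue, consecutive
C$\alpha$ 3.8 Å apart) and packs them with controllable inter-axis spacing
and angles, antiparallel by default. Only backbone + C$\beta$ heavy atoms
are generated; exact bond values are not critical because every test
compares against construction-time ground truth, not literature values.
Residue numbering leaves a gap between helices instead of modelling loop
atoms (loop realism is out of scope; the gap provides the sequence
separation the windows need, and helix termini exercise the boundary rule).
Each chain receives a random rigid pose, as any deposited structure would.

`perturb()` adds i.i.d. Gaussian noise per coordinate — the package's model
of predicted-structure error. In `synthetic_dataset()` the noisy twin is
additionally re-posed rigidly before the noise is added, because a predicted
structure arrives in its own frame; truth (labels, axes) always stays with
the clean chain. The preset (10 chains, 2–4 helices of 12–16 residues,
spacing 9.5 Å) gives on the order of 500 candidate pairs per chain at a
pooled contact ratio of roughly 2–3.5%, matching the natural regime.

What the generator does **not** emulate: side-chain packing (contacts here
are backbone/C$\beta$ contacts), membrane context, kinked or curved helices,
and — importantly — the *correlated, locally rigid* character of real
predicted-structure error. Passing tests therefore demonstrate the
machinery and the rigid-invariance argument, not performance on real TM
proteins.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use 10 synthetic chains
(~5–7k candidate pairs) and 100 training epochs — sizes chosen so the whole
study runs comfortably on a laptop CPU while still exhibiting the class
imbalance and per-sequence variability of the real task; the package
defaults keep the full 400-epoch recipe. Brute-force oracles (exhaustive
atom-pair loops, threshold sweeps, the Mann–Whitney formulation of AUC)
back every geometric and metric computation at $10^{-9}$ tolerance.

## A limitation worth knowing

Under the i.i.d. noise model the clean-trained SDF classifier outperforms
both baselines at moderate noise (at $\sigma = 0.5$ Å the acceptance script
reports mean AP ≈ 0.66 for SDF vs ≈ 0.55 for the binary-annotation baseline
and ≈ 0.33 for CF), but at $\sigma = 1.0$ Å per coordinate — a 1.7 Å RMS
atom displacement, larger than a backbone bond — the residue-plane and
axis-vector features degrade into noise and the binary baseline, which reads
the centre pair's own distance, pulls ahead (≈ 0.35 vs ≈ 0.29). Real
predicted-structure error preserves local bond geometry almost exactly, so
this crossover is a property of the uncorrelated noise stand-in, not of the
method on real predictions. The numbers above are recomputed, not stored:
see `scripts/acceptance.R`.

## Known limitations

* Helix axes are single straight lines (no kink handling); strongly bent
  helices will blur $\theta$.
* PDB insertion codes are rejected; sequence logic assumes plain integer
  author numbering, with `apply_offset()` for renumbering.
* The CF baseline needs N, C$\alpha$, O per residue; residues missing those
  backbone atoms contribute zero blocks.
* No GPU path; the network is intentionally small and CPU-trainable.
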