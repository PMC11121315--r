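# tmhc — inter-helical contact prediction from TM protein structures

`tmhc` predicts residue–residue contacts between the transmembrane (TM)
helices of α-helical membrane proteins from a 3D structure. Two residues are
a contact when they lie on different TM helices, are ≥ 5 positions apart in
sequence, and their closest heavy atoms are < 5.5 Å apart; only about 2% of
candidate pairs qualify, so predictions are evaluated as ranked lists per
sequence.

The core idea: instead of feeding a classifier the raw coordinates of a
candidate pair's neighbourhood, feed it **structure-derived features** (SDFs)
that are invariant under rigid motion of the chain. For each pair (i, j) the
eight positions of the 3×3 window (i±1, j±1) — centre excluded, so the
label-defining distance is never an input — each contribute five quantities:

- **D₁** — mean Euclidean distance over all M×N cross pairs of the two
  residues' heavy atoms,
- **SD<sub>D₁</sub>** — population standard deviation of those M×N distances,
- **Dα** — Cα–Cα distance,
- **δ** — angle between the two residue-plane normals (planes spanned by
  Cα→N and Cα→C),
- **θ** — tilt angle between the two helix axes (each axis the averaged
  O(i)→N(i+4) hydrogen-bond-partner direction),

giving a 40-dimensional vector per pair. A 192-dimensional
coordinates-as-features (CF) baseline (raw x,y,z of N, Cα, O, Cβ for both
residues across the window) and a binary-annotation baseline (the contact
map read directly off a — possibly predicted/noisy — structure, scored as
precision × recall) are included for comparison.

The classifier is a 6-hidden-layer leaky-ReLU network (binary cross-entropy,
Adam at 1e-4, batches of 256, 400 epochs, Xavier-uniform init, elementwise
gradient clipping to [−1, 1]); SDF inputs pass through a static (frozen)
40→192 linear projection so one architecture serves both feature sets.
Features are min–max scaled to [−1, 1] with parameters fitted on training
data only. Evaluation reports per-sequence average precision
(Σₙ (Rₙ−Rₙ₋₁) Pₙ), trapezoidal AUC-ROC and top-L/L2/L5/L10
precision/recall (L = combined TM helix length), with sequence-level
k-fold cross-validation.

A synthetic α-helical bundle generator (ideal helices from internal
coordinates, controllable inter-axis spacing/angles, Gaussian coordinate
noise standing in for predicted-structure error) provides fully controlled
data with construction-time ground truth.

## Worked example

```r
library(tmhc)

# one synthetic 3-helix bundle with known geometry and labels
b <- make_bundle(n_helices = 3, helix_length = 16, seed = 7, random_pose = TRUE)
b$chain
#> <chain_structure> chain A (synthetic): 48 residues [1..54], 240 heavy atoms
b$truth$labels
#> <contact_labels> chain A: 21/766 contacts (< 5.50 A), CR = 0.0274

# a small study set: train on clean chains, score noisy twins (sigma 0.5 A)
ds <- synthetic_dataset(6, seed = 7, noise_sigma = 0.5)
fs <- build_dataset(ds$chains, ds$annotations, "SDF")
fs
#> <pair_feature_set> SDF: 3556 pairs x 40 features, 6 chains, 119 contacts (CR = 0.0335)

m <- contact_net(fs, config = contact_net_config(epochs = 60, seed = 7))
m
#> <contact_net> SDF classifier: 40 -> 192 -> 512 -> 256 -> 128 -> 64 -> 32 -> 16 -> 1
#>   trained 60 epochs on 3556 pairs (base rate 0.0335); final BCE 0.01225

fsn <- build_dataset(ds$noisy_chains, ds$annotations, "SDF",
                     label_chains = ds$chains)   # features noisy, labels clean
eval_report(fsn, predict(m, fsn), ds$annotations)
#> <eval_report> 6 sequences
#>   AP     0.6795 +- 0.0487
#>   AUC    0.9738 +- 0.0117
#>   P_L    0.3879 +- 0.0878
#>   R_L    0.8358 +- 0.0843
#>   ...
```

Reading: on structures perturbed by 0.5 Å coordinate noise, the clean-trained
SDF model ranks contacts with mean per-sequence average precision 0.68 and
AUC 0.97; 39% of the top-L pairs are true contacts, covering 84% of all
contacts. `crossvalidate()` runs the 5-fold × 5-repeat protocol;
`plot(m)` shows the training-loss trace; `save_contact_net()` /
`load_contact_net()` archive a model as JSON.

A command-line front end wraps the same stages
(`simulate | annotate | featurize | train | predict | evaluate | crossval |
demo`):

```sh
TMHC=$(Rscript -e 'cat(system.file("exec", "tmhc", package = "tmhc"))')
Rscript $TMHC demo --out run --n-chains 6 --seed 1 --epochs 40
```

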