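---
title: "Predicting drug-drug interactions from structure-derived feature images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions from structure-derived feature images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Co-administered drugs can interact — enhancing, diminishing or dangerously
altering each other's effects — and screening candidate pairs experimentally
is slow and expensive. `ddimage` predicts the *probability that a drug pair
interacts* from chemical structure alone: the only input per drug is its
SMILES string, and the only input per pair is a binary interacted /
not-interacted label for the training examples.

The pipeline is:

1. **SMILES → molecular graph.** `parse_smiles()` builds an atom/bond graph
   with perceived rings, Hückel-style aromaticity (so Kekulé and aromatic
   spellings of the same molecule become the same graph) and implicit
   hydrogen counts. Strings that cannot be parsed are *dropped with a
   reason*, never silently accepted (`filter_invalid()`).
2. **Graph → features.** Two feature families:
   - a hashed circular (Morgan/ECFP-style) **fingerprint**: every atom
     environment up to radius 2 is iteratively hashed and folded into 2048
     bits (`morgan_fingerprint()`);
   - a panel of 3, 6 or 12 **molecular descriptors** (`descriptors()`), in a
     fixed prefix order: molecular weight, logP, exact mass | rotatable
     bonds, H-bond donors, H-bond acceptors | aromatic rings, sp³-carbon
     fraction, N count, O count, TPSA, radical electrons.
3. **Features → image.** `feature_to_image()` lays the feature vector
   row-major on the smallest square grid that covers it, on a white
   background, pixel = round(255·(1 − value)): an active fingerprint bit is
   a black point, a scaled descriptor a gray level. `resize_normalize()`
   nearest-neighbor-resizes to the network side and maps pixels to
   (p/255 − mean)/sd.
4. **Image pair → prediction.** One *shared* residual encoder (the standard
   18-layer layout: 7×7/2 stem, 3×3/2 max pool, four stages of two residual
   blocks at widths 64/128/256/512, global average pool) embeds each image
   into 512 dimensions. A residual block computes `ReLU(h(x) + F(x, W))`,
   where `F` is conv3×3–BN–ReLU–conv3×3–BN and `h` is the identity or a
   1×1-conv+BN projection when shape changes; if every branch weight is
   zero, `F(x) = 0` and the block degenerates to `ReLU(x)` — a property the
   test suite asserts *exactly*. The pair head concatenates the two
   embeddings (1024), applies FC 1024→1024, ReLU, dropout, FC 1024→2, and
   the two logits are softmaxed into interaction / no-interaction
   probabilities. Inference averages both input orders
   (`predict_proba()`), so the score is symmetric in the pair by
   construction.

Training minimises two-class cross-entropy with Adam (default) or SGD,
records per-epoch train/validation curves, and returns the
best-validation-loss weights. Because drug pairs share drugs, every
minibatch deduplicates its images: each unique drug is encoded once and its
embedding gradient is summed over the pairs that mention it. This is an
*exact* reformulation of the naive per-pair computation, not an
approximation, and is what makes CPU training practical.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| fingerprint `n_bits` | 2048 | folded fingerprint length |
| fingerprint `radius` | 2 | environment radius in bonds (ECFP4-equivalent) |
| descriptor set | D12 | 3/6/12-descriptor prefix panel |
| `target_side` | 224 (tests/benchmarks use 46 or 32) | network input side, px; the encoder needs ≥ 32 |
| normalization mean/sd | 0.5 / 0.5 | maps 8-bit pixels to [−1, 1] |
| `dropout_p` | 0.5 | head dropout probability |
| learning rate | 1e-3 | Adam step size |
| `batch_size` | 128 pairs | minibatch size before image deduplication |
| split ratios | 0.6/0.2/0.2 | train/validation/test partition |
| early-stop patience | 10 epochs | on validation loss |

The 2048/radius-2 fingerprint, the descriptor families, the 6:2:2 split, the
two-logit head over a 1024-dimensional concatenated pair embedding and the
choice of cross-entropy with SGD/Adam are the method's fixed design; the
remaining rows are tunable engineering defaults chosen once as
field-standard values.

## Descriptor definitions and their provenance

All descriptors are computed from the parsed structure only — no lookups.

* **Molecular weight / exact mass** use standard average and monoisotopic
  atomic masses, implicit hydrogens included.
* **logP** is a coarse atomic-contribution scheme in the Crippen tradition:
  each heavy atom contributes by element/aromaticity/hybridisation class and
  each hydrogen by its attachment (+0.123 on carbon, −0.30 on heteroatoms).
  It is deterministic and monotone in hydrophobic surface, which is all the
  feature pipeline needs; it is *not* a fitted reproduction of any published
  parameterisation, and no test asserts literature logP values.
* **TPSA** implements the Ertl fragment-contribution method for N and O
  environments (S and P contribute 0, as in the original method). For
  neutral molecules the values match the published scale exactly
  (acetaminophen 49.33 Å², phenyl nitrite 38.66 Å²); for the charged nitro
  group written `[N+](=O)[O-]` the N⁺/O⁻ contributions (11.68 + 23.06 +
  17.07 Å²) differ from toolkits that normalise nitro groups to the neutral
  form first — a documented convention, not an error.
* **H-bond donors** are N/O atoms bearing ≥ 1 H; **acceptors** are all N/O
  atoms (Lipinski-style count). **Rotatable bonds** are non-ring single
  bonds whose endpoints both have another heavy neighbor (amide bonds are
  counted; stricter definitions exclude them). **Radical electrons** is 0
  for every closed-shell structure the parser accepts; the column is kept so
  the 12-descriptor panel is complete.

Descriptors are min–max scaled **on the training drugs only** and clipped to
[0, 1] at test time — both because the grayscale codec needs bounded values
and so that no test-set statistics leak into the features.

## The synthetic benchmark: what it emulates and what it does not

Real DDI corpora (thousands of drugs, tens of thousands of links) are
external downloads; the package instead ships a generator
(`generate_synthetic()`) whose *defaults are the stated benchmark world*:
100 drugs built from a fragment grammar (aromatic/aliphatic scaffolds with
one or two substituent slots), 1000 labeled pairs, noise rate 0, one
negative per positive.

The default planted rule is **substructure-based**: a pair interacts iff
*both* drugs carry a nitro group. Crucially, drugs without the motif carry
the isomeric nitrite-ester decoy (O–N=O, same NO₂ formula, same hydrogen
count) in the same slot, so molecular weight, exact mass and the
atomic-contribution logP are *identical in distribution* between motif and
non-motif drugs. The three-descriptor panel is therefore blind to the rule
by construction, while specific fingerprint bits see it directly — the
fingerprint-vs-descriptor ablation contrast is a design guarantee, not a
tuned outcome. (An alternative `rule = "descriptor"` plants a
TPSA-threshold signal the descriptor panels *can* see.) The motif
probability is 0.5, so roughly a quarter of random pairs satisfy the rule
and positive pools are deep enough to sample from.

What a green benchmark does establish: the whole pipeline — parsing,
fingerprinting, imaging, the shared encoder, the pair head, the training
loop — can represent and learn a pair-AND over localized structural
evidence, and the feature ablation behaves causally. What it does not
establish: performance on real pharmacology, where interaction mechanisms
are heterogeneous, labels are noisy and incomplete, negative pairs are
unverified absences, and test drugs may be structurally novel. The
generator's pairs also reuse the same drug pool across partitions
(transductive splitting, as in the standard link-prediction setting), so a
small amount of drug-identity signal is available to any feature set — the
reason the descriptor-blind ablation arm sits slightly above chance rather
than exactly at 0.5.

## Numerical choices and degenerate inputs

* **Codec quantization.** 8-bit grayscale costs at most 1/255 per feature on
  decode; binary fingerprint bits are exactly representable (0 ↔ 255,
  1 ↔ 0) and round-trip bit-exactly. Values outside [0, 1] are a contract
  violation, signalled as a classed condition.
* **Nearest-neighbor resizing** keeps binary pixels binary (no invented
  gray levels); tests assert the gray-level set is preserved under
  upscaling.
* **Batch norm** uses biased batch variance with momentum-0.1 running
  statistics and eps 1e-5; evaluation always uses running statistics, so
  repeated evaluations are identical.
* **Thresholded metrics** call score ≥ 0.5 positive. AUC uses the
  Mann–Whitney rank form with ties counted ½; AUPR is the step integral of
  precision over recall at the distinct score thresholds. Ratios with a zero
  denominator (single-class test sets, no positive predictions) are
  reported as 0 with the metric named in an `undefined` flag — never NaN.
* **Splits** put `round(n·ratio)` rows in validation and test and the
  remainder in train, so 1000 pairs give exactly 600/200/200.
* **Ties in canonical ranking** (symmetric atoms) are broken by promoting
  the lowest-index atom of the smallest tied class and re-refining —
  deterministic, and invariant across spellings because refinement keys are
  graph-derived.
* **Determinism.** All randomness (init, shuffling, dropout, sampling) flows
  from R's RNG seeded per component via fixed offsets from one master seed;
  two runs with the same config are bitwise identical, which the test suite
  asserts on metrics TSV bytes.

## Design choices where the design was open

* **One shared encoder** for both pair images (rather than two towers):
  halves the parameters and makes order-averaged inference meaningful.
* **Head shape**: concatenate 2×512 → FC 1024→1024 → ReLU → dropout →
  FC 1024→2, so the pair representation both enters and leaves the hidden
  layer at 1024 dimensions; dropout sits after the activation.
* **Grayscale, single channel**: the feature image has no color semantics,
  so the encoder stem takes 1 channel instead of triplicating data to
  pretend RGB.
* **Grid geometry**: row-major square of side ⌈√L⌉ — the simplest
  deterministic bijection from feature index to pixel.
* **Initialisation**: He-style random. Loading pretrained backbone weights
  is supported conceptually by the checkpoint mechanism but nothing is ever
  downloaded; all tests run offline from random init.
* **Unordered pairs** are stored with `drug_a < drug_b`; a duplicate under
  swap with a conflicting label is a schema error, not a silent overwrite.
* **12-descriptor identity**: the panel is fixed to twelve well-defined,
  structure-computable quantities spanning the physicochemical,
  topological and pharmacokinetic families (average and monoisotopic mass
  are kept as distinct quantities; nothing requiring 3D conformers or
  quantum chemistry is included).

## Known limitations

* The SMILES dialect covers the organic subset, bracket atoms with
  charge/isotope/H-counts, rings (including `%nn`), branches and dot
  fragments; stereo descriptors are accepted and discarded, and exotic
  valences outside the standard lists are rejected rather than guessed.
* Aromaticity perception handles 5–7-membered Hückel systems including
  fused bicyclics; it is not a full electron-counting model for complex
  polycyclics.
* logP and TPSA are simplified (documented above); they are features for a
  learning system, not property predictions.
* Training at side 224 on thousands of pairs is possible but slow on one
  CPU; the benchmark world (side 46) is where CPU budgets were validated.
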