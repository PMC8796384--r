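---
title: "Residue-level prediction of plasma protein binding for cyclic peptides"
author: "MacrocyclePPB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level prediction of plasma protein binding for cyclic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The plasma protein binding rate (%PPB) — the percentage of a compound
reversibly bound to serum albumin, hemoglobin and the acid glycoproteins —
controls how much free drug is available for distribution and clearance.
For cyclic peptides, whole-molecule QSAR descriptors blur exactly the
information that matters: binding to the hydrophobic pocket of human serum
albumin is often driven by one residue (a fatty acyl chain, an aromatic
side chain), so two peptides with near-identical whole-molecule descriptors
can differ by tens of percentage points in %PPB. MacrocyclePPB models %PPB
at the residue level and treats the macrocycle as what it is — a ring, with
no privileged start position.

The pipeline has five stages, each usable on its own:

1. **Decomposition.** The macrocycle is located and every backbone amide
   bond and disulfide bond on it is cleaved simultaneously. Cut ends are
   capped so fragments keep the parent's local electronic character: the
   amide nitrogen is methylated (it was an amide, not an amine), the
   carbonyl carbon becomes an aldehyde, and disulfide sulfurs get a
   hydrogen. Side-chain amides are never cleaved. The n fragments
   ("substructures") retain their ring order.
2. **Descriptors.** 2D physicochemical descriptors are computed for whole
   peptides and substructures; both are z-scored with the *whole-peptide
   training* means and standard deviations, and substructure rows are
   weighted by their training appearance frequency.
3. **Objective and split.** Experimental %PPB is clamped to [50, 95]
   (peptides below 50% are not drug-like and the assay saturates above
   95%). The train/test split is Kennard–Stone on the standardized
   whole-peptide matrix: a deterministic, space-covering test set.
4. **Model.** Substructure descriptor vectors are arranged in ring order in
   the center of a D x 15 map (zero padding elsewhere) and regressed by a
   small 1D CNN. Circularity enters by two independent mechanisms:
   *CyclicConv*, a convolution whose receptive field wraps around the
   occupied span; and *augmentation*, which enumerates all
   n x (15 - n + 1) rotation/translation replicas of each map. Test-time
   predictions average all replicas and are clamped to [50, 95].
5. **Attribution.** Per-input saliency |d yhat / d x| (vanilla gradients,
   taken at the raw output before clamping), averaged over all replicas and
   mapped back to ring positions, ranks the residues by their influence on
   the prediction.

## Model and assumptions

The four variants share one spine — convolution stack, global max pooling
over the occupied span, fully connected stack (64, 16, 1), batch
normalization after every convolutional and hidden dense layer:

| variant                | convolution | augmentation |
|------------------------|-------------|--------------|
| `baseline`             | ordinary    | no           |
| `cyclicconv`           | circular    | no           |
| `augmented`            | ordinary    | yes          |
| `cyclicconv_augmented` | circular    | yes          |

Assumptions worth stating explicitly:

* **Additive residue contributions modulated locally.** A convolution of
  kernel 3 sees a residue and its two ring neighbours; max pooling then
  detects the strongest local motif. This matches the driving mechanism —
  one binding-competent residue — rather than averaging over the molecule.
* **The ring has no origin.** Our convolutions, batch-norm statistics and
  pooling are all computed on the occupied span only (zeros outside it are
  never mixed in), which makes every variant exactly translation
  equivariant; with augmentation the replica multiset of a rotated peptide
  is identical, so augmented predictions are *exactly* rotation invariant,
  not merely approximately so. The decomposition still fixes a
  deterministic anchor (lexicographically smallest capped SMILES, N-to-C
  direction) purely so that outputs are reproducible.
* **2D is enough.** All descriptors are topological/2D; no conformer
  generation is attempted.

## Parameters that matter

* `clampPPB` bounds: 50 and 95 %PPB. Fixed by the modeling objective.
* Max map length `L = 15` substructures; peptides of 5–15 residues are
  supported, shorter ones rejected.
* Descriptor trio (default model input): `MolLogP` (atomic-contribution
  octanol–water logP), `PEOE_VSA1` (approximate van der Waals surface area
  carrying the most negative Gasteiger charges, bin below -0.25 e) and
  `ESOL_LogS` (estimated aqueous solubility). These are open-source
  surrogates of the commercial lipophilicity / partial-charge / solubility
  descriptors a practitioner would use; the engine identity is recorded on
  every matrix so models are never mixed across engines. The charge-bin
  edges are calibrated to the Gasteiger implementation at hand, whose most
  negative charges (carbonyl oxygens) sit near -0.29 e.
* Frequency weighting: `count / max(count)` (strategy hook: `none`,
  `linear`, `sqrt`). The weighting expresses that descriptors of common
  substructures are estimated from more evidence; its exact functional form
  is a convention, so it is pluggable.
* Descriptor selection: constant filter, then |r| >= 0.95 pairwise filter
  (the member less correlated with clamped %PPB is dropped, deterministic
  visiting order), then bootstrap Lasso: 100 resamples, selection
  frequency threshold 1.0 (strict intersection), penalty grid 0.5–4.9 in
  steps of 0.2 with the stable window 4.3–4.9. The grid is on the scale of
  %PPB-unit targets; for differently scaled targets pass a rescaled grid.
* Training defaults: Adam (lr 1e-3), squared error on clamped labels,
  minibatches of 128 replicas, up to 300 epochs with early-stopping
  patience 30 on a 10% peptide-level validation split, full replica
  enumeration per epoch (subsample via `replicasPerEpoch` for speed).
  The network internally regresses z-scored labels — on the raw 50–95 scale
  the output bias alone would need tens of thousands of optimizer steps —
  and maps predictions (and saliency magnitudes) back to %PPB units.

## The synthetic data generator

Real cyclic-peptide PPB panels are proprietary, so the package ships a
generator that emulates their structure and makes every stage testable:

* **Chemistry.** Head-to-tail amide-cyclized peptides of 5–15 residues
  (sampled with mode near 7–10), optional N-methylation of interior amide
  nitrogens, optional terminal-cysteine disulfide cyclization. Two
  populations mirror real panels: an optimized, lipophilic,
  partly N-methylated majority and a hydrophilic natural-alphabet,
  disulfide-cyclized minority (default 15%) that supplies the low-%PPB
  tail.
* **Labels.** %PPB = clamp(a + b·mean(substructure logP) +
  c·max(substructure logP) + noise), defaults a = 30, b = 25, c = 25,
  noise sd 3 %PPB, clamped to [0, 100]. The mean term carries bulk
  lipophilicity; the max term plants a single "important residue" per
  peptide (the analogue of a fatty acyl chain), so attribution methods have
  a known target. With the default coefficients the label distribution
  concentrates in (50, 95) with mass at both clamp boundaries.
* **Consistency.** The generator assembles each peptide's molecular graph
  directly from residue templates and registers it with the parser cache;
  a test asserts canonical-SMILES identity between the stitched graph and
  a fresh parse of the emitted SMILES, and every generated peptide
  round-trips through the decomposer with exactly the requested residue
  count.

What the generator does *not* emulate: conformational ensembles,
stereochemistry, exotic monomers, ester linkages, measurement artefacts
correlated with chemistry. Passing the recovery tests therefore shows the
*machinery* (decomposition, featurization, learning, attribution) works
under a lipophilicity-driven signal — it does not validate predictive
accuracy on real assay panels.

## Numerical choices

* Centering an n-length span in 15 columns uses start = floor((15 - n)/2)
  (the spare zero column goes right).
* Kennard–Stone seeds with the two mutually farthest points and ties are
  broken by the smallest row index, making the split a pure function of the
  matrix.
* Standardization uses population standard deviations; a zero-variance
  column is an error naming the column.
* Batch-norm batches are homogeneous in span length; a singleton tail batch
  is merged into its predecessor so no sample is dropped. Inference uses
  running statistics, so replica averaging is deterministic.
* Saliency gradients are taken at the raw output: the clamp has zero
  gradient in its saturated regions and would erase attribution exactly for
  the strongly bound peptides one most wants to explain. The per-residue
  score sums |gradient| over descriptor rows.
* The degenerate case n = 1 map: 15 replicas, all rotations identical.

## Design decisions that were genuinely open

* **Decomposition anchor.** Nothing in the problem fixes where a ring
  "starts". We anchor at the lexicographically smallest capped canonical
  SMILES and traverse N-to-C. Augmentation makes the model indifferent to
  this; determinism is the only reason.
* **Clamp after averaging.** Replica predictions are averaged first and
  clamped once, preserving the mean as the ensemble estimate.
* **Span-restricted batch norm and pooling.** The padding columns carry no
  information; including them in statistics would leak the translation
  offset into the features and break exact rotation invariance.
* **What "the planted residue ranks first" means.** For a max-pooled conv
  net, vanilla-gradient saliency also attends to hydrophilic extremes
  (they inform the mean term), and peptides whose two most lipophilic
  residues nearly tie have no unambiguous "first". The package's recovery
  experiment therefore checks that the most lipophilic substructure is the
  *modal* top-saliency residue across held-out peptides — the qualitative
  claim that it attracts the most attention — rather than per-peptide
  exact top-1.
* **Validation monitoring.** Early stopping monitors identity-replica loss
  on a 10% peptide-level holdout; augmenting the validation set would only
  slow the loop without changing the ranking of checkpoints.

## Problem sizes used by the shipped experiments

The recovery experiment trains the `augmented` variant on a 334-peptide
synthetic panel (Kennard–Stone 10% test, so ~300 training peptides), with
8 replicas per peptide per epoch, batch 64, up to 120 epochs with patience
20 — about two minutes on one CPU. The null control (label coefficients
b = c = 0) trains on 50 peptides and evaluates 200 held-out ones so the
|R| < 0.25 bound is a ~3.5-sigma statement rather than small-sample noise.
These sizes are the package's chosen desk-scale study conditions; all are
configurable.

## Known limitations

* OpenBabel's SMILES reader is slow on occasional macrocycles (seconds per
  molecule); the package parses each SMILES once and memoizes, and the
  generator bypasses parsing entirely, but user-supplied tables of
  thousands of novel macrocycles will feel the reader's cost.
* Charged/zwitterionic inputs are handled as drawn; no protonation-state
  normalization is attempted, and descriptor surrogates are calibrated on
  neutral forms.
* Peptides with more than one macrocycle, depsipeptide ester linkages and
  HELM inputs are out of scope; the decomposer rejects what it cannot
  interpret rather than guessing.
* The CNN is intentionally small. It is sized for hundreds of peptides;
  for much larger panels both the architecture grid and the replica
  subsampling defaults deserve revisiting.
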