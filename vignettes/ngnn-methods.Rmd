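---
title: "Methods: solvent-aware natural-growth message passing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solvent-aware natural-growth message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most molecular property models see only the solute. For properties measured
in solution — aqueous solubility, absorption and emission wavelengths,
photoluminescence quantum yields — the solvent can shift the observable by
more than the entire solute-to-solute spread, and a model trained per solvent
overfits badly once data are thin. This package implements a natural-growth
message-passing network: information grows from atoms, to the intact
molecular graph, to two "dissolved" molecular graphs that carry solvent
information, and finally to a bulk-level scalar prediction.

# Featurization

Every molecule is a heavy-atom graph; hydrogens are implicit and enter only
through the per-atom H-count one-hot. Each chemical bond is stored as two
directed edges with identical features, which makes "messages into atom i"
a plain segment sum. Atom and bond indices are 1-based.

Three feature scales:

* **Inherent atomic features** (6 reals, "natural coding"): covalent radius
  (Å), Pauling electronegativity, atomic number, atomic mass (amu), first
  ionization energy (eV), electron affinity (eV). Because these are physical
  values rather than one-hot element identities, any element with tabulated
  constants is usable at prediction time even if it never occurred in
  training; the bundled table covers H through I including Ge, Se, Sn, Te.
* **Environmental atomic features** (23 bits + `k` marking bits): one-hot
  blocks in fixed order — valence 0–6, H count 0–4, formal charge in the
  listed order (−1, −2, 1, 2, 0), hybridization (s, sp, sp2, sp3) — then an
  in-ring bit and an aromatic bit. The ring/aromatic indicators are single
  bits, not 2-wide one-hots: a binary flag and its complement carry the same
  information, and the narrow coding keeps block offsets simple. Marking
  rules (e.g. `hydrophobic_halogen`, which flags F/Cl/Br/I for
  solubility-type tasks) each append exactly one extra bit.
* **Bond features** (7 bits): bond type one-hot (single, double, triple,
  aromatic), conjugated, aromatic, in-ring.

Structure perception is delegated to OpenBabel/ChemmineR (canonical SMILES,
implicit hydrogens, kekulized bond orders); ring membership comes from a
bridge-edge test and aromaticity from a Hückel 4m+2 count over kekulized
ring systems (an exocyclic double bond contributes sp2 character but no ring
π electron, so quinones are non-aromatic). Conjugation uses a documented
neighbourhood rule: aromatic bonds are conjugated; a multiple bond is
conjugated when an adjacent atom carries another π system or a lone-pair
donor; a single bond is conjugated when both ends are π-capable and at least
one is a π participant. These conventions agree with common toolkit output on
the standard cases (esters, amides, dienes) and, more importantly, are
deterministic and documented.

Multi-fragment (dot-separated) solutes are rejected: message passing over a
disconnected solute has no defined semantics here.

## Solvent descriptors

Each solvent is summarised once per molecule by 66 whole-molecule
descriptors in four families — electrotopological state (Kier–Hall intrinsic
states and their topological perturbation), VSA-type surface-area
contributions (a Labute-style sphere-cap approximation of per-atom van der
Waals areas, binned by E-state value and by electronegativity), topological
indices (Wiener, Balaban J, Zagreb, eccentricity measures, Kier kappa shape
indices with and without the covalent-radius alpha correction) and
connectivity indices (Randić chi 0–4 in simple and valence forms). The exact
identity of the 66 is a versioned implementation constant recorded in
`descriptor_registry()`; the literature only fixes the families, so the
choice is validated for length, finiteness and family coverage, and kept
stable under a version string. The same vector is broadcast to every solute
atom during node dissolution — descriptors describe the solvent molecule,
not any particular solute atom, so there is no atom-pairing rule to invent.

Solvent polarity enters separately through five empirical solvatochromic
parameters — Reichardt's Et(30) (kcal/mol) and the Catalán SP
(polarizability), SdP (dipolarity), SA (acidity), SB (basicity) — bundled
for the 12 registry solvents with literature citations. Lookup works by
conventional name, alias, or canonical SMILES, and the two routes resolve to
the same entry. A solvent outside the registry can have descriptors computed
on the fly, but its polarity is unknown; that is an error unless zero-fill
is explicitly allowed.

# The model

With `act` the configured activation (LeakyReLU(0.01) by default):

1. **Node embedding.** `h_i = concat(act(W1 h_ia), act(W2 h_ib))`. Inherent
   and environmental blocks are mapped by separate scales because natural
   and one-hot codings live in incompatible spaces.
2. **Intramolecular passing** (`k_intra` rounds, default 3):
   `h_i^k = Θ_k h_i^{k-1} + (1/N_i) Σ_{j∈N(i)} h_j^{k-1} ⊙ MLP(act(W4 e_ij_a))`.
   The gate is an elementwise product with an edge-conditioned MLP output of
   node width — the minimal reading of the juxtaposed product; the
   matrix-valued edge-network variant is deliberately not used. `1/N_i` is a
   mean over the receiving atom's neighbours; isolated atoms receive a zero
   message. There is no activation between rounds: the recurrence is kept
   linear in the states apart from the gate.
3. **Node dissolution.** `h_i^q = concat(h_i', act(W3 h_c))` — the final
   intramolecular state widened by one shared solvent tail.
4. **Edge dissolution.** `e_ij_c = concat(act(W4 e_ij_a), act(W5 e_ij_b))`;
   W4 is shared with stage 2 (the bond embedding is one object), W5
   maps the 5 polarity parameters; the polarity half is identical for every
   edge of a sample.
5. **Intermolecular passing, branch one**: same recurrence on the widened
   states, gated again by `MLP(act(W4 e_ij_a))` with its own MLP and Θ bank.
6. **Intermolecular passing, branch two**: on the unwidened states, gated by
   `MLP(e_ij_c)` — the gate consumes the dissolved edge features directly,
   with no inner re-embedding — the two branches deliberately gate on
   different views of the bond.
7. **Readout.** `h_G = concat(Set(·), Set(·))` over the two branches' final
   states. `Set` defaults to a set2set operator (LSTM controller with
   content-based attention, 3 processing steps) and can be switched to plain
   sum pooling. The aggregation over atoms is performed by the operator
   itself. Both choices are permutation-invariant by construction.
8. **Head.** A plain MLP (widths 128, 64, 1 by default) decodes `h_G` to the
   scalar property.

Θ is a bare learnable square map with no bias term,
one independent copy per round and stage; a config switch shares one Θ per
stage. Each round having its own Θ is the standard non-shared choice.

Defaults, all overridable and entirely this package's own design choices: all embedding widths 64 (node
width 128, dissolved width 192), `k_intra = 3`, `k_inter = 2`,
LeakyReLU(0.01), set2set with 3 steps, head (128, 64, 1), MSE loss, Adam at
`lr = 1e-3`, up to 300 epochs with early stopping (patience 30) on a 10%
validation carve-out of the training split, mini-batches of 64 disjoint
graph unions, Glorot-uniform initialization fully determined by the run
seed (the LSTM forget-gate bias starts at 1). No dropout or batch
normalization: neither is part of the core method.

## Numerical and engineering choices

* **Batching is exact.** A mini-batch is one disjoint graph union; because
  aggregation is a per-receiver mean and the readout is per-graph, batched
  and one-by-one evaluation agree to float round-off (asserted to 1e-5 in
  the tests).
* **Two implementations, one contract.** The reference forward/backward is
  written in plain R matrix algebra with hand-derived reverse-mode
  gradients; a compiled RcppArmadillo kernel reimplements the identical math
  for the training loop. The test suite asserts agreement of losses,
  predictions and all gradients between the two, and both are checked
  against central finite differences bank by bank.
* **Reproducibility.** Split, validation carve-out, initialization and batch
  shuffling draw from independent sub-streams of the run seed (a fixed
  congruential jump keeps derived seeds in 32-bit range). The compiled path
  fixes the batch partition once per training run and re-shuffles only the
  batch order per epoch (the R path re-partitions every epoch); within an
  engine, a seed reproduces the fit bit for bit.
* **Training traces** record the running mean MAE over each epoch's
  mini-batch predictions (the usual "training loss" semantics); the final
  train metrics are recomputed from a fresh pass with the final parameters.
* **Standardization.** Targets are z-scored on the training split; metrics
  and predictions are always reported in original units.
* **Checkpoints** are JSON text with base64-encoded IEEE-754 doubles per
  tensor, so a save/load round-trip is bit-exact without binary files.
* **Early stopping** monitors a carve-out of the training split only — the
  test set is never touched during model selection. For pure capacity
  checks (the 32-sample overfit test) the carve-out is disabled, since
  early stopping would defeat the point of the check.

# The toy-data generator

`generate_toy_dataset()` emulates the *shape* of solution-property datasets
— a CSV of (solute SMILES, solvent, numeric target) — with targets that are
exact closed forms of the features, plus optional Gaussian noise added only
at assembly:

* `solvent_linear`: `y = 10·SdP(solvent) + 5·n_aromatic + 3·n_halogen`;
* `solute_only`: `y = 5·n_aromatic + 3·n_halogen` (ablation control);
* `marked_sensitive`: `y = 3·n_halogen` (exercises atom marking).

The constants (α = 10, β = 5, γ = 3; y in arbitrary property units) are
frozen so that solvent and solute terms have comparable variance over the
default pools; the default solvent pool (water, hexane, DMSO, toluene)
spreads the SdP coordinate over nearly its full range. Solutes come from
five enumerated template families (alkanes, alcohols, halides, aromatics,
heteroaromatics); solvents are assigned round-robin and shuffled by seed.

Because the rules are known, the generator carries its own oracles: with
zero noise, ordinary least squares on the rule's three features explains the
targets with R² = 1; and the best *solute-only* predictor (the per-solute
conditional mean) has a closed-form R² ceiling
`1 − (V_within + σ²)/(V_total + σ²)` computed exactly from the noise-free
values. That ceiling is what the solvent-blind ablation (W3 and W5 frozen at
zero) is compared against: a model that cannot see the solvent cannot beat
it, whereas the full model can, which reproduces at toy scale the
qualitative finding that per-solvent information is what separates the
joint model from per-solvent overfitting.

What the toy task does *not* emulate: real photophysics or solubility
physics, conformational effects, measurement error structure,
concentration dependence, or dataset-scale chemical diversity. Passing tests
on it demonstrates that the architecture, gradients, training loop and
solvent plumbing are correct — not that the model attains literature
accuracy on external benchmarks, which would require their datasets.

# Problem sizes used in the checks

The automated checks run, on one CPU: dense-oracle equivalence on all toy
molecules with ≤ 6 heavy atoms over 20 random parameter draws;
permutation-invariance on 50 molecules; a 32-sample noiseless overfit run
(300 epochs, target: train MAE below 5% of the target SD); a 2,000-sample
`solvent_linear` task (noise at 5% of the signal SD, 80/20 split) where the
default model must reach held-out R² ≥ 0.9 — trained for up to 60 epochs
with patience 15, which the learning curves show is well past convergence
for this task — against the frozen ablation trained the same way; and a
1,000-sample `marked_sensitive` comparison of marked vs unmarked featurization
over three seeded runs (up to 30 epochs each). These sizes are the package's
chosen study conditions for a desk-scale, download-free verification.

# Known limitations

* Aromaticity/conjugation perception is a documented in-package convention,
  not a toolkit-exact reimplementation; exotic ring systems (fused
  heteroaromatics beyond ring size 7, mesoionic species) may be typed
  differently than by a specific cheminformatics toolkit.
* The 66-descriptor registry is one defensible instantiation of the four
  descriptor families; models trained under different registry versions are
  not interchangeable (checkpoints record the version).
* Formal charges outside {−2, −1, 0, +1, +2}, valences above 6 and atoms
  with more than 4 implicit hydrogens are rejected rather than clamped.
* `MRE` is undefined when any target is zero and is reported as `NA` there.
* Single-atom solutes are legal everywhere except the solvated-edge branch's
  edge construction, which requires at least one bond (the branch
  contributes a Θ-chain only, so predictions remain defined).
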