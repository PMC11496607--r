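# ngnn — solvent-aware graph neural networks for molecular property prediction

Properties measured in solution — aqueous solubility, absorption and
emission wavelengths, photoluminescence quantum yields, lipophilicity —
depend on the solvent as much as on the solute. Models trained on a single
solvent overfit badly; models that ignore the solvent cannot distinguish the
same dye in hexane from the same dye in DMSO. `ngnn` implements a
natural-growth message-passing network for solute–solvent systems: feature
information grows from atoms to the intact molecular graph, then to two
*dissolved* molecular graphs carrying solvent information, and finally to a
bulk-level scalar prediction. It is aimed at computational chemists who want
a solvent-aware graph regression baseline that runs from R with no external
model runtime.

## The model

Each solute is a heavy-atom graph. Atom *i* carries inherent physical
constants **h**<sub>i−a</sub> (covalent radius, electronegativity, atomic
number, mass, first ionization energy, electron affinity — encoded as their
numeric values, so unseen elements with tabulated constants remain usable)
and one-hot environmental features **h**<sub>i−b</sub> (valence, H count,
formal charge, hybridization, ring/aromatic flags, optional task-specific
marking bits such as a hydrophobic-halogen flag). Bond *ij* carries a 7-bit
block **e**<sub>ij−a</sub> (type, conjugation, aromaticity, ring). The
solvent enters twice: as a 66-dimensional whole-molecule descriptor vector
**h**<sub>i−c</sub> (E-state, VSA, topological and connectivity families)
broadcast to every solute atom, and as the solvatochromic polarity vector
**e**<sub>ij−b</sub> = (Et(30), SP, SdP, SA, SB) injected into every edge.

With σ the activation, the stages are

1. **h**<sub>i</sub> = concat(σ(W₁**h**<sub>i−a</sub>), σ(W₂**h**<sub>i−b</sub>))
2. **h**<sub>i</sub><sup>k</sup> = Θ**h**<sub>i</sub><sup>k−1</sup> + (1/N<sub>i</sub>) Σ<sub>j∈N(i)</sub> **h**<sub>j</sub><sup>k−1</sup> ⊙ MLP(σ(W₄**e**<sub>ij−a</sub>))
3. **h**<sub>i</sub><sup>q</sup> = concat(**h**<sub>i</sub>′, σ(W₃**h**<sub>i−c</sub>))
4. **e**<sub>ij−c</sub> = concat(σ(W₄**e**<sub>ij−a</sub>), σ(W₅**e**<sub>ij−b</sub>))
5. intermolecular rounds on the widened states, gated by the bond embedding
6. intermolecular rounds on the unwidened states, gated by MLP(**e**<sub>ij−c</sub>)
7. **h**<sub>G</sub> = concat(Set(·), Set(·)) over the two branches (set2set or sum)
8. y = MLP(**h**<sub>G</sub>)

Training minimises MSE on z-scored targets with Adam, early-stopped on a
validation carve-out; everything is reproducible from one seed. The
reference forward/backward pass is plain R matrix algebra with hand-derived
gradients; a compiled RcppArmadillo kernel implements the identical math for
the training loop and is asserted equal to the reference (and to finite
differences) in the test suite.

## A worked example

```r
library(ngnn)

# a deterministic toy dataset: y = 10*SdP(solvent) + 5*n_aromatic + 3*n_halogen
ds <- generate_toy_dataset(toy_dataset_spec(n_samples = 500, noise_sd = 0.7,
                                            seed = 7))
samples <- featurize_dataset(ds)
sp <- split_dataset(samples, train_fraction = 0.8, seed = 3)

fit <- ngnn_train(sp$train, ngnn_config(seed = 11), epochs = 100,
                  batch_size = 64)
ngnn_evaluate(fit, sp$test)$metrics
#> # A tibble: 1 × 5
#>     mae  rmse   mre    r2     n
#>   <dbl> <dbl> <dbl> <dbl> <int>
#> 1  1.95  2.47 0.856 0.972   100
```

A held-out R² of 0.972 on this task means the network has recovered both the
solute terms (aromatic and halogen counts) and the solvent term (the SdP
dipolarity coordinate) of the generating rule; the MRE is large only because
some targets sit near zero. The solvent matters: refitting with
`ngnn_config(solvent_blind = TRUE)` (W₃ and W₅ frozen at zero) caps the
same model at the closed-form solute-only ceiling
(`solute_only_ceiling()`, ≈ 0.92 here), which it approaches but cannot
exceed.

Inspect a fit the usual ways: `glance(fit)` (one-row summary), `tidy(fit)`
(per-parameter-bank summary), `autoplot(fit)` (learning curves),
`predict(fit, samples)` (a tibble of predictions in original units),
`ngnn_save(fit, "model.json")` / `ngnn_load()` (bit-exact text checkpoints).
A thin command-line wrapper with `generate` / `featurize` / `train` /
`predict` / `evaluate` / `multirun` subcommands ships in `inst/cli/ngnn.R`.

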