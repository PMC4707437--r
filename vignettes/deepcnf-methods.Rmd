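---
title: "Deep convolutional neural fields for secondary structure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep convolutional neural fields for secondary structure: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepcnf)
```

## The model

Protein secondary structure prediction assigns each residue of a sequence a
local-conformation class: three-state (helix H, strand E, coil C) or the
eight-state DSSP alphabet (H, G, I, E, B, T, S, L).  Two properties of the
problem drive the model implemented here.  First, the label at a residue
depends on a long stretch of sequence context, through a complicated,
non-linear map from profile features.  Second, adjacent labels are strongly
interdependent — secondary structure comes in segments, and an isolated
strand residue inside a helix is essentially impossible.

A deep convolutional neural field (DeepCNF) addresses both at once.  It is a
linear-chain conditional random field (CRF) whose node potentials are
produced by a multi-layer *windowed* (convolutional) network:

* **Feature layer.** Each residue $i$ carries a 42-vector $X_i$: the 20
  profile log-odds scores passed through $\sigma(x) = 1/(1+e^{-x})$, an
  unknown-residue profile slot, and a 21-way indicator of the amino-acid
  identity (20 standard residues plus X).
* **Convolutional stack.** Layer $k$ maps activations $H^k$ (with
  $H^1 = X$) to
  $H^{k+1}_i(m) = h\big(\sum_{n=-N_k}^{N_k}\sum_{m'} W^k_n(m',m)\,
  H^k_{i+n}(m')\big)$, with $h$ either tanh or the sigmoid.  Weights are
  shared across positions, so each additional layer widens the receptive
  field by $2N_k$ residues: five layers of window 11 see $\pm 25$ residues.
* **CRF on top.** With $S$ labels, the node score of label $a$ at position
  $i$ is $\sum_m U(m,a) H^{\mathrm{top}}_i(m)$, adjacent labels contribute
  the shared pair score $T(a,b)$, and
  $P(Y \mid X) \propto \exp\big(\sum_i \Phi_i(Y_i) + \sum_{i\ge 2}
  T(Y_{i-1}, Y_i)\big)$, normalised by the partition function $Z(X)$.

With one hidden layer this is exactly a conditional neural field (CNF); the
test suite checks that reduction against an independently coded CNF.

## Inference

All chain inference is exact dynamic programming in log space
(log-sum-exp), so potentials scaled by $10^3$ remain finite.  Forward and
backward recursions give $\log Z(X)$, per-position posteriors
$P(Y_i = a \mid X)$ and adjacent-pair posteriors; `crf_viterbi()` returns a
maximum-probability path with ties broken toward the lower label index at
every backtracking step (a determinism contract, not a modelling choice).
Viterbi is the default decoder; per-position posterior argmax is available
via `decoder = "posterior"`.  Pair potentials apply between positions
$2\ldots L$ only — there are no separate start/end label parameters, which
matches the single label-pair table $T$.

Normalisation tolerances are $10^{-9}$: posterior rows sum to one, pairwise
slices marginalise to the adjacent singletons, and the probabilities of all
label sequences of a small chain sum to one, all verified against
brute-force enumeration.

## Training

Parameters $\theta = \{W, U, T\}$ are fit by maximum likelihood with an L2
penalty: the objective is $-\sum_{\text{seq}} \log P(Y \mid X) + \lambda
\lVert\theta\rVert_2^2$.  Conventions that the problem statement leaves
open and that are frozen here:

* The penalty is $\lambda\sum\theta^2$ with **no** $\tfrac12$ factor, applied
  to all of $W$, $U$, $T$; the factor choice is absorbed into $\lambda$.
* The data term is **summed**, not averaged, over sequences, so $\lambda$
  scales with dataset size.  The cross-validation optimum for the
  full-scale task (thousands of proteins) is around 50; for the small
  synthetic tasks in this package $\lambda = 1$ is a sensible default and
  `cross_validate()` exists to choose it on new data.
* Initialization is uniform on $[-0.05, 0.05]$, seeded; small symmetric
  draws keep the squashing activations out of saturation.
* The optimizer is full-batch L-BFGS (memory 10, projected-gradient
  tolerance $10^{-4}$, iteration cap configurable) via R's reference
  implementation; no mini-batching, matching the CRF/CNF training lineage.
* Hidden activations default to tanh (zero-centred gradients optimise more
  easily); sigmoid is selectable per layer.  Either is permitted by the
  model family, which does not prescribe one.

Gradients are analytic.  For the CRF block they are
observed-minus-expected sufficient statistics, with expectations from
forward-backward; for the stack, the per-position label error
$E_i(a) = \delta(y_i = a) - P(Y_i = a \mid X)$ is propagated down through
$U$ and each window layer, using the activation derivative expressed in
activation values ($a(1-a)$ for sigmoid, $1-a^2$ for tanh).  Window
positions off either end of the sequence contribute zero, mirroring the
zero-padded forward pass (whether the original implementation padded or
truncated at termini is unstated; zero padding is this package's contract,
chosen because it keeps the displayed sum over fixed offsets and the
differentiation bookkeeping simple).  Every parameter class is checked
against central finite differences (step $10^{-5}$, relative error
$<10^{-5}$) at dozens of random points — the package's central correctness
property, exposed as `gradient_check()`.

There are **no bias terms**: the forward recurrence has none, and the
parameter accounting then reproduces the published depth series exactly
(47,064 / 267,064 / 487,064 / 707,064 parameters for 1/3/5/7 layers of 100
neurons at window 11 over 42 inputs and 8 labels, i.e. the quoted ~50K /
~270K / ~500K / ~700K).  A model trained here can optionally be built
layer-by-layer (`pretrain_layerwise()`): each window layer is trained
inside a one-hidden-layer model on the frozen activations of the previous
stage, and the stacked weights then initialise a simultaneous fine-tune,
whose objective can only improve on the stacked starting point.

## The synthetic world

Real training data for this task (thousands of PSI-BLAST-profiled,
DSSP-labelled chains) cannot ship with a package, so `simulate_dataset()`
generates a stated, fixed world in which every stage is testable:

* **Labels** follow a semi-Markov process with geometric segment durations
  — means helix 11, strand 6, coil 5, the first two being the field's
  standard average segment lengths, coil set between them; geometric
  durations are the simplest law with controllable means (real secondary
  structure length distributions are not geometric, which is a stated
  non-goal).  Jumps between distinct states are uniform by default.
* **Emissions**: residue $i$ in state $s$ gets 20 pseudo-profile scores
  $\text{round}(s\cdot\mu_s + \varepsilon)$, $\varepsilon \sim
  N(0, 2^2)$, clipped to $[-9, 13]$ to mimic the printed range of real
  PSI-BLAST matrices (so the real parser dialect is exercised).  The
  per-state means $\mu_s$ are disjoint $+1$ blocks scaled by
  `emission_signal`; signal 0 removes all label information, large signal
  makes states separable.  The default signal 1 with noise sd 2 puts the
  Bayes rate near 0.88 — hard enough that the chain prior matters, easy
  enough that training is fast.  Residue identities are uniform and carry
  no signal, so the indicator block is exercised but uninformative.
* **Bayes oracle.** `bayes_accuracy()` decodes with the true generative
  model (Gaussian emission log-densities at the stored integer scores,
  true transitions, stationary initial distribution) through the same
  forward-backward machinery and is the ceiling for any trained model.
  Because scores are rounded before the oracle sees them, the oracle is a
  near-exact surrogate for the true Bayes decoder on the discretised data
  (the discretisation loss is far below the sampling noise of the tests).

What a green learnability test establishes: the full pipeline — feature
construction, convolution, CRF inference, analytic gradients, L-BFGS —
can recover a planted sequence-labelling rule to within 10% of the optimal
decoder (the observed run reaches 96% of the Bayes rate), and never beats
the ceiling by more than sampling noise.  What it does not establish:
performance on real proteins, whose profiles have homology structure,
non-geometric segment laws and label-correlated residue identities that
the generator deliberately does not emulate.

## Evaluation

`q_accuracy()` is the per-residue percentage correct (Q3 or Q8 depending
on the alphabet).  `sov()` implements the 1999 revision of the segment
overlap score on three-state strings (eight-state input is mapped first,
since the score is defined and reported on helix/strand/coil): every
reference segment is paired with each overlapping same-state predicted
segment, contributing $\mathrm{len}(s_1)\,(\mathrm{minov}+\delta)/
\mathrm{maxov}$ with
$\delta = \min(\mathrm{maxov}-\mathrm{minov},\ \mathrm{minov},\
\lfloor \mathrm{len}(s_1)/2\rfloor,\ \lfloor \mathrm{len}(s_2)/2\rfloor)$;
unpaired reference segments contribute zero, and the normaliser counts a
reference segment once per overlapping pair (once if unpaired).  The
$\delta$ allowance forgives small boundary shifts, while a wrong patch in
the middle of a segment splits it into two pairs with poor spans — the
tests confirm a mid-segment error never scores above an equal-size
terminal error.  The earlier 1994 $\delta$ is deliberately not
implemented.  Per-state recall/precision use the convention that an empty
denominator yields 0, not NaN, so reports aggregate cleanly.

## Numerical and interface choices

* Eight-state alphabet order (H, G, I, E, B, T, S, L), three-state
  (H, E, C), amino acids alphabetical + X: arbitrary but frozen, since
  serialized models index into them.  Blank/'-'/'.' coil symbols from DSSP
  dialects normalise to L.
* A real PSSM has 20 columns but the feature contract says 21 profile
  features: column 21 is an unknown-residue flag, and at flagged positions
  the 20 profile features are neutralised to $\sigma(0)=0.5$.  This keeps
  the 21/21 feature split while giving degenerate residues a neutral
  profile.
* Profile columns are re-ordered from the file's order (the PSI-BLAST
  A R N D C ... convention) into the package's alphabetical ordering at
  featurization, so features are independent of the source dialect.
* Model files are JSON with doubles printed at 17 significant digits,
  which round-trips bit-exactly; 15 digits (the library default) does not.
* `cross_validate()` uses a seeded random k-way split; every sequence
  lands in exactly one validation fold.
* Degenerate inputs: length-1 chains are valid everywhere (no pair terms);
  empty datasets, mismatched lengths, out-of-range labels and malformed
  profile files raise immediate, named errors.

## Worked example

```{r example, eval = FALSE}
train <- simulate_dataset(generator_config(num_sequences = 60, seed = 1))
test  <- simulate_dataset(generator_config(num_sequences = 25, seed = 1001))
spec  <- deepcnf_spec(input_width = 42, num_labels = 3,
                      hidden_sizes = c(10, 10), window = 5)
model <- train_deepcnf(train, spec,
                       train_config(lambda = 1, max_iterations = 100))
preds <- predict(model, test)
evaluate_predictions(vapply(preds, `[[`, character(1), "ss3"),
                     vapply(test, `[[`, character(1), "labels"),
                     states = 3)
bayes_accuracy(test)$accuracy
```

The same pipeline is scripted in `scripts/acceptance.R` and on the command
line via the installed wrapper (`system.file("cli", "deepcnf.R", package =
"deepcnf")`) with the subcommands `simulate`, `train`, `predict`,
`evaluate`, `gradcheck` and `cv`.

## Known limitations

* Full-batch L-BFGS in pure R is fine for the package's synthetic scale
  (hundreds of sequences, thousands of parameters) but would need days for
  the full-scale task; that scale is out of scope here.
* The generator does not emulate evolutionary profiles, effective-homolog
  depth, or template information; conclusions about real-protein accuracy
  cannot be drawn from it.
* Running PSI-BLAST or DSSP is out of scope: their outputs are parsed, not
  produced.  Binary PSSM checkpoints are not parsed.
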