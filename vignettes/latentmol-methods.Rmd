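---
title: "Generative autoencoders for molecular design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative autoencoders for molecular design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

De novo molecular design asks for novel structures with desired properties —
an inverse-QSAR problem: a forward model predicts activity from structure,
but no explicit inverse map exists from descriptor space back to chemistry.
`latentmol` follows the generative-autoencoder route: encode molecules
(as SMILES strings) into a continuous latent space, learn that space well
enough that nearby points decode to similar chemistry, and then search the
space directly with Bayesian optimization against a QSAR score. No inverse
mapping is ever constructed; the decoder *is* the map from latent space to
structures.

## Sequence representation

A SMILES string is tokenized into single characters, except the
two-character halogen atoms `Cl` and `Br`, which are single tokens. Bracket
atoms such as `[nH]` remain character-level. The vocabulary is derived from
the training corpus (pad token first, remaining tokens in C-locale
lexicographic order, so shuffled corpora give identical vocabularies).
Sequences are padded with spaces to a fixed maximum length (120 by default)
and one-hot encoded; the pad token doubles as the terminator, so decoding
cuts at the first pad. There is no separate start/stop token: at the first
decoding step the previous-token input is a zero vector.

## The four autoencoders

All variants share one architecture family. The encoder applies three 1-d
convolutions over the one-hot sequence, SELU activations, then two dense
layers. The decoder maps the latent point through a dense layer to the
initial hidden states of three stacked GRU layers; the latent point is also
concatenated as the input of the first GRU layer at every step, so the
latent code conditions every position rather than only the initial state
(this was a genuinely open design point; conditioning every step makes the
no-teacher-forcing variant workable at all, since its last layer otherwise
receives no position-dependent signal). A final dense layer produces token
logits at each position.

* **NoTeacher VAE** — variational encoder; the last GRU layer sees only the
  previous layer's output, in both training and generation.
* **Teacher VAE** — variational encoder; during training the last GRU layer
  additionally receives the true previous target token; during generation it
  receives the previously *sampled* token.
* **Gauss AAE / Uniform AAE** — deterministic encoder whose output
  distribution is pushed toward a standard Gaussian or a per-coordinate
  Uniform(-1, 1) prior by an adversarial discriminator. Teacher forcing is
  always on for the adversarial decoders.

The variational loss is the reconstruction negative log-likelihood (summed
over every padded position and averaged over the batch) plus the KL
divergence of the diagonal Gaussian posterior from N(0, I), in closed form
`-1/2 * sum(1 + log s^2 - mu^2 - s^2)`. Pad positions count: the
reconstruction metric of record is position-to-position accuracy over the
full padded string, and the loss matches it. A `kl_weight` ramps linearly
from 0 to `kl_max` (default 1, which reproduces the plain variational
objective) over `kl_anneal_epochs`; unannealed sequence VAEs are prone to
posterior collapse. When early stopping triggers before the ramp completes,
the effective final weight is below `kl_max`; the training log records the
weight per epoch.

The adversarial loop runs three optimizer updates per batch, in order:
(1) encoder + decoder on the reconstruction loss; (2) discriminator on
`-(log D(z') + log(1 - D(z)))` with fresh prior draws `z'`; (3) encoder on
`-log D(z)`. The discriminator is three dense layers: affine only, affine +
SELU, affine + sigmoid. Probabilities are clamped to `[1e-7, 1 - 1e-7]`
before logarithms. Each of the three losses has its own Adam state, as in
the usual three-optimizer implementation.

All networks, including full backpropagation through the GRU stack,
convolutions and the reparameterization `z = mu + sigma * eps`, are written
in base R matrix code; the test suite verifies every analytic gradient
against central finite differences at relative error below 1e-4.

## Generation and metrics

Decoding a latent point samples the token distribution at every position
(temperature 1). Teacher-forcing architectures feed the sampled token back
at the next step. Each latent point is decoded `n_samples` times (500 at
full scale); every sequence is converted to a string and validity-checked
with the chemistry toolkit; the most frequently sampled valid SMILES is the
consensus output, with ties broken lexicographically for determinism, and no
consensus when no sample is valid.

Metrics: *training-mode* character accuracy scores teacher-forced argmax
predictions against the target over all padded positions; *generation-mode*
accuracy scores sampled strings character-by-character against the padded
target; validity is reported per reconstruction attempt (each sample
counts), and consensus accuracy (fraction of molecules whose consensus
equals the target) is reported separately.

## Similarity probe

To ask whether the latent space preserves the chemical similarity
principle, a query molecule is mapped to its latent point and, for each
distance d on a grid (0 to 8 in steps of 0.1 at full scale), points are
drawn uniformly on the sphere of radius d around it — "random points at
distance d" is under-determined; the uniform-sphere construction is the
least-informative choice. Ten points per bin and 500 samples per point give
5000 reconstruction attempts per bin. Per bin we record the fraction of
valid SMILES and the median ECFP6 Tanimoto similarity of all valid
structures to the query. The raw per-sample log is attached to the returned
curve so the aggregation can be recomputed independently.

## QSAR scoring and the search objective

The activity model is a Gaussian-kernel SVM with probability outputs on
ECFP6 fingerprints. The toolkit computes extended-connectivity fingerprints
of diameter 6 on a 4096-bit space; we fold to 2048 bits by OR-ing halves
(configurable). C and gamma are grid-searched by cross-validated AUROC;
classes are weighted inversely to frequency because bioactivity tables are
typically heavily imbalanced. The decision threshold is fixed at 0.5.

The score of a latent point z is two-branch: decode z, keep unique valid
compounds, drop structures whose smallest-set-of-smallest-rings contains a
ring of more than eight atoms (optimizers drift toward synthetically
implausible macrocycles), predict P(active) for the survivors; if any
exceeds 0.5 the score is the mean P(active) of those predicted actives,
otherwise the mean over all remaining compounds, and 0 when nothing valid
survives — so non-decodable regions rank worst. Scoring averages over
*unique* compounds by default (the alternative, frequency-weighted
averaging, is one flag away; uniqueness was chosen so that a single
over-sampled string cannot dominate the score).

## Bayesian optimization

The surrogate is a Gaussian process with squared-exponential kernel (single
length-scale, no automatic relevance determination), jitter 1e-6, and
hyperparameters (length-scale, signal variance, noise variance) fitted by
L-BFGS-B on the log marginal likelihood; between refits (every 10
iterations by default) the kernel is kept and only the data grow. The
expected-improvement acquisition `(mu - best) * pnorm(u) + sigma * dnorm(u)`
is maximized by random multistart plus Nelder-Mead refinement, with
perturbations of the incumbent best added to the candidate set. The search
box is the prior's support for Uniform-prior models and [-4, 4] per
coordinate otherwise (covering > 99.99% of a standard Gaussian's mass per
coordinate). A search runs 100 random initial points followed by 500 EI
iterations at full scale; repeated searches restart independently rather
than sharing a surrogate, matching the independent-repeats reading of the
protocol. Objective failures score 0 and the search continues.

## Desk-scale study conditions

Full-scale training of these models is a GPU-and-megacorpus exercise
(million-molecule corpora, 56-dimensional latent spaces, batches of 500 at
learning rate 3.1e-4 until convergence — those remain the package
defaults). Everything in the test suite instead runs on a synthetic fixture
corpus: 50 unique canonical SMILES assembled from a curated
scaffold/substituent grammar (`make_fixture_corpus()`), guaranteeing rings,
branches, aromatic heteroatoms, bracket atoms and two-character halogen
tokens, 10+ heavy atoms, and at most ~27 tokens. The corpus emulates the
token-level structure of a drug-like training set, not its diversity:
passing the overfit tests demonstrates that the machinery (codec, losses,
gradients, samplers, consensus selection) is correct, not that the model
generalizes to unseen chemistry.

The overfit harness uses narrow networks (conv channels 8/8/8 with kernel
3, dense width 64), minibatches of 25 at learning rate 5e-3 and Adam. The
teacher-forcing VAE uses latent dimension 16 and GRU width 64, stopping at
99.9% training-mode accuracy under a KL ramp of 600 epochs. The
no-teacher-forcing VAE must store the whole sequence in the latent code —
its last GRU layer receives no token feedback — and needs latent dimension
24, GRU width 96, a longer low-KL horizon (ramp 2000 epochs), learning rate
4e-3 with per-epoch decay 0.996, and up to 900 epochs; without the decay
its late-training accuracy oscillates instead of converging. The
adversarial variants use latent dimension 8 (fewer dimensions make
desk-scale prior matching attainable), GRU width 96, discriminator widths
64/64, and train a fixed 450 epochs with learning-rate decay 0.997: the
encoder-prior game keeps settling after reconstruction has converged, and
the decay anneals it to rest. Problem sizes throughout the suite (probe
grids of a few distances with tens of samples, BO budgets of 60+60) keep a
full test run in minutes on one CPU; one probe bin and one accounting check
run at the full 10 x 500 = 5000 attempts-per-bin setting.

Adversarial prior matching at this scale is approximate: with 50 encoder
outputs the empirical moments carry both Monte-Carlo noise and an
adversarial-equilibrium gap. The documented acceptance band is: pooled
encoder-output mean within 0.4 of the prior mean, pooled variance within a
factor of [0.5, 1.5] of the prior variance, and held-out discriminator
accuracy in [0.4, 0.6], where the held-out evaluation classifies 200 fresh
prior draws against the encodings of 200 fixture molecules never seen in
training — encodings of the 50 training molecules alone make an unstable,
imbalanced statistic this close to chance.

## Numerical choices and degenerate inputs

* Weights: LeCun-normal initialization (the standard pairing for SELU);
  GRU weights uniform in ±1/sqrt(hidden).
* Optimizer: Adam (0.9/0.999, eps 1e-8) for every update.
* Softmax/cross-entropy computed with max-subtraction; probabilities inside
  adversarial losses clamped at 1e-7.
* Consensus ties: lexicographic; empty strings never win (an all-pad
  decode is not a molecule).
* GP: kernel length-scale initialized at the median pairwise squared
  distance; Cholesky failures during hyperparameter search are treated as
  infinite negative log-likelihood; predictive variances are clamped at 0.
* Degenerate decoders (all-pad output) give 0% validity and a character
  accuracy equal to the mean pad fraction of the targets — both covered by
  tests.
* `sigma = 0` in expected improvement falls back to `max(mu - best, 0)`.

## Known limitations

* OpenBabel (via ChemmineOB) defines canonical SMILES and validity here;
  its canonical forms differ textually from other toolkits', and it is more
  permissive about exotic valences than some. All round-trip guarantees are
  internal to this one toolkit.
* The hand-written networks are CPU-bound base R; they are sized for
  method-correctness work, not corpus-scale training.
* Stereochemistry is stripped by design; the codec has no stereo-aware
  path.
* The fixture generator guarantees validity by construction from a curated
  grammar; it cannot produce the pathological SMILES found in real
  registries (that is what the validity checker is for).
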