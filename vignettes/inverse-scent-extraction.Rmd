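---
title: "Inverse extraction of odorant mass spectra from scent impressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse extraction of odorant mass spectra from scent impressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentmap)
```

## The problem

Predicting how a molecule smells from its sensing data (here, its
electron-ionization mass spectrum) is the *forward* problem. `scentmap`
addresses the *inverse* one: given a desired scent impression expressed
as binary odor descriptors, find the mass spectra of molecules that
realize it. Because each odorant carries several descriptors and
descriptor sets overlap across chemically related molecules, a plain
per-descriptor classifier does not answer this; instead the package
clusters spectra in a compressed space, writes descriptors onto the
cluster map, and reads the map backwards.

The pipeline has four stages, each exposed as ordinary functions so any
stage can be run, inspected or replaced on its own.

## Preprocessing

Spectra are unit-mass binned (fractional m/z rounds to the nearest
integer; duplicate bins merge by summing) and windowed to m/z 51–262,
giving 212 intensity channels. The low-m/z region is excluded because
fragments there are shared by odorless molecules and carry little
discriminative signal. Each row is then divided by its own maximum so
the base peak within the window equals 1.

Base-peak scaling (rather than total-ion-current or unit-norm scaling)
is a deliberate choice: the autoencoder reconstructs through sigmoid
output units, whose range is (0, 1), so inputs must live on that scale,
and base-peak normalization is the convention spectral libraries already
use for relative intensities. Molecules with no peak inside the window
cannot be normalized and are excluded with a warning — never silently.

`window_and_normalize()` is idempotent: applying it to already windowed,
normalized data reproduces the data.

## The sparse autoencoder

A symmetric five-layer network (212–90–50–90–212) with logistic sigmoid
activations at every layer compresses each spectrum to a 50-dimensional
bottleneck code. Training minimizes

$$E \;=\; \frac{1}{N}\sum_{n=1}^{N}\sum_{k=1}^{K}\bigl(y_{kn}-x_{kn}\bigr)^2
\;+\; \frac{\lambda}{2}\sum_{l,j,i}\bigl(W^{(l)}_{ji}\bigr)^2
\;+\; \beta\,\Omega_{\text{sparsity}},$$

the mean-over-samples, summed-over-channels squared reconstruction
error plus an L2 weight penalty and a sparsity penalty. Defaults follow
the optimized values of the reference setup: hidden sizes 90 and 50,
learning rate $\eta = 0.01$, $\lambda = 10^{-4}$, $\beta = 1$, 1000
epochs.

Several points were genuinely open and are resolved as follows:

* **Sparsity form.** $\Omega_{\text{sparsity}}$ is the sum over
  bottleneck units of the Bernoulli Kullback–Leibler divergence
  $\mathrm{KL}(\rho\,\|\,\hat\rho_j)$, where $\hat\rho_j$ is unit $j$'s
  mean activation over the batch — the standard sparse-autoencoder
  penalty. The target $\rho$ defaults to 0.05 and is exposed in
  `ae_config()`. Mean activations at exactly 0 or 1 are clamped to
  $[10^{-12}, 1-10^{-12}]$ with a warning, since the KL is otherwise
  infinite.
* **Which layers are penalized.** The bottleneck only, the simplest
  reading of a penalty "on the hidden layer"; `sparsity_layers =
  "all_hidden"` covers the alternative reading and is exercised by the
  gradient-check tests.
* **Output activation.** Sigmoid, keeping reconstructions in the input
  range. Only the hidden activation is dictated by the architecture
  description; sigmoid output is the natural pairing with inputs in
  $[0,1]$.
* **Biases in the L2 sum.** Included. The cost's wording sums the
  weight matrices *including the biases*; this is unusual (most
  implementations exempt biases) but is followed literally.
* **Optimizer.** Plain mini-batch gradient descent with fixed $\eta$
  (batch size 32, exposed). Only $\eta$ and the epoch count are
  specified by the reference conditions, so no momentum or adaptive
  scheme is layered on.
* **Initialization.** Seeded Glorot-style uniform weights, zero biases.
* **Normalization of the reconstruction term.** The cost divides by the
  sample count $N$ only, not by the channel count $K$; this is
  implemented literally (summed over channels, averaged over samples),
  which is why per-epoch losses are on the order of the per-spectrum
  squared error.

The analytic backpropagation gradient — including the L2 and KL terms —
is verified against central finite differences to below $10^{-5}$
relative error on seeded toy networks; this is the strongest correctness
guarantee in the module and runs in the test suite and the acceptance
script.

Model selection uses k-fold cross-validation (`ae_cross_validate()`,
five folds by convention: four train, one evaluates) scored by mean
per-sample summed squared reconstruction error with the regularization
terms excluded, and `ae_grid_search()` ranks candidate configurations by
that score (ties favor the smaller bottleneck). The model used by the
pipeline is retrained on all data after selection.

## The self-organizing map

The 50-d latent codes are organized on a hexagonal lattice (default
30×20 = 600 units; the pipeline's synthetic-data validation uses 10×8,
matched to its 300 molecules). Hexagon centers use odd-row offset
coordinates — $x = H + 0.5\,(V \bmod 2)$, $y = V\sqrt{3}/2$ — so all six
neighbors of an interior neuron are at planar distance exactly 1, which
makes "neighborhood radius 1" mean precisely one ring. All distances
(BMU search in codebook space, neighborhoods in lattice space) are
Euclidean; the Gaussian neighborhood is
$h(u) = \exp(-d^2(u,\text{BMU})/2\sigma^2)$.

Training is competitive and sample-wise: each of the 500 iterations
draws one random sample, finds its best matching unit (ties broken by
the smallest row-major index, so results are deterministic), and moves
every codebook vector toward the sample by $\alpha(t)\,h(u)$. The
reference conditions list fixed values ($\alpha_0 = 0.5$, $\sigma_0 =
1$) without a schedule; the package defaults to the asymptotic decay
$\alpha(t) = \alpha_0/(1+t/(T/2))$ used by the common SOM
implementations, with `decay = "none"` available to reproduce the
fixed-rate reading. 500 iterations is far fewer than one pass over a
couple of thousand molecules, which implies sample draws rather than
epochs; that is the default and the iteration count is configurable.

Two diagnostics guide map sizing: the quantization error (mean distance
from each sample to its BMU) and the number of blank lattice units
(`map_size_scan()` reports both). Larger maps always fit at least as
well but strand more empty neurons and split clusters; the working size
is the knee of that trade-off.

## Labeling and inverse extraction

`label_lattice()` writes each neuron's label set as the **union** of its
member molecules' descriptor sets. Union is the only rule consistent
with finding two descriptors on one neuron while its members
individually carry one of them; molecules without annotations still
count as members (they can be extracted) but contribute no labels. An
optional exclusion list drops over-broad descriptors (e.g. "sweet",
"fruity") from labels without touching membership.

Queries then come in three forms:

* `neurons_for_descriptor()` — all neurons carrying one label;
* `neurons_for_descriptor_pair()` — neurons carrying both labels, either
  anywhere on the neuron (`both_on_neuron`) or on a single member
  molecule (`both_on_molecule`, always a subset of the former);
* `locate_molecule()` — the BMU of a named molecule.

`inverse_map()` performs the retrieval: every molecule whose BMU is the
chosen neuron, with its latent spectrum and, optionally, cosine
similarity to a reference member. `nearest_neuron()` finds the closest
neuron (planar hexagon-center distance) satisfying a label predicate,
for contrasting a both-descriptors neuron against a nearby
one-descriptor neuron.

Similarity is the plain spectral cosine $\cos\theta$ between intensity
vectors — no m/z weighting, matching the stated score exactly — and one
implementation serves both raw 212-channel spectra and 50-d latent
codes. With sigmoid latents all entries are positive, so pipeline scores
lie in $[0,1]$, and proportional spectra score 1 regardless of scale.
PCA closeness checks use mean-centered, unscaled projections with each
axis's sign fixed by its largest-magnitude loading, so plots are
reproducible run to run.

## Duo-trio statistics

Panel results (k of n panelists matched the reference) are scored by the
exact right-tailed one-proportion binomial test at chance rate
$p_0 = 0.5$ — appropriate at panel sizes around 20, where the normal
approximation is rough — alongside the uncorrected z statistic
$z = (k - np_0)/\sqrt{np_0(1-p_0)}$. The exact tail is an explicit sum
of binomial terms for $n \le 64$ and a log-sum-exp of log binomial
coefficients above that; the test suite checks it against both a
brute-force coefficient sum and `pbinom` as independent oracles.

## The synthetic data generator

Licensed spectral and descriptor databases cannot be redistributed, so
the package ships a generator whose output has the statistical structure
the method relies on, not arbitrary Gaussian blobs:

* **Archetypes as fragment ladders.** Each of the (default 12)
  archetypes is a template spectrum of 8 peaks at $base + 14k$ m/z — the
  CH₂ homologous-series spacing of EI spectra — with geometrically
  decaying intensities. Same-archetype molecules therefore share peak
  *positions* and differ in intensities, which is exactly the similarity
  structure spectral cosine and the autoencoder exploit in real
  libraries.
* **Molecule-level noise.** Per-peak lognormal intensity jitter
  ($\sigma = 0.3$) and Poisson(2) spurious minor peaks at ≤ 10% of the
  base peak.
* **Descriptors.** Each archetype draws 2–4 labels from a 20-label pool
  with 25% overlap between adjacent archetypes, and each molecule drops
  each inherited label with probability 0.1 — emulating both the
  descriptor overlap across related odorants and the annotation sparsity
  of flavor databases.

Default sizes (300 molecules, 12 archetypes) keep a full pipeline run at
a few seconds while leaving ~25 molecules per archetype, enough for
majority statistics per neuron. What the generator does **not** emulate:
real fragmentation chemistry, isotope patterns, heterogeneous
within-class variance, and descriptors that cut across spectral classes.
Passing the end-to-end test therefore shows the pipeline recovers
cluster structure *when it exists in the spectra*; it does not show that
real odor descriptors are always spectrally clustered — that is the
scientific hypothesis the method embodies, not a property of the code.

## End-to-end validation

The pipeline's acceptance property is parameter recovery on generated
data: with the defaults above, a 150-epoch autoencoder and a 10×8 map,
querying each archetype's first descriptor must yield, for at least 80%
of archetypes, a neuron whose member majority belongs to the archetype
owning that descriptor (`archetype_recovery()`; ground truth is used
only for scoring). The problem sizes — 300 molecules, 150 epochs, 10×8
map, toy networks for the gradient checks — were chosen so the whole
suite exercises every stage at full fidelity in seconds while leaving
per-neuron memberships large enough to be statistically meaningful.

Numerical edge cases are handled explicitly rather than left to float
behavior: KL clamping at saturated activations (with a warning),
BMU and nearest-neuron ties broken by row-major index, cosine scores
clamped into $[-1,1]$ against rounding overshoot, BMU distances
recomputed by direct subtraction so samples sitting exactly on a
codebook vector report distance 0, and zero-signal spectra rejected
before normalization.

## Limitations

* Training is plain gradient descent in pure R; adequate for datasets of
  a few thousand spectra, not for large libraries.
* The map gives no ranking of neurons by descriptor strength; neuron
  choice among several matches is left to the user, as in the original
  procedure.
* Tanimoto/structural similarity and word-embedding descriptor
  similarity are out of scope; SMILES strings are carried as opaque
  annotations only.
* The z statistic is reported without continuity correction; at small
  panels the exact p-value, not z, should decide.
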