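---
title: "Integrating unpaired single-cell modalities with a coupled VAE and unbalanced optimal transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating unpaired single-cell modalities with a coupled VAE and unbalanced optimal transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell experiments increasingly profile the same biological system
through different instruments: transcriptomes (scRNA-seq), chromatin
accessibility summarized as gene-activity scores (scATAC-seq), or spatially
resolved panels (MERFISH, Visium-style spots). The cells are *unpaired* —
no cell is measured twice — the feature spaces only partially overlap, and
each modality carries its own systematic distortions. `uotvae` embeds such
datasets into one latent space in which the same cell populations from
different modalities coincide, and then uses the fitted model as an
instrument: imputing genes one modality never measured, transferring labels,
and decomposing spatial spots into cell-type proportions.

## Model

Let $X^c \in [0,1]^{n_x \times k}$ and $Y^c \in [0,1]^{n_y \times k}$ be the
two datasets restricted to $k$ highly variable *common* genes after
preprocessing, and $X^s$, $Y^s$ their dataset-specific highly variable
genes.

**Coupled VAE.** A single dataset-free probabilistic encoder $\psi$ maps a
cell's common-gene profile to a diagonal Gaussian posterior
$\psi(z \mid x) = \mathcal N(\mu, \operatorname{diag}(\sigma^2))$ in $K$
dimensions, sampled by reparameterization $z = \mu + \sigma \odot \nu$,
$\nu \sim \mathcal N(0, I)$. Because the encoder has no dataset-specific
parameters, two identical profiles from different datasets receive identical
posteriors — sharing is structural, not learned. Decoding is asymmetric:

* one *common decoder* $\phi$ (linear, then batch normalization, then
  sigmoid) reconstructs the common genes, with a separate batch-normalization
  branch per dataset (separate scale/shift and running statistics, selected
  by the cell's dataset id). This dataset-specific batch normalization
  (DSBN) is what absorbs modality-level distribution shift while the latent
  space stays shared;
* one *specific decoder* per dataset ($\phi_x$, $\phi_y$; a direct linear
  map plus sigmoid, no hidden layer) reconstructs that dataset's own genes
  from the same latent code, so modality-private signal shapes the embedding
  without leaking across datasets.

Inputs are max-abs scaled to $[0,1]$ and all decoders end in a sigmoid, so
reconstruction log-likelihoods are Bernoulli (binary cross-entropy). The
modified evidence lower bound on a joint minibatch is
$$
\mathcal L_{\mathrm{ELBO}^*} =
\mathbb E_{\psi(z\mid x)}\Big[\log \phi(x^c \mid z)
 + \lambda_s \big(\log \phi_x(x^s \mid z) + \log \phi_y(y^s \mid z)\big)\Big]
 - \lambda\, D_{\mathrm{KL}}\!\big(\psi(z \mid x)\,\|\,\mathcal N(0, I)\big),
$$
where each cell's specific genes are reconstructed from its own latent code
through its own dataset's specific decoder, the natural reading of the
coupled architecture.

**Transport alignment.** Maximizing $\mathcal L_{\mathrm{ELBO}^*}$ alone
embeds both datasets but does not make corresponding populations coincide.
Alignment comes from minibatch unbalanced optimal transport on the
posteriors. For minibatches $I$, $J$ the cost is the squared 2-Wasserstein
distance between diagonal Gaussians,
$$
C_{ij} = \lVert \mu_{x_i} - \mu_{y_j} \rVert^2
       + \lVert \sigma_{x_i} - \sigma_{y_j} \rVert^2,
$$
and the plan solves the entropic *unbalanced* problem
$$
T^* = \arg\min_{T \ge 0}\; \langle C, T\rangle - \epsilon H(T)
 + \rho\, \mathrm{KL}(T \mathbf 1 \,\|\, a)
 + \rho\, \mathrm{KL}(T^\top \mathbf 1 \,\|\, b),
\qquad H(T) = -\textstyle\sum_{ij} T_{ij}(\log T_{ij} - 1),
$$
with uniform minibatch marginals $a = \mathbf 1/B_x$, $b = \mathbf 1/B_y$ by
default (user-weighted marginals are supported for known population
imbalance). Relaxing the marginals through KL penalties is the key to
*unbalanced* integration: mass on cell types missing from one dataset can
simply go unmatched instead of being forced onto the wrong population. The
alignment loss is $\mathcal L_{\mathrm{UOT}^*} = \sum_{ij} C_{ij} T^*_{ij}$
with the plan treated as a constant — gradients flow only through $C$, i.e.
through the encoder. The total training objective is
$\mathcal L = -\mathcal L_{\mathrm{ELBO}^*} + \gamma\, \mathcal L_{\mathrm{UOT}^*}$.

## Solving the transport problem

`solve_uot()` uses multiplicative scaling: with kernel
$G = e^{-C/\epsilon}$ and exponent $\rho/(\rho+\epsilon)$,
$$
\alpha \leftarrow \big(a / (G\beta)\big)^{\rho/(\rho+\epsilon)}, \qquad
\beta \leftarrow \big(b / (G^\top\alpha)\big)^{\rho/(\rho+\epsilon)}, \qquad
T = \operatorname{diag}(\alpha)\, G\, \operatorname{diag}(\beta),
$$
updated in Gauss–Seidel order ($\beta$ uses the fresh $\alpha$). With the
kernel held fixed this iteration converges to the unique minimizer of the
strictly convex entropic objective above — the package's default, and the
object the loss is defined on. The test suite verifies the attained
objective against an independent general-purpose convex minimizer.

An alternative *proximal* scheme re-centers the kernel at the current plan
after every outer iteration ($G = T^{(l)} \odot e^{-C/\epsilon}$). This
anneals the entropic smoothing away, so the iterates drift toward the
*unregularized* unbalanced optimum — sharper, lower-entropy plans that no
longer minimize the entropic objective (on random $3\times3$ problems the
objective gap is of order $10^{-2}$, versus $10^{-10}$ for the fixed-kernel
scheme). Because the method's loss and its theory are stated on the entropic
problem, the fixed-kernel solver is the default and the re-centered scheme
is exposed as `recenter = TRUE` for users who want near-unregularized plans.

Numerical safety: the kernel is clamped at $10^{-300}$ and the scaling
denominators at $10^{-280}$, so partial kernel underflow (cost entries far
beyond $\epsilon$'s scale, routine mid-training) cannot spin the scaling
vectors to infinity; convergence is declared on the relative change of the
scaling vector, which is overflow-safe even when $\beta$ spans hundreds of
orders of magnitude. Shifting $C$ by row minima — a common balanced-OT
stabilization — is deliberately *not* applied, because subtracting a
constant changes the optimal total mass of the unbalanced problem.

## Training loop

Per iteration: sample duplicate-free index sets from each dataset
(epoch-cycling permutations; partial batches are dropped because batches of
fewer than two cells break batch normalization), encode both minibatches,
reparameterize, decode common (per-dataset DSBN branch, batch statistics)
and specific genes, build $C$, solve $T^*$, and take one Adam step on
$\mathcal L$. Optionally, a dense global plan $T$ (initialized uniform at
$1/(n_x n_y)$) has its sampled $I \times J$ block overwritten by each
converged minibatch plan; this is the cell-to-cell correspondence used by
label transfer and deconvolution. Keeping the plan optional costs nothing:
with the default solver the minibatch problem does not depend on the stored
block, so enabling it changes no training numerics (a tested invariant).

Defaults follow the method's published training recipe: encoder hidden
layers 1024–128 (ReLU), $K = 16$, decoders without hidden layers, Adam with
learning rate $2\times10^{-4}$ and weight decay $5\times10^{-4}$, minibatch
256 per dataset, $\epsilon = 0.1$, $\rho = 1$, at most 30{,}000 iterations
with early stopping after 30 epochs without improvement. The loss-weight
grids are $\lambda \in \{0.5, 1, 5\}$, $\lambda_s \in \{0.5, 1\}$,
$\gamma \in \{0.5, 1\}$; the package fixes $\lambda = 0.5$,
$\lambda_s = 0.5$, $\gamma = 1$ as defaults. Choices the recipe leaves
open, settled here:

* **Posterior scale.** The encoder emits a log-variance clamped to
  $[-10, 10]$; $\sigma = e^{\mathrm{logvar}/2}$. The clamp bounds
  $\sigma \in [e^{-5}, e^{5}]$ and its gradient is masked outside the
  window.
* **Loss reduction.** Mean over cells within each dataset, summed over the
  two datasets; BCE summed over features and KL summed over latent
  dimensions. This keeps $\lambda$, $\lambda_s$, $\gamma$ meaningful when
  the two datasets differ in size.
* **Epoch.** $\lceil \max(n_x, n_y) / B \rceil$ iterations; early stopping
  tracks the epoch-mean total loss with a $10^{-4}$ relative improvement
  threshold and returns the best epoch's parameter snapshot.
* **Initialization.** Kaiming-uniform weights, zero biases, batch-norm
  scale 1 / shift 0; all randomness (initialization, minibatch order,
  reparameterization draws) flows from the single `seed` argument, so runs
  are bit-reproducible.
* **Batch statistics.** Training uses per-minibatch statistics and updates
  running statistics with momentum 0.1 (the unbiased variance enters the
  running estimate); all evaluation-mode passes (embedding, imputation,
  prediction) use the selected branch's running statistics.

The hot path (joint forward/backward pass plus the minibatch transport
solve) is implemented in C++ (RcppArmadillo) for speed; a pure-R reference
implementation of the identical computation ships in the package
(`engine = "r"`), and the test suite checks the two agree to machine
precision, alongside a finite-difference check of every parameter gradient.

## Preprocessing

The fixed pipeline mirrors standard single-cell practice: detection
filtering (cells with fewer than 200 detected genes, genes detected in fewer
than 3 cells — strict "fewer than" semantics; intended for droplet-style
data and off by default for simulations and spot data), per-cell total-count
normalization (target = median of per-cell totals unless given),
$\log(1+x)$, highly-variable-gene selection, and per-gene max-abs scaling
to $[0,1]$, in that order. HVGs are ranked by mean-binned normalized
dispersion on the log-normalized data (statistics on
$\mathrm{expm1}$-backtransformed values, dispersion = variance/mean,
z-scored within 20 quantile bins of the mean — the widely used "seurat"
flavor). For the *common* list the score is computed per dataset on the
gene-id intersection and genes are ranked by the sum of their per-dataset
ranks, ties broken lexicographically, making the selection deterministic
and cell-order invariant. A TF-IDF + truncated-SVD utility
(`tfidf_lsi()`, IDF $= \log(1 + n_{\mathrm{cells}} / (1 + n_{\mathrm{cells\ with\ peak}}))$
— dialects differ, so the form is pinned here) is provided for peak-level
accessibility matrices; it is not on the default training path.

## Downstream uses

* **Imputation** (`impute()`): encode source cells (evaluation mode, no
  sampling — deterministic), decode through the *target* dataset's DSBN
  branch and specific decoder. Works unchanged on cells never seen in
  training, so new samples can be projected into a trained atlas without
  retraining.
* **Label transfer / deconvolution** (`label_transfer()`,
  `deconvolute()`): a target cell's (or spot's) class probability is the
  column-normalized plan mass received from source cells of that class.
  Column normalization makes the result invariant to global rescaling of
  the plan; zero-mass columns are flagged rather than silently labelled,
  and argmax ties go to the lexicographically first class, recorded.
* **TLS score** (`tls_score()`): per spot, the summed T-cell and B-cell
  proportion with a colocalization flag (both above a floor, default 0.05 —
  a reporting convention, configurable).

## Evaluation metrics

All metrics run on a caller-supplied embedding (the latent means, or a 2-D
UMAP of them computed externally with the conventional
`n_neighbors = 15`, `min_dist = 0.1`; the package never computes UMAP).
kNN label transfer (deterministic $k=5$ classifier; ties to the
lexicographically first class) is scored by pair-counting ARI, NMI
($2I/(H_U + H_V)$, defined 0 for single-class partitions) and macro-averaged
F1 over the union of observed classes. The silhouette is computed over
cell-type labels and rescaled to $[0,1]$ via $(s+1)/2$, with the $0/0$ case
taken as 0. Batch entropy corrects regional batch proportions by the global
ones, restricts to cell types common to all batches, and is reported
normalized as $-E/\log(n_{\mathrm{batches}})$ averaged over 100 seeded
probe cells with 50-nearest-neighbour regions (region size and probe count
are conventions, configurable; the raw regional entropy is $\le 0$, so the
sign/normalization makes 1 = perfect mixing). FOSCTTM uses Euclidean
distances on row-paired embeddings. Independent cross-checks against
`mclust`, `igraph` and `cluster` implementations are part of the tests.

## Synthetic data: what it emulates, and what it does not

`simulate_multiome()` provides the ground truth every validation rests on:
per-type latent centroids (sd 1) plus within-type noise (sd 0.4) in a 10-D
state space; non-negative half-normal loadings through an exp-link; Poisson
counts with Bernoulli dropout (rate 0.3 by default); a monotone gene-wise
gain and additive log-scale shift on modality *y* (batch effect, scale 0.5);
optional removal of cell types from one modality (unbalanced designs);
optional pairing (identical latent draws, aligned rows) for FOSCTTM. Gene
intercepts are $\mathcal N(\log 50, 0.3^2)$: deep-count highly variable
genes, chosen so that at zero dropout and zero batch effect the paired
modalities' per-gene correlation is dominated by shared signal rather than
Poisson noise (median above 0.95 — a generator property the tests assert).
Defaults are 600 cells per modality, 3 types, 300 common + 150 specific
genes. `simulate_spots()` sums 5–15 real cell profiles per spot and records
the true mixing proportions.

What it does *not* emulate: zero inflation beyond Bernoulli-thinned Poisson,
peak-level chromatin sparsity, library-size gradients confounded with cell
type, continuous differentiation trajectories, doublets, or spatial
autocorrelation between spots. Passing the synthetic studies therefore
demonstrates that the estimator recovers the structure its model class
assumes, at realistic noise levels — not that it is robust to every real
artefact.

## Validation studies and problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) runs the full method on the generator defaults with
2,000 training iterations, encoder hidden sizes (256, 64) and $K = 16$ —
a compact configuration suited to the ~500-feature synthetic problem, fit
in about a minute on one CPU; the package defaults (1024–128) remain those
of the published recipe. The studies are: cell-type recovery (kNN-transfer
ARI on the latent embedding across 5 seeds, and FOSCTTM on the paired
variant), robustness to removing one of three cell types from one modality
(shared-type ARI against the balanced run at matched seed), held-out gene
imputation against a cell-shuffled baseline (an 80/20 split of the common
genes, with the withheld genes attached to the reference modality's
specific decoder — the withheld genes must sit behind *some* decoder to be
predictable, which is exactly how panel-limited spatial data is handled),
and spot deconvolution through the accumulated global plan. Solver, KL,
cost and metric implementations are checked against independent oracles
(a BFGS minimizer of the transport objective, numeric quadrature, naive
double loops, and pair-counting formulas).

For the spot-deconvolution study the KL weight is taken at the top of the
recipe's grid ($\lambda = 5$) — the recipe selects $\lambda$ per dataset,
and a strong KL pull compacts the latent scale so that the entropic plan
spreads mass over a spot's composition instead of collapsing onto its
dominant cell type. Even so, plan-based composition estimates are the
package's weakest instrument on cleanly separated synthetic populations:
plan mass between a spot and two clusters scales like
$e^{-\Delta d^2/\epsilon}$, so once training has fully separated the
clusters relative to $\epsilon = 0.1$, proportions bias toward the dominant
type. The acceptance study reports the resulting mean absolute proportion
error as measured; real tissue, with its continuum of states and noisier
boundaries, is closer to the regime this instrument was designed for.

## Known limitations

* Two datasets per fit in this version; the interface (dataset-id
  registries throughout) is laid out for a future dataset list.
* Bernoulli reconstruction only — appropriate for max-abs-scaled inputs,
  not a count likelihood; ZINB/Gaussian decoders are out of scope.
* The dense global plan costs $O(n_x n_y)$ memory (a message reports the
  footprint before allocation); export supports thresholded sparse output.
* Matrices are densified at the model boundary; inputs of ~$10^4$ cells by
  ~$10^3$ HVGs are the intended scale on CPU.
* No HDF5-based container reader; MTX triplets and dense CSV/TSV are the
  supported interchange formats.
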