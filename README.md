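# uotvae

Integration of **unpaired single-cell datasets from different modalities**
(scRNA-seq, scATAC-seq gene-activity scores, spatial transcriptomics) into a
shared latent space, for analysts who need one embedding across instruments:
a coupled variational autoencoder trained jointly with a minibatch
**unbalanced optimal-transport** alignment loss, plus the downstream tools
the embedding enables — cross-modality gene imputation, transport-plan label
transfer, spatial spot deconvolution — and the standard integration metric
suite (kNN-transfer ARI/NMI/F1, scaled silhouette, batch entropy, FOSCTTM).

## Model

Two preprocessed datasets X, Y share *k* highly variable common genes
(X^c, Y^c, scaled to [0,1]) and keep their own specific genes (X^s, Y^s).
A single dataset-free encoder ψ maps each cell to a diagonal Gaussian
posterior N(μ, diag(σ²)) in K dimensions (z = μ + σ ⊙ ν). One common decoder
φ with a **dataset-specific batch-normalization branch per dataset**
reconstructs the common genes, and per-dataset decoders φ_x, φ_y reconstruct
the specific genes, all Bernoulli-likelihood (sigmoid + binary
cross-entropy):

    L_ELBO* = E_ψ[ log φ(x^c|z) + λ_s (log φ_x(x^s|z) + log φ_y(y^s|z)) ]
              − λ KL(ψ(z|x) ‖ N(0, I))

Alignment comes from entropic **unbalanced** optimal transport between the
minibatch posteriors, with cost the squared 2-Wasserstein distance between
diagonal Gaussians:

    C_ij = ‖μ_xi − μ_yj‖² + ‖σ_xi − σ_yj‖²
    T*   = argmin_{T≥0} ⟨C,T⟩ − εH(T) + ρ KL(T1‖a) + ρ KL(Tᵀ1‖b)
    L    = −L_ELBO* + γ Σ_ij C_ij T*_ij        (plan detached)

Relaxed marginals (weight ρ) let mass go unmatched, so cell types present in
only one dataset are tolerated instead of being forced onto the wrong
population. The plan is solved by multiplicative scaling with exponent
ρ/(ρ+ε); accumulated across minibatches it becomes the dense cell-to-cell
(or cell-to-spot) correspondence used for label transfer and deconvolution.

Defaults follow the published recipe: encoder 1024–128 (ReLU), K = 16,
decoders without hidden layers, Adam (lr 2e-4, weight decay 5e-4),
minibatch 256, ε = 0.1, ρ = 1, λ = 0.5, λ_s = 0.5, γ = 1, up to 30,000
iterations with 30-epoch-patience early stopping. The training hot path is
compiled (RcppArmadillo) with a pure-R reference implementation tested for
exact agreement.

## Worked example

```r
library(uotvae)

# two synthetic modalities with shared cell types, batch effect and dropout
sim <- simulate_multiome(n_cells = c(400, 400), seed = 42)

fit <- uotvae(sim$x, sim$y, filter = FALSE,
              n_common_hvg = 300, n_specific_hvg = 150,
              hidden_dims = c(128, 32), max_iterations = 800,
              patience = 10000, seed = 42)
print(fit)
#> Coupled-VAE / unbalanced-OT integration fit
#>   datasets: x + y (400 and 400 cells)
#>   genes: 300 common, 150/150 specific
#>   latent dim 16, encoder 128-32
#>   800 iterations; best epoch 398 (loss 523.4943)

emb_x <- predict(fit, dataset_id = "x", type = "latent")
emb_y <- predict(fit, dataset_id = "y", type = "latent")
metric_report(emb_x, emb_y, sim$x$cell_types, sim$y$cell_types, seed = 42)
#> <metric_report>
#>   ari                1.0000
#>   nmi                1.0000
#>   f1                 1.0000
#>   silhouette_scaled  0.8251
#>   batch_entropy      0.9857
```

The report reads: a kNN classifier trained on the x-cells' latent
coordinates predicts every y-cell's type exactly (ARI/NMI/F1 = 1), cell
types stay separated in the embedding (scaled silhouette 0.83, where 0.5 is
indifferent), and local neighbourhoods mix the two datasets almost
perfectly (batch entropy 0.99, where 1 is ideal mixing). Downstream:

```r
imp  <- impute(fit, source_id = "y", target_id = "x")   # y-cells' x-genes
plan <- uotvae(sim$x, sim$y, filter = FALSE, global_plan = TRUE, ...)$global_plan
deconvolute(plan, sim$x$cell_types)                     # spot/cell proportions
```

`run_integrate(x, y, out_dir)` runs preprocess → fit → embed → metrics and
writes embeddings, loss history, checkpoint, metrics and a manifest to disk.

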