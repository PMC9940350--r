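# sivae

Interpretable variational autoencoders for single-cell transcriptomes, with
downstream gene co-expression network analysis.

## What problem this solves

Nonlinear dimensionality reduction (VAEs, t-SNE, UMAP) produces cell
embeddings whose axes mean nothing: unlike PCA, there is no loading matrix
telling you which genes drive which embedding dimension. `sivae` fits a
variational autoencoder with **two** coupled encoder-decoder pairs — one over
cells, one over genes — so that every cell gets a score vector
*z*<sub>c</sub> ∈ ℝ<sup>K</sup> and every gene a loading vector
*v*<sub>f</sub> ∈ ℝ<sup>K</sup> in a shared K-dimensional space, exactly
analogous to PCA scores and loadings but learned by a nonlinear model.

The generative model draws both latents from standard normal priors, pushes
them through separate decoders, and combines them bilinearly:

    z_c,1 ~ N(0, I_K)        z_c,l = mu_l(z_c,l-1)      (cell decoder)
    v_f,1 ~ N(0, I_K)        v_f,l = omega_l(v_f,l-1)   (feature decoder)
    X_cf  ~ N( v_f,L' z_c,L , sigma_d(z_c,L) )

Inference uses a pair of amortized encoders (cells are encoded from their
gene vector; genes are encoded from their expression profile across cells,
reduced to length `c_red` by PCA or stratified downsampling). The objective
is the usual evidence lower bound plus a γ-weighted **interpretability
term**, `γ · Σ log N(X_cf ; v_f,1' z_c,1, 1)`, which softly aligns the latent
dot product with the data so that dimension k of the loadings corresponds to
dimension k of the scores (γ = 0.05 by default). Observation-model variants:
Gaussian (centered/scaled log-normalized data), negative binomial (raw
counts, scVI-style library-size handling), and a linear decoder variant.

Because the model must reconstruct all genes from a low-dimensional space, a
trained model carries co-expression information for free:

- **degree centrality** of a gene = its negative reconstruction error (hub
  genes reconstruct best);
- **network neighbors** = nearest genes in loading space (`siVAE-Euc`), or
  neighbors in a network inferred from data sampled out of the generative
  model (`siVAE-GCN`);
- **population-level network comparison** = per-population loading-derived
  adjacencies compared with a Weisfeiler-Lehman subtree kernel, embedded by
  PCA, and tested edge-by-edge against phenotypes (rank-sum tests with
  Benjamini-Hochberg correction).

The package also ships the simulation designs used to validate all of this:
a hub-and-spoke gene network simulator (five 50-gene communities, each a hub
connected to 49 spokes at correlation 0.6, plus 50 isolated genes; 5000
multivariate-Gaussian cells) and a labeled cell-cluster simulator.

All networks are trained with a built-in reverse-mode autodiff engine and
Adam — no external deep-learning runtime is required.

## Worked example

```r
library(sivae)

# simulate expression data from a known co-expression network
net <- build_hub_spoke_network(n_communities = 5, community_size = 50,
                               n_isolated = 50, edge_weight = 0.6)
net
#> gene_network: 300 genes, 245 edges, 5 hubs

cells <- sample_cells(network_to_covariance(net), n_cells = 5000, seed = 21)
x <- center_scale(cells)$values

cfg <- sivae_config(n_latent = 2, encoder_widths = c(64, 32),
                    decoder_widths = c(32, 64), gamma = 0.05,
                    c_red = 128, learning_rate = 1e-2,
                    epochs = c(20, 20, 30), seed = 33)
fit <- sivae_fit(x, cfg)
emb <- extract_embeddings(fit, x)
emb
#> sivae embedding: 5000 cells x 2 dims; 300 gene loadings

# genes of the same community co-localize in the feature embedding
d <- as.matrix(dist(emb$loadings))
comm <- net$community
ut <- upper.tri(d); same <- outer(comm, comm, "==")
both <- outer(comm > 0, comm > 0)
sprintf("loading distance within communities: %.3f, between: %.3f",
        mean(d[ut & same & both]), mean(d[ut & !same & both]))
#> "loading distance within communities: 0.060, between: 0.734"

# hub genes have the lowest per-gene reconstruction error
cent <- sivae_degree_centrality(emb)
head(cent$gene_ids[order(-cent$score)], 8)
#> [1] "hub2"       "hub5"       "c2_spoke42" "c2_spoke28" "c2_spoke31"
#> [6] "c2_spoke16" "c2_spoke41" "c2_spoke46"
```

Genes from the same simulated community sit an order of magnitude closer to
each other in loading space than genes from different communities, and the
top of the centrality ranking is dominated by the communities this K = 2
model captured (at K = 64, the dimension used for co-expression analyses,
all five hubs land in the top decile; see the methods vignette).

A thin command-line wrapper is provided at `inst/cli/sivae.R`
(`simulate`, `train`, `embed`, `sample` subcommands over MatrixMarket/TSV
files).

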