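# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

toy_gaussian_model <- function(seed = 3L, gamma = 0.05) {
  cfg <- sivae_config(n_latent = 2L, encoder_widths = c(7L, 5L),
                      decoder_widths = c(4L, 6L), gamma = gamma,
                      observation_model = "gaussian", c_red = 6L,
                      l2_scale = 1e-3, seed = seed)
  sivae_init(cfg, n_features = 5L, c_red = 6L)
}

toy_batch <- function(nc = 10L, nf = 5L, c_red = 6L, seed = 11L) {
  set.seed(seed)
  list(x = matrix(rnorm(nc * nf), nc, nf),
       xred = matrix(rnorm(nf * c_red), nf, c_red))
}

# small clustered fixture and fitted gaussian models for evaluation tests
cluster_fixture <- function() {
  fixture("clusters", function() {
    em <- simulate_clustered_cells(3L, 120L, 30L, separation = 8,
                                   seed = 101L)
    list(em = em, x = center_scale(em)$values,
         labels = em$cell_labels)
  })
}

cluster_fit <- function(gamma) {
  key <- paste0("cluster_fit_", gamma)
  fixture(key, function() {
    fx <- cluster_fixture()
    cfg <- sivae_config(n_latent = 2L, encoder_widths = c(32L, 16L),
                        decoder_widths = c(16L, 32L), gamma = gamma,
                        observation_model = "gaussian", c_red = 64L,
                        learning_rate = 1e-2, epochs = c(25L, 10L, 40L),
                        batch_cells = 120L, batch_features = 30L,
                        seed = 404L)
    sivae_fit(fx$x, cfg, n_restarts = 3L)
  })
}

# the hub-and-spoke simulation study: network, covariance, sampled cells
gcn_fixture <- function() {
  fixture("gcn", function() {
    net <- build_hub_spoke_network()
    cov <- network_to_covariance(net)
    em <- sample_cells(cov, n_cells = 5000L, seed = 21L)
    list(net = net, cov = cov, x = center_scale(em)$values)
  })
}

gcn_config <- function(K, seed = 33L) {
  sivae_config(n_latent = K, encoder_widths = c(64L, 32L),
               decoder_widths = c(32L, 64L), gamma = 0.05,
               observation_model = "gaussian", c_red = 128L,
               learning_rate = 1e-2, epochs = c(20L, 20L, 30L),
               batch_cells = 128L, batch_features = 300L, seed = seed)
}

gcn_fit <- function(K) {
  fixture(paste0("gcn_fit_K", K), function() {
    fx <- gcn_fixture()
    sivae_fit(fx$x, gcn_config(K))
  })
}

gcn_embedding <- function(K) {
  fixture(paste0("gcn_emb_K", K), function() {
    extract_embeddings(gcn_fit(K), gcn_fixture()$x)
  })
}

# Two groups of populations drawn from structurally different hub-and-spoke
# networks over a shared 40-gene universe; per population a correlation
# network is inferred from 400 sampled cells and binarized.
multipop_fixture <- function() {
  fixture("multipop", function() {
    ids <- paste0("g", 1:40)
    reid <- function(net) gene_network(unname(net$weights), gene_ids = ids,
                                       is_hub = net$is_hub,
                                       community = net$community)
    netA <- reid(build_hub_spoke_network(2L, 15L, 10L))
    netB <- reid(build_hub_spoke_network(3L, 10L, 10L))
    covA <- network_to_covariance(netA)
    covB <- network_to_covariance(netB)
    n_per_group <- 20L
    groups <- rep(c("A", "B"), each = n_per_group)
    adjacencies <- lapply(seq_len(2L * n_per_group), function(p) {
      cv <- if (groups[p] == "A") covA else covB
      em <- sample_cells(cv, n_cells = 400L, seed = 1000L + p)
      w <- correlation_adjacency(em)$weights
      gene_network((w >= 0.45) * 1, gene_ids = ids)
    })
    pop_sim <- wl_similarity(adjacencies, n_iterations = 3L)
    ut <- which(upper.tri(netA$weights), arr.ind = TRUE)
    inA <- netA$weights[ut] != 0
    inB <- netB$weights[ut] != 0
    keys <- paste(ids[ut[, 1]], ids[ut[, 2]])
    corr_diff <- abs(covA[ut] - covB[ut]) > 0.01
    list(adjacencies = adjacencies, groups = groups, pop_sim = pop_sim,
         true_diff_keys = keys[xor(inA, inB)],
         corr_diff_keys = keys[corr_diff & !xor(inA, inB)])
  })
}
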