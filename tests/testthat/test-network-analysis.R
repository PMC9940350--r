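make_embedding <- function(loadings, gene_ids = NULL, recon_err = NULL) {
  f <- nrow(loadings)
  structure(list(
    scores = matrix(0, 1, ncol(loadings)),
    loadings = loadings,
    per_gene_recon_error = recon_err %||% rep(0, f),
    gene_ids = gene_ids %||% paste0("g", seq_len(f))
  ), class = "sivae_embedding")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("embedding centrality is the negative reconstruction error", {
  emb <- make_embedding(matrix(0, 4, 2), recon_err = c(0, 2, 1, 0.5))
  ct <- sivae_degree_centrality(emb)
  expect_equal(ct$score, c(0, -2, -1, -0.5))
  expect_equal(order(ct$score), rev(order(emb$per_gene_recon_error)))
  expect_equal(which.max(ct$score), 1L)       # zero error ranks first
})

test_that("network mean-weight centrality matches the fixture arithmetic", {
  net <- build_hub_spoke_network()
  ct <- gcn_degree_centrality(net)
  hub <- which(net$is_hub)[1]
  spoke <- which(net$community == 1 & !net$is_hub)[1]
  iso <- which(net$community < 0)[1]
  expect_equal(ct$score[hub], 49 * 0.6 / 299, tolerance = 1e-12)
  expect_equal(ct$score[spoke], 0.6 / 299, tolerance = 1e-12)
  expect_equal(ct$score[iso], 0)

  full <- gene_network(matrix(1, 4, 4) - diag(4))
  expect_equal(gcn_degree_centrality(full)$score, rep(1, 4))
})

test_that("embedding-space and weight-based neighbors match brute force", {
  # line fixture: loadings at 0, 1, 2, 3
  emb <- make_embedding(matrix(c(0, 1, 2, 3), 4, 1))
  ns <- neighbors_euclidean(emb, "g1", k = 2L)
  expect_equal(ns$neighbors, c("g2", "g3"))
  # duplicate loading at the query position ranks first (zero distance)
  emb2 <- make_embedding(matrix(c(0, 5, 0, 3), 4, 1))
  expect_equal(neighbors_euclidean(emb2, "g1", k = 2L)$neighbors[1], "g3")
  expect_error(neighbors_euclidean(emb, "nope", 1L), "unknown")

  net <- build_hub_spoke_network()
  hubns <- neighbors_from_weights(net, "hub1", k = 20L)
  expect_length(hubns$neighbors, 20L)
  expect_true(all(grepl("^c1_spoke", hubns$neighbors)))
  isons <- neighbors_from_weights(net, "iso1", k = 20L)
  expect_true(isons$low_confidence)
  expect_false(hubns$low_confidence)

  # exhaustive-oracle agreement on random instances
  set.seed(71)
  for (rep in 1:5) {
    f <- 30L
    load <- matrix(rnorm(f * 3), f, 3)
    w <- abs(matrix(rnorm(f * f), f, f)); w <- (w + t(w)) / 2; diag(w) <- 0
    emb3 <- make_embedding(load)
    net3 <- gene_network(w)
    q <- sample(f, 1)
    qid <- paste0("g", q)
    ns_e <- neighbors_euclidean(emb3, qid, k = 7L)
    d <- sqrt(colSums((t(load) - load[q, ])^2))
    d[q] <- Inf
    expect_equal(ns_e$neighbors, paste0("g", order(d)[1:7]))
    ns_w <- neighbors_from_weights(net3, paste0("gene", q), k = 7L)
    ww <- w[q, ]; ww[q] <- -Inf
    expect_equal(ns_w$neighbors, paste0("gene", order(-ww)[1:7]))
  }
})

test_that("correlation adjacency is symmetric, bounded, and near-zero for
           independent genes", {
  set.seed(73)
  x <- matrix(rnorm(4000 * 6), 4000, 6)
  x <- cbind(x, x[, 1])                       # gene 7 copies gene 1
  colnames(x) <- paste0("g", 1:7)
  net <- correlation_adjacency(x)
  expect_equal(net$weights, t(net$weights))
  expect_equal(net$weights["g1", "g7"], 1, tolerance = 1e-12)
  expect_lt(max(net$weights[1:6, 1:6]), 0.08)  # independent, n = 4000
  expect_equal(unname(diag(net$weights)), rep(0, 7))

  xz <- cbind(x[, 1:3], const = 1)
  expect_warning(netz <- correlation_adjacency(xz), "zero-variance")
  expect_equal(unname(netz$weights[, 4]), rep(0, 4))
  expect_error(correlation_adjacency(x[1:2, ]), "3 cells")
})

test_that("query-gene selection intersects per-method top lists exactly", {
  ids <- paste0("g", 1:10)
  c1 <- structure(list(gene_ids = ids, score = 10:1, method = "a"),
                  class = "centrality_result")
  c2 <- structure(list(gene_ids = ids, score = 10:1, method = "b"),
                  class = "centrality_result")
  expect_equal(select_query_genes(list(c1, c2), top_n = 4L), ids[1:4])
  c3 <- structure(list(gene_ids = ids, score = 1:10, method = "c"),
                  class = "centrality_result")
  expect_length(select_query_genes(list(c1, c3), top_n = 4L), 0L)
  # brute-force agreement on random scores
  set.seed(79)
  cs <- lapply(1:3, function(i) {
    structure(list(gene_ids = ids, score = rnorm(10), method = "r"),
              class = "centrality_result")
  })
  got <- select_query_genes(cs, top_n = 5L)
  want <- Reduce(intersect, lapply(cs, function(ct) {
    ids[order(ct$score, decreasing = TRUE)[1:5]]
  }))
  expect_setequal(got, want)
  bad <- structure(list(gene_ids = rev(ids), score = 1:10, method = "x"),
                   class = "centrality_result")
  expect_error(select_query_genes(list(c1, bad)), "mismatched")
})

test_that("neighborhood overlap and mean correlation match definitions", {
  mk <- function(q, nb) structure(list(query_gene = q, neighbors = nb,
                                       method = "t"), class = "neighbor_set")
  a <- mk("q", paste0("g", 1:20))
  b <- mk("q", paste0("g", 11:30))
  expect_equal(neighborhood_overlap(a, a), 100)
  expect_equal(neighborhood_overlap(a, b), 50)
  expect_equal(neighborhood_overlap(mk("q", paste0("g", 1:20)),
                                    mk("q", paste0("h", 1:20))), 0)
  expect_error(neighborhood_overlap(a, mk("q", "g1")), "same k")

  set.seed(83)
  x <- matrix(rnorm(500 * 10), 500, 10)
  colnames(x) <- paste0("g", 1:10)
  a2 <- mk("q", paste0("g", 1:4))
  b2 <- mk("q", paste0("g", 5:8))
  got <- neighborhood_mean_correlation(x, a2, b2)
  # brute-force double loop
  acc <- 0
  for (i in 1:4) for (j in 5:8) acc <- acc + cor(x[, i], x[, j])
  expect_equal(got, acc / 16, tolerance = 1e-12)
  expect_lt(abs(got), 0.1)
  # perfectly correlated sets give 1
  xx <- matrix(rep(rnorm(100), 4), 100, 4); colnames(xx) <- paste0("g", 1:4)
  expect_equal(neighborhood_mean_correlation(xx, mk("q", c("g1", "g2")),
                                             mk("q", c("g3", "g4"))), 1)
  expect_error(neighborhood_mean_correlation(x, a2, mk("z", "g5")), "query")
})

test_that("neighborhood benchmark recovers exact and null relationships", {
  set.seed(89)
  n <- 400
  base <- rnorm(n)
  x <- cbind(q = base, copy = base,
             matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("n", 1:3))))
  mk <- function(nb) structure(list(query_gene = "q", neighbors = nb,
                                    method = "t"), class = "neighbor_set")
  pve_copy <- benchmark_neighborhood(x, mk(c("copy", "n1", "n2", "n3")),
                                     epochs = 300L, learning_rate = 1e-2)
  expect_gt(pve_copy, 0.95)
  pve_null <- benchmark_neighborhood(x, mk(c("n1", "n2", "n3")),
                                     epochs = 100L, learning_rate = 1e-2)
  expect_lt(abs(pve_null), 0.1)
  expect_error(benchmark_neighborhood(x, mk(c("q", "n1"))), "among")
})

test_that("neighborhood benchmark approaches the closed-form linear R^2 on
           jointly Gaussian data", {
  net <- build_hub_spoke_network(n_communities = 1L, community_size = 6L,
                                 n_isolated = 2L)
  cm <- network_to_covariance(net)
  em <- sample_cells(cm, n_cells = 1500L, seed = 31L)
  # predict the hub from its 5 spokes: closed-form R^2 from the covariance
  hub <- net$gene_ids[net$is_hub][1]
  spokes <- net$gene_ids[net$community == 1 & !net$is_hub]
  s_idx <- match(spokes, colnames(cm)); h_idx <- match(hub, colnames(cm))
  r2 <- drop(cm[h_idx, s_idx] %*% solve(cm[s_idx, s_idx], cm[s_idx, h_idx]))
  ns <- structure(list(query_gene = hub, neighbors = spokes, method = "t"),
                  class = "neighbor_set")
  pve <- benchmark_neighborhood(em, ns, epochs = 300L, learning_rate = 1e-2)
  expect_equal(pve, r2, tolerance = 0.12)
})

test_that("ground-truth centrality separates hub from isolated queries", {
  net <- build_hub_spoke_network(n_communities = 1L, community_size = 8L,
                                 n_isolated = 4L)
  cm <- network_to_covariance(net)
  em <- sample_cells(cm, n_cells = 800L, seed = 37L)
  x <- center_scale(em)
  hub <- net$gene_ids[net$is_hub][1]
  iso <- net$gene_ids[net$community < 0][1]
  ct <- ground_truth_centrality(x, c(hub, iso), hidden = c(8L, 8L),
                                epochs = 150L, learning_rate = 1e-2)
  expect_gt(ct$score[1], ct$score[2])
  # closed form: hub explains r^2 = 0.36 of each spoke, 0 of isolated genes
  r2_expected <- (7 * 0.36 + 4 * 0) / 11
  expect_equal(ct$score[1], r2_expected, tolerance = 0.1)
  expect_lt(abs(ct$score[2]), 0.05)
})

test_that("the generative neighbor route recovers a hub's spokes", {
  fit <- gcn_fit(2L)
  net <- gcn_fixture()$net
  cent <- sivae_degree_centrality(gcn_embedding(2L))
  # pick the best-reconstructed hub: its community is captured by the model
  hubs <- net$gene_ids[net$is_hub]
  hub <- hubs[which.max(cent$score[match(hubs, net$gene_ids)])]
  ns <- sivae_gcn_neighbors(fit, hub, k = 20L, seed = 5L)
  truth <- neighbors_from_weights(net, hub, k = 20L)
  comm <- net$community[match(hub, net$gene_ids)]
  frac_same_comm <- mean(net$community[match(ns$neighbors, net$gene_ids)] ==
                           comm)
  expect_gt(frac_same_comm, 0.5)
  expect_length(ns$neighbors, 20L)
  expect_identical(ns$neighbors,
                   sivae_gcn_neighbors(fit, hub, k = 20L, seed = 5L)$neighbors)
})
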