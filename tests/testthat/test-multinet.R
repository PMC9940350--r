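test_that("cell binning discards the remainder and keeps bins disjoint", {
  bins <- bin_cells(2500L, bin_size = 1000L, seed = 3L)
  expect_length(bins, 2L)
  expect_equal(attr(bins, "discarded"), 500L)
  expect_length(unique(unlist(bins)), 2000L)
  expect_true(all(lengths(bins) == 1000L))

  one <- bin_cells(1000L, bin_size = 1000L)
  expect_length(one, 1L)
  expect_equal(attr(one, "discarded"), 0L)

  expect_warning(none <- bin_cells(700L, bin_size = 1000L), "no bins")
  expect_length(none, 0L)
})

test_that("mutual k-NN adjacency matches brute force and finds tight pairs", {
  mk <- function(l) structure(list(loadings = l,
                                   gene_ids = paste0("g", seq_len(nrow(l)))),
                              class = "sivae_embedding")
  # two tight pairs far apart: exactly those two edges at k_graph = 1
  l <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  net <- embeddings_to_adjacency(mk(l), k_graph = 1L)
  expect_equal(sum(net$weights) / 2, 2)
  expect_equal(net$weights[1, 2], 1)
  expect_equal(net$weights[3, 4], 1)
  expect_equal(net$weights, t(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 4))

  set.seed(91)
  l2 <- matrix(rnorm(40), 20, 2)
  got <- embeddings_to_adjacency(mk(l2), k_graph = 4L)$weights
  d <- as.matrix(dist(l2))
  want <- matrix(0, 20, 20)
  for (i in 1:20) {
    oi <- order(d[i, -i]); nbrs <- (1:20)[-i][oi[1:4]]
    for (j in nbrs) {
      oj <- order(d[j, -j]); nbj <- (1:20)[-j][oj[1:4]]
      if (i %in% nbj) want[i, j] <- 1
    }
  }
  expect_equal(unname(got), want)
  expect_error(embeddings_to_adjacency(mk(l2), k_graph = 20L), "smaller")
})

test_that("WL kernel: identity, hand-computed path-vs-triangle value, PSD", {
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  tri <- matrix(1, 3, 3) - diag(3)
  sim <- wl_similarity(list(path, path, tri), n_iterations = 1L,
                       init = "degree")
  expect_equal(sim[1, 2], 1)
  # by hand with raw-degree labels: iteration-0 histograms give <h_p, h_t> =
  # 2*0 + 1*3 = 3; refined labels share no signatures, so k(p,t) = 3,
  # k(p,p) = (4+1) + (4+1) = 10, k(t,t) = 9 + 9 = 18
  expect_equal(sim[1, 3], 3 / sqrt(10 * 18), tolerance = 1e-12)
  ev <- eigen(sim, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)

  # random instances: agreement with an independent WL re-implementation
  set.seed(97)
  graphs <- lapply(1:4, function(i) {
    w <- matrix(rbinom(900, 1, 0.15), 30, 30)
    w <- ((w + t(w)) > 0) * 1; diag(w) <- 0
    w
  })
  got <- wl_similarity(graphs, n_iterations = 2L, init = "degree")
  # brute force: explicit string labels, dense loops
  brute_labels <- lapply(graphs, function(g) as.character(rowSums(g)))
  hist_dot <- function(la, lb) {
    u <- union(la, lb)
    sum(tabulate(match(la, u), length(u)) * tabulate(match(lb, u), length(u)))
  }
  k <- matrix(0, 4, 4)
  labs <- brute_labels
  for (it in 0:2) {
    if (it > 0) {
      labs <- lapply(seq_along(graphs), function(g) {
        vapply(1:30, function(i) {
          nb <- which(graphs[[g]][i, ] != 0)
          paste0(labs[[g]][i], "(", paste(sort(labs[[g]][nb]),
                                          collapse = ";"), ")")
        }, character(1))
      })
    }
    for (a in 1:4) for (b in 1:4) k[a, b] <- k[a, b] +
        hist_dot(labs[[a]], labs[[b]])
  }
  want <- k / sqrt(outer(diag(k), diag(k)))
  expect_equal(unname(got), want, tolerance = 1e-12)
  expect_error(wl_similarity(list()), "at least one")
})

test_that("bin-level similarities average to population level", {
  sim <- matrix(c(1, .8, .2, .1,
                  .8, 1, .3, .2,
                  .2, .3, 1, .9,
                  .1, .2, .9, 1), 4, 4)
  b2p <- c("A", "A", "B", "B")
  got <- average_bin_similarity(sim, b2p)
  expect_equal(got["A", "B"], mean(sim[1:2, 3:4]))
  expect_equal(got["A", "A"], mean(sim[1:2, 1:2]))
  # one bin per population: unchanged
  single <- average_bin_similarity(sim, c("a", "b", "c", "d"))
  expect_equal(unname(single), unname(sim))
  # identical duplicate bins equal the single-bin value
  sim2 <- sim[c(1, 1, 3, 3), c(1, 1, 3, 3)]
  dup <- average_bin_similarity(sim2, c("A", "A", "B", "B"))
  expect_equal(dup["A", "B"], sim[1, 3])
  # invariance to bin ordering
  perm <- c(3, 1, 4, 2)
  got2 <- average_bin_similarity(sim[perm, perm], b2p[perm])
  expect_equal(got2[rownames(got), colnames(got)], got)
})

test_that("population embedding is deterministic and preserves block structure", {
  sim <- rbind(c(1, .9, .1, .1), c(.9, 1, .1, .1),
               c(.1, .1, 1, .9), c(.1, .1, .9, 1))
  rownames(sim) <- colnames(sim) <- paste0("p", 1:4)
  ke <- embed_populations(sim)
  co <- ke$pc_coordinates
  expect_lt(dist(co[1:2, 1, drop = FALSE]), dist(co[c(1, 3), 1, drop = FALSE]))
  # identical populations land on identical coordinates
  sim2 <- matrix(.5, 3, 3); diag(sim2) <- 1
  sim2[1, 2] <- sim2[2, 1] <- 1
  ke2 <- embed_populations(sim2)
  expect_equal(ke2$pc_coordinates[1, ], ke2$pc_coordinates[2, ],
               tolerance = 1e-10)
  # sign convention: largest-magnitude element positive
  expect_gte(max(co[, 1]), abs(min(co[, 1])))
})

test_that("centrality-phenotype association: monotone genes and BH step-up", {
  ph <- 1:8
  cent <- cbind(mono = 1:8, anti = 8:1, flat = rep(1, 8),
                noise = c(3, 1, 4, 1, 5, 9, 2, 6))
  res <- centrality_phenotype_association(cent, ph)
  expect_equal(res$rho[1], 1)
  expect_equal(res$rho[2], -1)
  expect_true(is.na(res$rho[3]))
  # reported adjusted p-values follow the BH step-up algebra
  p <- res$p_value[!is.na(res$p_value)]
  m <- length(p)
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(res$p_adjusted[!is.na(res$p_value)], pmin(stepup, 1))
  expect_error(centrality_phenotype_association(cent[1:4, ], ph[1:4]),
               "at least 5")
})

test_that("edge-phenotype tests match exact rank-sum enumeration", {
  # six populations; one edge present in exactly the high-phenotype half
  f <- 3L
  mk <- function(has_edge) {
    w <- matrix(0, f, f)
    if (has_edge) { w[1, 2] <- w[2, 1] <- 1 }
    w[1, 3] <- w[3, 1] <- 1       # background edge present everywhere
    gene_network(w, gene_ids = c("a", "b", "c"))
  }
  nets <- lapply(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), mk)
  res <- edge_phenotype_test(nets, phenotype = c(1, 2, 3, 4, 5, 6))
  row_ab <- res[res$gene_a == "a" & res$gene_b == "b", ]
  # exact two-sided p for {4,5,6} vs {1,2,3}: U = 9 (maximal), p = 2*(1/20)
  expect_equal(row_ab$p_value, 0.1)
  row_ac <- res[res$gene_a == "a" & res$gene_b == "c", ]
  expect_true(row_ac$skipped)                # present in all -> untestable

  # group mode with identical groups: p = 1
  gr <- rep(c("x", "y"), each = 3)
  nets_same <- lapply(rep(TRUE, 6), mk)
  res2 <- edge_phenotype_test(lapply(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                                     mk), groups = gr)
  row2 <- res2[res2$gene_a == "a" & res2$gene_b == "b", ]
  expect_equal(row2$p_value, 1)

  # exhaustive U enumeration for a small two-group comparison
  stat_g1 <- c(0, 0, 0, 1); stat_g2 <- c(1, 1, 1, 1)
  nets3 <- lapply(c(stat_g1, stat_g2) == 1, mk)
  res3 <- edge_phenotype_test(nets3, groups = rep(c("x", "y"), each = 4))
  row3 <- res3[res3$gene_a == "a" & res3$gene_b == "b", ]
  wt <- suppressWarnings(stats::wilcox.test(stat_g1, stat_g2))
  expect_equal(row3$p_value, wt$p.value)
  expect_error(edge_phenotype_test(nets3), "exactly one")
})

test_that("group edge consensus respects the inclusive threshold", {
  f <- 2L
  mk <- function(has) {
    w <- matrix(0, f, f); if (has) w[1, 2] <- w[2, 1] <- 1
    gene_network(w, gene_ids = c("a", "b"))
  }
  nets <- lapply(c(rep(TRUE, 2), rep(FALSE, 8)), mk)
  groups <- rep("g1", 10)
  out <- summarize_group_edges(nets, groups, min_frac = 0.2)
  expect_equal(out$g1$weights[1, 2], 1)      # 2/10 kept (boundary inclusive)
  nets1 <- lapply(c(TRUE, rep(FALSE, 9)), mk)
  out1 <- summarize_group_edges(nets1, groups, min_frac = 0.2)
  expect_equal(out1$g1$weights[1, 2], 0)     # 1/10 dropped
  out0 <- summarize_group_edges(nets1, groups, min_frac = 0)
  expect_equal(out0$g1$weights[1, 2], 1)     # union
})
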