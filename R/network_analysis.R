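# Degree centrality, neighbor identification and neighborhood benchmarking.
# All rankings break ties by ascending original gene index.

centrality_result <- function(gene_ids, score, method) {
  stopifnot(length(gene_ids) == length(score))
  structure(list(gene_ids = gene_ids, score = as.numeric(score),
                 method = method),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("centrality (", x$method, "): ", length(x$score), " genes, top: ",
      paste(x$gene_ids[order(-x$score)[1:min(5, length(x$score))]],
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

neighbor_set <- function(query_gene, neighbors, method,
                         low_confidence = FALSE) {
  if (query_gene %in% neighbors) stop("query must not be in its neighbors")
  if (anyDuplicated(neighbors)) stop("duplicate neighbors")
  structure(list(query_gene = query_gene, neighbors = neighbors,
                 method = method, low_confidence = low_confidence),
            class = "neighbor_set")
}

#' Degree centrality from the fitted embedding
#'
#' Genes whose expression pattern the model reconstructs well are the genes
#' whose patterns predict many others — the hubs — so centrality is defined
#' as the negative per-gene reconstruction error.
#'
#' @param embedding A \code{sivae_embedding} from [extract_embeddings()].
#' @return A \code{centrality_result} (higher score = more central).
#' @export
sivae_degree_centrality <- function(embedding) {
  stopifnot(inherits(embedding, "sivae_embedding"))
  centrality_result(embedding$gene_ids, -embedding$per_gene_recon_error,
                    "sivae")
}

#' Degree centrality from a weighted network
#'
#' The mean of the weights between the query gene and every other gene.
#'
#' @param net A [gene_network()].
#' @return A \code{centrality_result}.
#' @export
gcn_degree_centrality <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  f <- nrow(net$weights)
  score <- (rowSums(net$weights) - diag(net$weights)) / (f - 1)
  centrality_result(net$gene_ids, score, "gcn_mean_weight")
}

#' Ground-truth degree centrality by single-gene prediction
#'
#' For each query gene, trains a network from that single gene to all other
#' genes and averages the per-target percentage of variance explained,
#' \eqn{1 - Var(X_{:,g} - \hat X_{:,g}) / Var(X_{:,g})}. Well-connected genes
#' explain much of the rest of the transcriptome; isolated genes explain
#' none.
#'
#' @param x Centered/scaled expression matrix (cells x genes) or
#'   [expression_matrix()].
#' @param query_genes Character vector of query gene identifiers.
#' @param hidden Hidden-layer widths of the predictor network.
#' @param epochs,learning_rate,seed Training settings.
#' @return A \code{centrality_result} over the query genes.
#' @export
ground_truth_centrality <- function(x, query_genes,
                                    hidden = c(128L, 512L, 1024L),
                                    epochs = 200L, learning_rate = 1e-3,
                                    seed = 1L) {
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  v <- em$values
  bad <- apply(v, 2L, stats::var) == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " zero-variance target gene(s)")
  }
  scores <- vapply(query_genes, function(q) {
    qi <- match(q, em$gene_ids)
    if (is.na(qi)) stop("unknown query gene: ", q)
    targets <- setdiff(which(!bad), qi)
    net <- fit_mlp_regressor(v[, qi, drop = FALSE],
                             v[, targets, drop = FALSE],
                             hidden = hidden, epochs = epochs,
                             learning_rate = learning_rate, seed = seed)
    pred <- predict(net, v[, qi, drop = FALSE])
    pve <- 1 - apply(v[, targets, drop = FALSE] - pred, 2L, stats::var) /
      apply(v[, targets, drop = FALSE], 2L, stats::var)
    mean(pve)
  }, numeric(1))
  centrality_result(query_genes, scores, "ground_truth")
}

#' Nearest genes in the feature-embedding space
#'
#' The k genes with the smallest Euclidean distance to the query gene's
#' loading vector, in ascending distance order (distance ties broken by lower
#' gene index).
#'
#' @param embedding A \code{sivae_embedding}.
#' @param query Query gene identifier.
#' @param k Number of neighbors (default 20).
#' @return A \code{neighbor_set}.
#' @export
neighbors_euclidean <- function(embedding, query, k = 20L) {
  stopifnot(inherits(embedding, "sivae_embedding"))
  qi <- match(query, embedding$gene_ids)
  if (is.na(qi)) stop("unknown query gene: ", query)
  v <- embedding$loadings
  if (k >= nrow(v)) stop("k must be smaller than the number of genes")
  d <- sqrt(rowSums(sweep(v, 2L, v[qi, ])^2))
  ord <- order(d)                      # stable: index tie-break
  ord <- ord[ord != qi][seq_len(k)]
  neighbor_set(query, embedding$gene_ids[ord], "sivae_euc")
}

#' Nearest genes by network weight
#'
#' The k genes with the largest pairwise weight to the query, in descending
#' weight order (ties broken by lower gene index). If the query has no
#' positive-weight neighbors, the set is flagged low-confidence.
#'
#' @param net A [gene_network()].
#' @param query Query gene identifier.
#' @param k Number of neighbors (default 20).
#' @return A \code{neighbor_set}.
#' @export
neighbors_from_weights <- function(net, query, k = 20L) {
  stopifnot(inherits(net, "gene_network"))
  qi <- match(query, net$gene_ids)
  if (is.na(qi)) stop("unknown query gene: ", query)
  w <- net$weights[qi, ]
  if (k >= length(w)) stop("k must be smaller than the number of genes")
  ord <- order(-w)
  ord <- ord[ord != qi][seq_len(k)]
  neighbor_set(query, net$gene_ids[ord], "gcn_weights",
               low_confidence = all(w[ord] == 0))
}

#' Absolute-correlation adjacency
#'
#' A simple co-expression network: edge weight is the absolute Pearson
#' correlation between the two genes' expression (zero diagonal). Serves as
#' the built-in inference method for the generative route to network
#' neighbors.
#'
#' @param x Expression matrix (cells x genes) or [expression_matrix()];
#'   at least 3 cells.
#' @return A [gene_network()] with weights in [0, 1].
#' @export
correlation_adjacency <- function(x) {
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  v <- em$values
  if (nrow(v) < 3L) stop("need at least 3 cells")
  sds <- apply(v, 2L, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s); their weights set to 0")
  }
  w <- suppressWarnings(abs(stats::cor(v)))
  w[zero, ] <- 0
  w[, zero] <- 0
  diag(w) <- 0
  w[is.na(w)] <- 0
  gene_network(w, gene_ids = em$gene_ids)
}

#' Network neighbors via the generative route
#'
#' Samples a dataset from the trained model matching the training size, runs
#' a co-expression inference function on the sample, and reads the query's
#' neighbors off the inferred network.
#'
#' @param fit A trained \code{sivae_fit}.
#' @param query Query gene identifier.
#' @param k Number of neighbors.
#' @param infer Function mapping an expression matrix to a
#'   [gene_network()]; defaults to [correlation_adjacency()].
#' @param n_cells Sample size (defaults to the training size).
#' @param seed Sampling seed.
#' @return A \code{neighbor_set}.
#' @export
sivae_gcn_neighbors <- function(fit, query, k = 20L,
                                infer = correlation_adjacency,
                                n_cells = NULL, seed = 1L) {
  stopifnot(inherits(fit, "sivae_fit"))
  if (is.null(n_cells)) n_cells <- fit$x_dim[1L]
  xs <- sample_from_model(fit, n_cells, seed = seed)
  net <- infer(xs)
  ns <- neighbors_from_weights(net, query, k = k)
  ns$method <- "sivae_gcn"
  ns
}

#' Benchmark a gene neighborhood by predicting the query gene
#'
#' Trains a small network from the k neighbor genes to the query gene and
#' returns the percentage of the query's expression variance explained
#' (negative values are reported as-is for bad fits).
#'
#' @param x Expression matrix (cells x genes) or [expression_matrix()].
#' @param ns A \code{neighbor_set}.
#' @param hidden Hidden widths of the predictor (default 16-8-4).
#' @param epochs,learning_rate,seed Training settings.
#' @return Fraction of variance explained (scale 0-1).
#' @export
benchmark_neighborhood <- function(x, ns, hidden = c(16L, 8L, 4L),
                                   epochs = 200L, learning_rate = 1e-3,
                                   seed = 1L) {
  stopifnot(inherits(ns, "neighbor_set"))
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  if (ns$query_gene %in% ns$neighbors) stop("query gene among neighbors")
  qi <- match(ns$query_gene, em$gene_ids)
  nidx <- match(ns$neighbors, em$gene_ids)
  if (anyNA(c(qi, nidx))) stop("gene identifiers not found in data")
  xq <- em$values[, qi]
  xn <- em$values[, nidx, drop = FALSE]
  net <- fit_mlp_regressor(xn, xq, hidden = hidden, epochs = epochs,
                           learning_rate = learning_rate, seed = seed)
  pred <- as.numeric(predict(net, xn))
  1 - stats::var(xq - pred) / stats::var(xq)
}

#' Query genes considered central by every method
#'
#' The intersection of each method's top-n genes by centrality score
#' (descending, ties broken by lower gene index).
#'
#' @param centralities List of \code{centrality_result}s on the same gene
#'   universe.
#' @param top_n Number of top genes per method (default 500).
#' @return Character vector of gene identifiers (in gene-universe order).
#' @export
select_query_genes <- function(centralities, top_n = 500L) {
  stopifnot(length(centralities) >= 2L)
  ids <- centralities[[1L]]$gene_ids
  for (ct in centralities) {
    if (!identical(ct$gene_ids, ids)) stop("mismatched gene universes")
  }
  tops <- lapply(centralities, function(ct) {
    ids[order(-ct$score)[seq_len(min(top_n, length(ids)))]]
  })
  out <- Reduce(intersect, tops)
  ids[ids %in% out]
}

#' Percentage overlap of two neighbor sets
#'
#' @param a,b \code{neighbor_set}s with the same k.
#' @return Overlap percentage in [0, 100].
#' @export
neighborhood_overlap <- function(a, b) {
  stopifnot(inherits(a, "neighbor_set"), inherits(b, "neighbor_set"))
  if (length(a$neighbors) != length(b$neighbors)) {
    stop("neighbor sets must have the same k")
  }
  100 * length(intersect(a$neighbors, b$neighbors)) / length(a$neighbors)
}

#' Mean pairwise expression correlation between two neighbor sets
#'
#' The mean over all k x k Pearson correlations between members of the two
#' sets (400 values at the default k = 20); pairs involving a zero-variance
#' gene are excluded with a warning.
#'
#' @param x Expression matrix or [expression_matrix()].
#' @param a,b \code{neighbor_set}s for the same query gene.
#' @return Mean Pearson correlation.
#' @export
neighborhood_mean_correlation <- function(x, a, b) {
  stopifnot(inherits(a, "neighbor_set"), inherits(b, "neighbor_set"))
  if (!identical(a$query_gene, b$query_gene)) {
    stop("neighbor sets must share the query gene")
  }
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  ai <- match(a$neighbors, em$gene_ids)
  bi <- match(b$neighbors, em$gene_ids)
  if (anyNA(c(ai, bi))) stop("gene identifiers not found in data")
  cc <- suppressWarnings(stats::cor(em$values[, ai, drop = FALSE],
                                    em$values[, bi, drop = FALSE]))
  if (anyNA(cc)) {
    warning("excluding ", sum(is.na(cc)), " pair(s) with zero variance")
  }
  mean(cc, na.rm = TRUE)
}
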