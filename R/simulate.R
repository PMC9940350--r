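# Synthetic data generators: the hub-and-spoke gene co-expression network
# design (five 50-gene communities, each a hub connected to its 49 spokes
# with weight 0.6, plus 50 isolated genes; cells drawn from a multivariate
# Gaussian whose correlation realizes that graph) and a labeled multi-cluster
# fixture for classification tests.

#' Gene network container
#'
#' @param weights Symmetric gene x gene weight matrix with zero diagonal
#'   (0 = no edge).
#' @param gene_ids Gene identifiers.
#' @param is_hub Logical flag per gene (simulator ground truth).
#' @param community Integer community label per gene (-1 = isolated).
#' @return An object of class \code{"gene_network"}.
#' @export
gene_network <- function(weights, gene_ids = NULL, is_hub = NULL,
                         community = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("weights must have zero diagonal")
  f <- nrow(weights)
  if (is.null(gene_ids)) gene_ids <- rownames(weights) %||% paste0("gene", seq_len(f))
  if (is.null(is_hub)) is_hub <- rep(FALSE, f)
  if (is.null(community)) community <- rep(-1L, f)
  dimnames(weights) <- list(gene_ids, gene_ids)
  structure(list(weights = weights, gene_ids = gene_ids,
                 is_hub = is_hub, community = as.integer(community)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat("gene_network:", length(x$gene_ids), "genes,", ne, "edges,",
      sum(x$is_hub), "hubs\n")
  invisible(x)
}

#' Build the hub-and-spoke co-expression network
#'
#' Each community has one hub connected to every other community member with
#' the given edge weight; spokes are not connected to each other, there are
#' no inter-community edges, and isolated genes have no edges at all. The
#' default design (5 communities of 50 plus 50 isolated genes, weight 0.6)
#' yields 300 genes and 245 edges.
#'
#' @param n_communities Number of communities.
#' @param community_size Genes per community (>= 2).
#' @param n_isolated Number of isolated genes.
#' @param edge_weight Hub-spoke edge weight (the pairwise correlation the
#'   sampled data should show on each edge).
#' @return A [gene_network()] with \code{is_hub} and \code{community} set.
#' @export
build_hub_spoke_network <- function(n_communities = 5L, community_size = 50L,
                                    n_isolated = 50L, edge_weight = 0.6) {
  n_communities <- as.integer(n_communities)
  community_size <- as.integer(community_size)
  n_isolated <- as.integer(n_isolated)
  if (community_size < 2L) stop("community_size must be >= 2")
  if (n_communities < 1L) stop("n_communities must be >= 1")
  if (n_isolated < 0L) stop("n_isolated must be >= 0")
  f <- n_communities * community_size + n_isolated
  w <- matrix(0, f, f)
  is_hub <- rep(FALSE, f)
  community <- rep(-1L, f)
  for (k in seq_len(n_communities)) {
    idx <- ((k - 1L) * community_size + 1L):(k * community_size)
    hub <- idx[1L]
    is_hub[hub] <- TRUE
    community[idx] <- k
    w[hub, idx[-1L]] <- edge_weight
    w[idx[-1L], hub] <- edge_weight
  }
  ids <- character(f)
  ids[community > 0 & is_hub] <- paste0("hub", seq_len(n_communities))
  spoke <- which(community > 0 & !is_hub)
  ids[spoke] <- sprintf("c%d_spoke%d", community[spoke],
                        stats::ave(seq_along(spoke), community[spoke],
                                   FUN = seq_along))
  iso <- which(community < 0)
  ids[iso] <- paste0("iso", seq_along(iso))
  gene_network(w, gene_ids = ids, is_hub = is_hub, community = community)
}

#' Convert a hub-and-spoke network to a positive-definite covariance
#'
#' Builds the correlation matrix implied by the Gaussian graphical model with
#' the network's edge pattern: unit diagonal, the edge weight on every edge,
#' and hub-mediated correlations on non-adjacent within-community pairs
#' (spokes are conditionally independent given their hub, so two spokes each
#' correlated \eqn{r} with the hub correlate \eqn{r^2}). Isolated genes are
#' uncorrelated with everything. The result is eigenvalue-clipped to the
#' nearest positive-definite matrix and rescaled to unit diagonal (a no-op
#' for valid hub-and-spoke inputs, which are one-factor blocks and hence
#' already positive definite).
#'
#' @param net A [gene_network()].
#' @param eig_floor Minimum eigenvalue enforced by clipping.
#' @return A positive-definite covariance (= correlation) matrix.
#' @export
network_to_covariance <- function(net, eig_floor = 1e-6) {
  stopifnot(inherits(net, "gene_network"))
  w <- net$weights
  f <- nrow(w)
  cm <- diag(f)
  cm[w != 0] <- w[w != 0]
  # hub-mediated correlation between non-adjacent genes sharing a community
  for (k in unique(net$community[net$community > 0])) {
    idx <- which(net$community == k)
    hub <- idx[net$is_hub[idx]]
    spokes <- setdiff(idx, hub)
    if (length(hub) == 1L && length(spokes) > 1L) {
      r <- w[hub, spokes]
      cm[spokes, spokes] <- outer(r, r)
      cm[cbind(spokes, spokes)] <- 1
    }
  }
  eg <- eigen(cm, symmetric = TRUE)
  if (min(eg$values) < eig_floor) {
    vals <- pmax(eg$values, eig_floor)
    cm <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(cm))
    cm <- cm / outer(d, d)
    eg2 <- eigen(cm, symmetric = TRUE, only.values = TRUE)
    if (min(eg2$values) <= 0) {
      stop("positive-definite construction failed; min eigenvalue ",
           format(min(eg2$values)))
    }
  }
  dimnames(cm) <- list(net$gene_ids, net$gene_ids)
  cm
}

#' Sample cells from a multivariate Gaussian
#'
#' Draws \code{n_cells} i.i.d. rows from \eqn{N(0, \Sigma)} via the Cholesky
#' factor, deterministically for a given seed.
#'
#' @param cov Positive-definite covariance matrix (genes x genes).
#' @param n_cells Number of cells (default 5000, the simulation design's
#'   training size).
#' @param seed Integer seed.
#' @return An [expression_matrix()] of \code{n_cells} x \code{F} values.
#' @export
sample_cells <- function(cov, n_cells = 5000L, seed = 1L) {
  cov <- as.matrix(cov)
  ch <- tryCatch(chol(cov), error = function(e) {
    stop("covariance is not positive definite: ", conditionMessage(e))
  })
  n_cells <- as.integer(n_cells)
  set.seed(seed)
  z <- matrix(stats::rnorm(n_cells * nrow(cov)), n_cells, nrow(cov))
  x <- z %*% ch
  colnames(x) <- colnames(cov)
  expression_matrix(x, gene_ids = colnames(cov) %||%
                      paste0("gene", seq_len(ncol(cov))))
}

#' Simulate labeled cell clusters
#'
#' Gaussian clusters whose means are separated by a given distance in a
#' random low-dimensional subspace of gene space, with unit-variance noise;
#' a fixture for classification and embedding-quality tests.
#'
#' @param n_clusters Number of clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param n_genes Number of genes.
#' @param separation Euclidean distance scale between cluster means.
#' @param n_dims Dimension of the subspace carrying the cluster structure.
#' @param seed Integer seed.
#' @return An [expression_matrix()] with \code{cell_labels} set.
#' @export
simulate_clustered_cells <- function(n_clusters, cells_per_cluster, n_genes,
                                     separation, n_dims = 2L, seed = 1L) {
  stopifnot(n_clusters >= 1, cells_per_cluster >= 1, n_genes >= 1,
            separation >= 0)
  set.seed(seed)
  basis <- qr.Q(qr(matrix(stats::rnorm(n_genes * n_dims), n_genes, n_dims)))
  centers_low <- matrix(stats::rnorm(n_clusters * n_dims), n_clusters, n_dims)
  if (n_clusters > 1L) {
    # scale so the closest pair of cluster means is `separation` apart
    dmin <- min(stats::dist(centers_low))
    centers_low <- centers_low * (separation / max(dmin, 1e-8))
  } else {
    centers_low <- centers_low * 0
  }
  centers <- centers_low %*% t(basis)
  n <- n_clusters * cells_per_cluster
  labels <- rep(paste0("cluster", seq_len(n_clusters)),
                each = cells_per_cluster)
  x <- centers[rep(seq_len(n_clusters), each = cells_per_cluster), ,
               drop = FALSE] +
    matrix(stats::rnorm(n * n_genes), n, n_genes)
  expression_matrix(x, cell_labels = labels)
}
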