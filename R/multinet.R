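# Per-population network comparison: bin cells, derive a network per bin
# from the fitted gene embeddings, compare networks with a Weisfeiler-Lehman
# subtree kernel, embed populations by PCA of the averaged similarities, and
# test network features (centrality, edges) against phenotypes.

#' Split cells into equal-sized random bins
#'
#' Cells that cannot fill a complete bin are discarded (their count is
#' reported as an attribute and via message).
#'
#' @param n_cells Total number of cells, or a matrix /
#'   [expression_matrix()] whose rows are cells.
#' @param bin_size Bin size (default 1000).
#' @param seed Integer seed for the random assignment.
#' @return List of disjoint index vectors, each of length \code{bin_size},
#'   with attribute \code{discarded}.
#' @export
bin_cells <- function(n_cells, bin_size = 1000L, seed = 1L) {
  if (!is.numeric(n_cells) || length(n_cells) > 1L) {
    n_cells <- nrow(as_values(n_cells))
  }
  n_cells <- as.integer(n_cells)
  bin_size <- as.integer(bin_size)
  n_bins <- n_cells %/% bin_size
  discarded <- n_cells - n_bins * bin_size
  if (n_bins == 0L) {
    warning("fewer cells (", n_cells, ") than bin_size (", bin_size,
            "); no bins formed")
    return(structure(list(), discarded = n_cells))
  }
  set.seed(seed)
  perm <- sample.int(n_cells)
  bins <- lapply(seq_len(n_bins), function(i) {
    sort(perm[((i - 1L) * bin_size + 1L):(i * bin_size)])
  })
  structure(bins, discarded = discarded)
}

#' Binary adjacency from gene embeddings by mutual k-nearest neighbors
#'
#' Two genes are connected iff each is among the other's \code{k_graph}
#' nearest neighbors in the loading space (Euclidean distance, index
#' tie-break); symmetric with zero diagonal.
#'
#' @param embedding A \code{sivae_embedding} (or any object with a
#'   \code{loadings} matrix and \code{gene_ids}).
#' @param k_graph Neighborhood size (default 10); must be < number of genes.
#' @return A [gene_network()] with binary weights.
#' @export
embeddings_to_adjacency <- function(embedding, k_graph = 10L) {
  v <- embedding$loadings
  f <- nrow(v)
  if (k_graph >= f) stop("k_graph must be smaller than the number of genes")
  d <- as.matrix(stats::dist(v))
  nn <- matrix(FALSE, f, f)
  for (i in seq_len(f)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i][seq_len(k_graph)]
    nn[i, ord] <- TRUE
  }
  w <- (nn & t(nn)) * 1
  diag(w) <- 0
  gene_network(w, gene_ids = embedding$gene_ids)
}

# WL label refinement shared across a list of graphs so compressed labels are
# comparable; returns per-graph label histograms per iteration
wl_histograms <- function(adjs, n_iterations, init_labels) {
  n_graphs <- length(adjs)
  labels <- init_labels                # list of integer vectors
  hists <- vector("list", n_iterations + 1L)
  relabel <- function(labs) {
    u <- sort(unique(unlist(labs)))
    lapply(labs, function(l) match(l, u))
  }
  labels <- relabel(labels)
  hist_of <- function(labs) {
    nl <- max(unlist(labs))
    lapply(labs, function(l) tabulate(l, nbins = nl))
  }
  hists[[1L]] <- hist_of(labels)
  neigh <- lapply(adjs, function(a) apply(a != 0, 1L, which, simplify = FALSE))
  for (it in seq_len(n_iterations)) {
    sigs <- vector("list", n_graphs)
    for (g in seq_len(n_graphs)) {
      lg <- labels[[g]]
      sigs[[g]] <- vapply(seq_along(lg), function(i) {
        nb <- neigh[[g]][[i]]
        paste(lg[i], paste(sort(lg[nb]), collapse = ","), sep = "|")
      }, character(1))
    }
    u <- sort(unique(unlist(sigs)))
    labels <- lapply(sigs, function(s) match(s, u))
    hists[[it + 1L]] <- hist_of(labels)
  }
  hists
}

#' Weisfeiler-Lehman subtree kernel similarity between networks
#'
#' Iteratively refines node labels (a node's new label is the hash of its own
#' label and the sorted multiset of its neighbors' labels), accumulates the
#' inner products of the label histograms over iterations 0..h, and
#' normalizes so self-similarity is 1. Initial labels are degree-quantile
#' bins computed on the pooled degree distribution so labels are comparable
#' across networks over a shared gene universe; \code{init = "degree"} uses
#' raw degrees instead.
#'
#' @param networks List of [gene_network()]s (or adjacency matrices) over a
#'   shared node set.
#' @param n_iterations Number of refinement iterations (default 3).
#' @param init Initial labeling: \code{"degree_quantile"} (default) or
#'   \code{"degree"}.
#' @param n_bins Number of quantile bins for the default labeling.
#' @return Symmetric positive semidefinite similarity matrix with unit
#'   diagonal.
#' @export
wl_similarity <- function(networks, n_iterations = 3L,
                          init = c("degree_quantile", "degree"),
                          n_bins = 5L) {
  init <- match.arg(init)
  if (length(networks) == 0L) stop("need at least one network")
  adjs <- lapply(networks, function(n) {
    w <- if (inherits(n, "gene_network")) n$weights else as.matrix(n)
    (w != 0) * 1
  })
  f <- nrow(adjs[[1L]])
  if (!all(vapply(adjs, nrow, 1L) == f)) stop("networks must share node set")
  degs <- lapply(adjs, rowSums)
  if (init == "degree") {
    init_labels <- lapply(degs, function(d) as.integer(d) + 1L)
  } else {
    pooled <- unlist(degs)
    br <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1L)))
    init_labels <- lapply(degs, function(d) {
      findInterval(d, br, rightmost.closed = TRUE, all.inside = TRUE)
    })
  }
  hists <- wl_histograms(adjs, n_iterations, init_labels)
  p <- length(adjs)
  k <- matrix(0, p, p)
  for (h in hists) {
    hm <- do.call(rbind, h)
    k <- k + hm %*% t(hm)
  }
  d <- sqrt(diag(k))
  d[d == 0] <- 1
  sim <- k / outer(d, d)
  nms <- names(networks) %||% paste0("network", seq_len(p))
  dimnames(sim) <- list(nms, nms)
  sim
}

#' Average bin-level similarities to population level
#'
#' Each population-pair entry is the mean of all bin-pair similarities
#' between the two populations' bins (within-population entries average the
#' corresponding bin block, diagonal included).
#'
#' @param sim Bin-level similarity matrix.
#' @param bin_to_population Vector (length = number of bins) mapping each bin
#'   to its population.
#' @return Population-level symmetric similarity matrix.
#' @export
average_bin_similarity <- function(sim, bin_to_population) {
  sim <- as.matrix(sim)
  stopifnot(nrow(sim) == length(bin_to_population))
  pops <- unique(bin_to_population)
  empty <- setdiff(pops, bin_to_population)
  if (length(empty)) {
    warning("excluding populations with zero bins: ",
            paste(empty, collapse = ", "))
    pops <- setdiff(pops, empty)
  }
  p <- length(pops)
  out <- matrix(0, p, p, dimnames = list(pops, pops))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      out[i, j] <- mean(sim[bin_to_population == pops[i],
                            bin_to_population == pops[j]])
    }
  }
  (out + t(out)) / 2
}

#' Embed populations from a similarity matrix
#'
#' PCA on the centered rows of the similarity matrix; the sign of each
#' component is fixed so its largest-magnitude element is positive.
#'
#' @param similarity Symmetric population similarity matrix.
#' @param d Number of principal coordinates (default 2).
#' @return An object of class \code{"kernel_embedding"} with the
#'   \code{similarity} matrix and \code{pc_coordinates} (P x d).
#' @export
embed_populations <- function(similarity, d = 2L) {
  similarity <- as.matrix(similarity)
  p <- nrow(similarity)
  d <- min(as.integer(d), p)
  pc <- stats::prcomp(similarity, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(d, ncol(pc$x))), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(similarity)
  structure(list(similarity = similarity, pc_coordinates = coords),
            class = "kernel_embedding")
}

#' @export
print.kernel_embedding <- function(x, ...) {
  cat("kernel embedding of", nrow(x$similarity), "populations,",
      ncol(x$pc_coordinates), "PCs\n")
  invisible(x)
}

#' Associate per-gene centrality with a population phenotype
#'
#' Two-sided Spearman correlation per gene between its centrality across
#' populations and the phenotype, with Benjamini-Hochberg adjustment across
#' genes. Genes with constant centrality get NA.
#'
#' @param centrality Matrix, populations x genes, of centrality scores.
#' @param phenotype Numeric phenotype per population (length P >= 5).
#' @return Data frame with \code{gene}, \code{rho}, \code{p_value},
#'   \code{p_adjusted}.
#' @export
centrality_phenotype_association <- function(centrality, phenotype) {
  centrality <- as.matrix(centrality)
  stopifnot(nrow(centrality) == length(phenotype))
  if (nrow(centrality) < 5L) stop("need at least 5 populations")
  genes <- colnames(centrality) %||% paste0("gene", seq_len(ncol(centrality)))
  res <- lapply(seq_len(ncol(centrality)), function(j) {
    v <- centrality[, j]
    if (stats::sd(v) == 0 || stats::sd(phenotype) == 0) {
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(v, phenotype, method = "spearman",
                      alternative = "two.sided", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  rho <- vapply(res, `[`, numeric(1), 1L)
  p <- vapply(res, `[`, numeric(1), 2L)
  data.frame(gene = genes, rho = rho, p_value = p,
             p_adjusted = stats::p.adjust(p, method = "BH"))
}

#' Test network edges against a phenotype or group labels
#'
#' Candidate edges are those present in at least one population and absent in
#' at least one (edges uniform across populations are skipped and flagged).
#' With \code{groups}, a two-sided Wilcoxon rank-sum test compares the
#' per-population edge statistic (the adjacency weight, or presence for
#' binary networks) between the two groups; with a continuous
#' \code{phenotype}, the phenotype values of populations carrying the edge
#' are rank-sum-tested against those lacking it. P-values are
#' Benjamini-Hochberg-adjusted across tested edges.
#'
#' @param adjacencies List of [gene_network()]s or adjacency matrices, one
#'   per population, over a shared gene set.
#' @param groups Optional two-level factor over populations.
#' @param phenotype Optional numeric phenotype over populations (exactly one
#'   of \code{groups} / \code{phenotype} must be given).
#' @return Data frame with one row per candidate edge: \code{gene_a},
#'   \code{gene_b}, \code{p_value}, \code{p_adjusted}, \code{skipped}.
#' @export
edge_phenotype_test <- function(adjacencies, groups = NULL, phenotype = NULL) {
  if (is.null(groups) == is.null(phenotype)) {
    stop("give exactly one of groups or phenotype")
  }
  ws <- lapply(adjacencies, function(n) {
    if (inherits(n, "gene_network")) n$weights else as.matrix(n)
  })
  f <- nrow(ws[[1L]])
  ids <- if (inherits(adjacencies[[1L]], "gene_network")) {
    adjacencies[[1L]]$gene_ids
  } else {
    rownames(ws[[1L]]) %||% paste0("gene", seq_len(f))
  }
  p <- length(ws)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
    if (min(table(groups)) < 2L) stop("need >= 2 populations per group")
    stopifnot(length(groups) == p)
  } else {
    stopifnot(length(phenotype) == p)
  }
  ut <- which(upper.tri(ws[[1L]]), arr.ind = TRUE)
  stat <- sapply(ws, function(w) w[ut])          # edges x populations
  present <- stat != 0
  n_present <- rowSums(present)
  candidate <- n_present > 0L & n_present < p
  res <- data.frame(
    gene_a = ids[ut[, 1L]], gene_b = ids[ut[, 2L]],
    n_present = n_present, p_value = NA_real_, skipped = !candidate
  )
  for (e in which(candidate)) {
    pv <- if (!is.null(groups)) {
      g1 <- stat[e, groups == levels(groups)[1L]]
      g2 <- stat[e, groups == levels(groups)[2L]]
      if (all(g1 == g1[1L]) && all(g2 == g2[1L]) && g1[1L] == g2[1L]) 1
      else suppressWarnings(stats::wilcox.test(g1, g2)$p.value)
    } else {
      suppressWarnings(
        stats::wilcox.test(phenotype[present[e, ]],
                           phenotype[!present[e, ]])$p.value)
    }
    res$p_value[e] <- pv
  }
  res$p_adjusted <- NA_real_
  tested <- !res$skipped & !is.na(res$p_value)
  res$p_adjusted[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res
}

#' Consensus networks per group
#'
#' Within each group, keeps an edge iff it is present in at least
#' \code{min_frac} of that group's networks (boundary inclusive).
#'
#' @param adjacencies List of binary [gene_network()]s or adjacency matrices.
#' @param groups Factor over populations.
#' @param min_frac Minimum presence fraction (default 0.2).
#' @return Named list of consensus [gene_network()]s, one per group level.
#' @export
summarize_group_edges <- function(adjacencies, groups, min_frac = 0.2) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == length(adjacencies))
  ws <- lapply(adjacencies, function(n) {
    w <- if (inherits(n, "gene_network")) n$weights else as.matrix(n)
    (w != 0) * 1
  })
  ids <- if (inherits(adjacencies[[1L]], "gene_network")) {
    adjacencies[[1L]]$gene_ids
  } else NULL
  out <- list()
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) == 0L) stop("empty group: ", lev)
    frac <- Reduce(`+`, ws[idx]) / length(idx)
    cons <- (frac >= min_frac) * 1
    diag(cons) <- 0
    out[[lev]] <- gene_network(cons, gene_ids = ids)
  }
  out
}
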