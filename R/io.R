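# Readers/writers for the standard interchange formats: MatrixMarket MTX with
# gene/cell TSVs, dense CSV, edge-list TSVs for networks, and TSV embeddings.

#' Read an expression matrix from MatrixMarket + metadata TSVs
#'
#' Expects the common genes-by-cells MTX orientation (transposed to cells x
#' genes on read); \code{genes_file} and \code{cells_file} are
#' one-identifier-per-line TSVs whose optional second column gives gene
#' symbols / cell labels.
#'
#' @param mtx_file Path to the .mtx file.
#' @param genes_file,cells_file Paths to the row/column metadata TSVs.
#' @return An [expression_matrix()].
#' @export
read_expression_mtx <- function(mtx_file, genes_file, cells_file) {
  m <- as.matrix(Matrix::readMM(mtx_file))
  genes <- utils::read.delim(genes_file, header = FALSE,
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_file, header = FALSE,
                             stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
    stop("metadata dimensions do not match the matrix")
  }
  expression_matrix(t(m), gene_ids = genes[[1L]], cell_ids = cells[[1L]],
                    cell_labels = if (ncol(cells) > 1L) cells[[2L]])
}

#' Write an expression matrix as MatrixMarket + metadata TSVs
#'
#' @param em An [expression_matrix()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_expression_mtx <- function(em, dir, prefix = "matrix") {
  stopifnot(inherits(em, "expression_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  genes <- file.path(dir, paste0(prefix, "_genes.tsv"))
  cells <- file.path(dir, paste0(prefix, "_cells.tsv"))
  Matrix::writeMM(Matrix::Matrix(t(em$values), sparse = TRUE), mtx)
  utils::write.table(data.frame(em$gene_ids), genes, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cdf <- if (is.null(em$cell_labels)) data.frame(em$cell_ids) else
    data.frame(em$cell_ids, em$cell_labels)
  utils::write.table(cdf, cells, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(mtx, genes, cells))
}

#' Write a gene network as edge-list + node TSVs
#'
#' @param net A [gene_network()].
#' @param edges_file Path for the edge list (gene_a, gene_b, weight).
#' @param nodes_file Optional path for the node table (gene, community,
#'   is_hub).
#' @return Invisibly, the edge-list path.
#' @export
write_network_tsv <- function(net, edges_file, nodes_file = NULL) {
  stopifnot(inherits(net, "gene_network"))
  ut <- which(upper.tri(net$weights) & net$weights != 0, arr.ind = TRUE)
  edges <- data.frame(gene_a = net$gene_ids[ut[, 1L]],
                      gene_b = net$gene_ids[ut[, 2L]],
                      weight = net$weights[ut])
  utils::write.table(edges, edges_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(nodes_file)) {
    utils::write.table(
      data.frame(gene = net$gene_ids, community = net$community,
                 is_hub = net$is_hub),
      nodes_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edges_file)
}

#' Read a gene network from edge-list + node TSVs
#'
#' @param edges_file Edge-list TSV written by [write_network_tsv()].
#' @param nodes_file Node-table TSV (gives the gene universe, community and
#'   hub annotation); without it the universe is the genes on edges.
#' @return A [gene_network()].
#' @export
read_network_tsv <- function(edges_file, nodes_file = NULL) {
  edges <- utils::read.delim(edges_file, stringsAsFactors = FALSE)
  if (!is.null(nodes_file)) {
    nodes <- utils::read.delim(nodes_file, stringsAsFactors = FALSE)
    ids <- nodes$gene
    community <- nodes$community
    is_hub <- nodes$is_hub
  } else {
    ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
    community <- NULL
    is_hub <- NULL
  }
  f <- length(ids)
  w <- matrix(0, f, f, dimnames = list(ids, ids))
  if (nrow(edges)) {
    w[cbind(edges$gene_a, edges$gene_b)] <- edges$weight
    w[cbind(edges$gene_b, edges$gene_a)] <- edges$weight
  }
  gene_network(w, gene_ids = ids, is_hub = is_hub, community = community)
}

#' Write scores or loadings as TSV with an identifier column
#'
#' @param mat Matrix (rows = cells or genes) with K columns.
#' @param ids Row identifiers.
#' @param file Output path.
#' @param id_col Name of the identifier column.
#' @return Invisibly, the path.
#' @export
write_embedding_tsv <- function(mat, ids, file, id_col = "id") {
  mat <- as.matrix(mat)
  df <- data.frame(ids, mat)
  colnames(df) <- c(id_col, paste0("dim", seq_len(ncol(mat))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
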