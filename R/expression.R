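#' Expression matrix container
#'
#' Lightweight container for a cells x genes matrix with identifiers and
#' optional cell labels / batch covariates. All modeling functions accept
#' either this container or a plain matrix.
#'
#' @param values Numeric matrix, cells x genes.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   column names or \code{gene1..geneF}).
#' @param cell_ids Character vector of cell identifiers.
#' @param cell_labels Optional per-cell labels (factor or character).
#' @param batch Optional per-cell batch covariate matrix (cells x b).
#' @return An object of class \code{"expression_matrix"}.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              cell_labels = NULL, batch = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values) %||% paste0("gene", seq_len(ncol(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values) %||% paste0("cell", seq_len(nrow(values)))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (length(gene_ids) != ncol(values)) stop("gene_ids length mismatch")
  if (length(cell_ids) != nrow(values)) stop("cell_ids length mismatch")
  if (!is.null(cell_labels) && length(cell_labels) != nrow(values)) {
    stop("cell_labels length mismatch")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_labels = cell_labels, batch = batch),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "cells x", ncol(x$values),
      "genes\n")
  if (!is.null(x$cell_labels)) {
    cat("  labels:", paste(utils::head(levels(as.factor(x$cell_labels)), 6L),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

as_values <- function(x) {
  if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
}

#' TP10K normalization
#'
#' Scales each cell's counts so the row sums to 10,000 transcripts, then (by
#' default) applies log1p. Cells with zero total counts are dropped with a
#' warning (or an error in strict mode).
#'
#' @param x Count matrix (cells x genes) or [expression_matrix()].
#' @param log1p Apply log1p after scaling (default TRUE).
#' @param strict Error (instead of dropping) on all-zero cells.
#' @return An \code{expression_matrix} of normalized values.
#' @export
tp10k_normalize <- function(x, log1p = TRUE, strict = FALSE) {
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  v <- em$values
  if (any(v < 0)) stop("counts must be non-negative")
  rs <- rowSums(v)
  zero <- rs == 0
  if (any(zero)) {
    if (strict) stop(sum(zero), " cell(s) with zero total counts")
    warning("dropping ", sum(zero), " cell(s) with zero total counts")
    v <- v[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  v <- v / rs * 1e4
  if (log1p) v <- log1p(v)
  expression_matrix(v,
                    gene_ids = em$gene_ids,
                    cell_ids = em$cell_ids[!zero],
                    cell_labels = if (!is.null(em$cell_labels))
                      em$cell_labels[!zero],
                    batch = if (!is.null(em$batch))
                      em$batch[!zero, , drop = FALSE])
}

#' Select highly variable genes
#'
#' Keeps the \code{n} genes with the highest variance across cells (original
#' gene order preserved; variance ties broken by lower original index).
#'
#' @param x Matrix or [expression_matrix()] of normalized values.
#' @param n Number of genes to keep.
#' @return An \code{expression_matrix} restricted to the selected genes.
#' @export
select_hvg <- function(x, n = 2000L) {
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  n <- as.integer(n)
  if (n > ncol(em$values)) stop("n exceeds the number of genes")
  v <- apply(em$values, 2L, stats::var)
  # order() is stable: ties resolve to the lower original index
  keep <- sort(order(-v)[seq_len(n)])
  expression_matrix(em$values[, keep, drop = FALSE],
                    gene_ids = em$gene_ids[keep],
                    cell_ids = em$cell_ids,
                    cell_labels = em$cell_labels,
                    batch = em$batch)
}

#' Center and scale genes
#'
#' Centers each gene to mean zero and scales to unit variance; zero-variance
#' genes become all-zero columns. Idempotent.
#'
#' @param x Matrix or [expression_matrix()].
#' @return An \code{expression_matrix} of standardized values.
#' @export
center_scale <- function(x) {
  em <- if (inherits(x, "expression_matrix")) x else expression_matrix(x)
  v <- em$values
  mu <- colMeans(v)
  sd <- apply(v, 2L, stats::sd)
  sd[sd == 0] <- Inf                      # constant genes -> zero columns
  v <- sweep(sweep(v, 2L, mu), 2L, sd, "/")
  expression_matrix(v, gene_ids = em$gene_ids, cell_ids = em$cell_ids,
                    cell_labels = em$cell_labels, batch = em$batch)
}
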