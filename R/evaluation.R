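# Cell-embedding quality evaluation and attribution-tensor summarization.

#' k-NN balanced accuracy of an embedding
#'
#' Classifies each test cell by majority vote over its k Euclidean nearest
#' training embeddings (neighbor ties broken by lower training index, vote
#' ties by smaller mean distance) and returns the mean of per-class recalls.
#' Classes absent from the test set are excluded from the mean with a
#' warning.
#'
#' @param train_z Training embeddings (n_train x K).
#' @param train_labels Training labels.
#' @param test_z Test embeddings.
#' @param test_labels Test labels.
#' @param k Number of neighbors (default 80; use ~15 for small datasets).
#' @return Balanced accuracy in [0, 1].
#' @export
knn_balanced_accuracy <- function(train_z, train_labels, test_z, test_labels,
                                  k = 80L) {
  train_z <- as.matrix(train_z); test_z <- as.matrix(test_z)
  train_labels <- as.character(train_labels)
  test_labels <- as.character(test_labels)
  k <- as.integer(k)
  if (k > nrow(train_z)) stop("k exceeds the number of training cells")
  pred <- knn_predict(train_z, train_labels, test_z, k)
  classes <- unique(train_labels)
  absent <- setdiff(classes, test_labels)
  if (length(absent)) {
    warning("class(es) absent from test set excluded from balanced accuracy: ",
            paste(absent, collapse = ", "))
  }
  recalls <- vapply(setdiff(classes, absent), function(cl) {
    idx <- test_labels == cl
    mean(pred[idx] == cl)
  }, numeric(1))
  mean(recalls)
}

knn_predict <- function(train_z, train_labels, test_z, k) {
  d2 <- outer(rowSums(test_z^2), rowSums(train_z^2), "+") -
    2 * test_z %*% t(train_z)
  vapply(seq_len(nrow(test_z)), function(i) {
    ord <- order(d2[i, ])[seq_len(k)]          # stable: index tie-break
    labs <- train_labels[ord]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) {
      md <- vapply(winners, function(w) mean(d2[i, ord[labs == w]]),
                   numeric(1))
      winners <- winners[which.min(md)]
    }
    winners[1L]
  }, character(1))
}

#' Stratified cross-validation of an embedding pipeline
#'
#' Splits cells into folds preserving class proportions; per fold, fits the
#' pipeline on the training folds, embeds the held-out cells with the fitted
#' encoder, and scores a k-NN classifier by balanced accuracy.
#'
#' @param x Expression matrix (cells x genes) or [expression_matrix()].
#' @param labels Cell labels (every class needs at least \code{n_folds}
#'   members).
#' @param pipeline Function \code{(x_train, labels_train)} returning an
#'   encoder function \code{(x_new) -> embedding matrix}.
#' @param n_folds Number of folds (default 5).
#' @param k k-NN neighborhood size.
#' @param seed Integer seed controlling fold assignment.
#' @return Numeric vector of per-fold balanced accuracies.
#' @export
stratified_cv <- function(x, labels, pipeline, n_folds = 5L, k = 15L,
                          seed = 1L) {
  v <- as_values(x)
  labels <- as.character(labels)
  stopifnot(nrow(v) == length(labels))
  tab <- table(labels)
  tiny <- names(tab)[tab < n_folds]
  if (length(tiny)) {
    stop("class(es) with fewer members than folds: ",
         paste(tiny, collapse = ", "))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    enc <- pipeline(v[tr, , drop = FALSE], labels[tr])
    ztr <- enc(v[tr, , drop = FALSE])
    zte <- enc(v[!tr, , drop = FALSE])
    knn_balanced_accuracy(ztr, labels[tr], zte, labels[!tr],
                          k = min(k, sum(tr)))
  }, numeric(1))
}

#' Summarize a per-cell attribution tensor into per-feature loadings
#'
#' For each embedding dimension d, takes the first principal-component
#' loadings of the features x cells attribution slice, giving one length-F
#' vector per dimension; columns are assembled into the F x D matrix U with
#' each component's sign fixed so its largest-magnitude element is positive.
#' Constant slices yield a zero column with a warning.
#'
#' @param s 3-d array, dimensions D (embedding dims) x F (features) x C
#'   (cells).
#' @return F x D matrix of summarized attributions (unit-norm columns).
#' @export
summarize_attributions <- function(s) {
  stopifnot(length(dim(s)) == 3L)
  d <- dim(s)[1L]
  f <- dim(s)[2L]
  u <- matrix(0, f, d)
  for (j in seq_len(d)) {
    slice <- s[j, , ]                      # F x C
    if (stats::sd(as.numeric(slice)) == 0) {
      warning("constant attribution slice for dimension ", j)
      next
    }
    # first PC of the cells-as-observations view: loadings over features
    pc <- stats::prcomp(t(slice), center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1L]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    u[, j] <- v
  }
  u
}

#' Compare two loading matrices by per-dimension Spearman correlation
#'
#' Loadings from different methods are sign-indeterminate, so by default the
#' two-sided Spearman correlation is computed between absolute values per
#' dimension; the median across dimensions is reported alongside.
#'
#' @param u1,u2 F x D loading matrices.
#' @param absolute Compare absolute values (default TRUE).
#' @return List with \code{rho} (per-dimension), \code{p_value} and
#'   \code{median_rho}.
#' @export
compare_loadings <- function(u1, u2, absolute = TRUE) {
  u1 <- as.matrix(u1); u2 <- as.matrix(u2)
  if (!all(dim(u1) == dim(u2))) stop("loading matrices must share dimensions")
  if (absolute) {
    u1 <- abs(u1); u2 <- abs(u2)
  }
  res <- lapply(seq_len(ncol(u1)), function(j) {
    ct <- suppressWarnings(
      stats::cor.test(u1[, j], u2[, j], method = "spearman",
                      alternative = "two.sided", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  rho <- vapply(res, `[`, numeric(1), 1L)
  list(rho = rho, p_value = vapply(res, `[`, numeric(1), 2L),
       median_rho = stats::median(rho))
}
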