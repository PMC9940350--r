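# Small feed-forward regressor trained by Adam on mean squared error; used
# by the ground-truth centrality estimator (one input node, wide hidden
# layers, all remaining genes as outputs) and the neighborhood benchmark
# (neighbor genes in, query gene out).

#' Fit a feed-forward regression network
#'
#' @param x Input matrix (observations x inputs).
#' @param y Target matrix (observations x outputs) or vector.
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param activation Hidden nonlinearity (\code{"tanh"}, \code{"softplus"}).
#' @param seed Integer seed for initialization and batching.
#' @return An object of class \code{"mlp_regressor"} with a \code{predict}
#'   method.
#' @export
fit_mlp_regressor <- function(x, y, hidden = c(16L, 8L, 4L), epochs = 200L,
                              learning_rate = 1e-3, batch_size = 128L,
                              activation = "tanh", seed = 1L) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  set.seed(seed)
  widths <- c(ncol(x), hidden, ncol(y))
  par <- list()
  for (i in seq_len(length(widths) - 1L)) {
    par <- new_layer(par, paste0("h", i), widths[i], widths[i + 1L])
  }
  n <- nrow(x)
  nm <- names(par)
  opt <- adam_new(learning_rate)
  bs <- min(batch_size, n)
  nlayer <- length(widths) - 1L
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (st in seq(1L, n, by = bs)) {
      idx <- perm[st:min(st + bs - 1L, n)]
      tape <- ad_tape()
      P <- wrap_pars(tape, par, nm)
      h <- ad_const(tape, x[idx, , drop = FALSE])
      for (i in seq_len(nlayer)) {
        h <- ad_affine(tape, h, P, paste0("h", i))
        if (i < nlayer) h <- ad_activation(tape, h, activation)
      }
      resid <- ad_sub(tape, ad_const(tape, y[idx, , drop = FALSE]), h)
      loss <- ad_scale(tape, ad_sum(tape, ad_square(tape, resid)),
                       1 / length(idx))
      ad_backward(tape, loss)
      par <- adam_step(opt, par, collect_grads(P, nm))
    }
  }
  structure(list(par = par, widths = widths, activation = activation),
            class = "mlp_regressor")
}

#' @export
predict.mlp_regressor <- function(object, newdata, ...) {
  h <- as.matrix(newdata)
  f <- act_fun(object$activation)
  nlayer <- length(object$widths) - 1L
  for (i in seq_len(nlayer)) {
    h <- plain_affine(h, object$par, paste0("h", i))
    if (i < nlayer) h <- f(h)
  }
  h
}
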