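# Model state: a flat named list of parameter matrices plus bookkeeping.
# Layer naming: cenc/fenc = cell/feature encoders, cdec/fdec = decoders,
# sdhead = observation variance (Gaussian) or inverse-dispersion (NB) head,
# mu_s/J = batch-correction projection and per-feature batch weights,
# lib.* = amortized library-size posterior head (NB only).

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

new_layer <- function(par, name, n_in, n_out) {
  par[[paste0(name, ".W")]] <- glorot(n_in, n_out)
  par[[paste0(name, ".b")]] <- matrix(0, 1L, n_out)
  par
}

encoder_layers <- function(par, prefix, n_in, widths, K) {
  for (i in seq_along(widths)) {
    par <- new_layer(par, sprintf("%s.h%d", prefix, i), n_in, widths[i])
    n_in <- widths[i]
  }
  par <- new_layer(par, paste0(prefix, ".mean"), n_in, K)
  par <- new_layer(par, paste0(prefix, ".sd"), n_in, K)
  par
}

decoder_layers <- function(par, prefix, K, widths) {
  n_in <- K
  for (i in seq_along(widths)) {
    par <- new_layer(par, sprintf("%s.h%d", prefix, i), n_in, widths[i])
    n_in <- widths[i]
  }
  par
}

#' Initialize model parameters
#'
#' Builds the four networks (cell-wise and feature-wise encoder and decoder),
#' the observation heads, and — when configured — the batch-correction and
#' library-size heads, with seeded Glorot-uniform weights and zero biases.
#'
#' @param config A [sivae_config()].
#' @param n_features Number of genes \code{F}.
#' @param c_red Length of the reduced per-gene input to the feature-wise
#'   encoder (defaults to \code{config$c_red}, which must then be set).
#' @return An object of class \code{"sivae_model"}.
#' @export
sivae_init <- function(config, n_features, c_red = config$c_red) {
  stopifnot(inherits(config, "sivae_config"))
  n_features <- as.integer(n_features)
  if (n_features < 1L) stop("n_features must be positive")
  if (is.null(c_red)) stop("c_red must be given (in config or as argument)")
  c_red <- as.integer(c_red)
  K <- config$n_latent
  ew <- config$encoder_widths
  dw <- config$decoder_widths
  d_last <- if (length(dw)) dw[length(dw)] else K

  set.seed(config$seed)
  par <- list()
  par <- encoder_layers(par, "cenc", n_features + config$n_batch, ew, K)
  par <- encoder_layers(par, "fenc", c_red, ew, K)
  par <- decoder_layers(par, "cdec", K, dw)
  par <- decoder_layers(par, "fdec", K, dw)
  sd_in <- if (config$observation_model == "linear") K else d_last
  sd_out <- if (config$sd_mode == "per_feature") n_features else 1L
  par <- new_layer(par, "sdhead", sd_in, sd_out)
  if (config$n_batch > 0L) {
    if (length(dw) == 0L) stop("batch correction needs a decoder hidden layer")
    par <- new_layer(par, "mu_s", config$n_batch, dw[1L])
    par$J <- matrix(0, n_features, config$n_batch)
  }
  if (config$observation_model == "nb") {
    last_ew <- ew[length(ew)]
    par <- new_layer(par, "lib.mean", last_ew, 1L)
    par <- new_layer(par, "lib.sd", last_ew, 1L)
  }

  structure(list(
    config = config,
    par = par,
    n_features = n_features,
    c_red = c_red,
    d_last = d_last,
    l_mu = 0,
    l_sd = 1,
    trained = FALSE
  ), class = "sivae_model")
}

#' @export
print.sivae_model <- function(x, ...) {
  cat("sivae model:", x$n_features, "features, K =", x$config$n_latent,
      ", observation:", x$config$observation_model, "\n")
  cat("  reduced feature input length:", x$c_red, "\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

## -- plain (non-differentiated) forward passes -------------------------------

act_fun <- function(act) {
  switch(act,
    tanh = tanh,
    softplus = function(x) pmax(x, 0) + log1p(exp(-abs(x))),
    identity = identity,
    stop("unknown activation: ", act)
  )
}

plain_affine <- function(x, par, name) {
  sweep(x %*% par[[paste0(name, ".W")]], 2L,
        as.numeric(par[[paste0(name, ".b")]]), "+")
}

plain_encoder_hidden <- function(x, par, prefix, widths, act) {
  f <- act_fun(act)
  for (i in seq_along(widths)) {
    x <- f(plain_affine(x, par, sprintf("%s.h%d", prefix, i)))
  }
  x
}

softplus_floor <- function(x, floor = 1e-4) {
  pmax(x, 0) + log1p(exp(-abs(x))) + floor
}

plain_encode <- function(model, x, prefix) {
  cfg <- model$config
  h <- plain_encoder_hidden(x, model$par, prefix, cfg$encoder_widths,
                            cfg$activation)
  list(
    mean = plain_affine(h, model$par, paste0(prefix, ".mean")),
    sd = softplus_floor(plain_affine(h, model$par, paste0(prefix, ".sd"))),
    hidden = h
  )
}

# decoder: tanh (or configured activation) on all hidden layers except the
# terminal one, which is affine so decoded activations carry both signs and
# the bilinear mean is unrestricted in sign.
plain_decoder <- function(z, model, prefix, s = NULL) {
  cfg <- model$config
  dw <- cfg$decoder_widths
  if (length(dw) == 0L) return(z)
  f <- act_fun(cfg$activation)
  for (i in seq_along(dw)) {
    z <- plain_affine(z, model$par, sprintf("%s.h%d", prefix, i))
    if (i == 1L && !is.null(s) && prefix == "cdec") {
      z <- z + plain_affine(s, model$par, "mu_s")
    }
    if (i < length(dw)) z <- f(z)
  }
  z
}

#' Encode cells into the cell-embedding space
#'
#' Runs the cell-wise encoder on rows of the expression matrix and returns the
#' Gaussian approximate posterior over each cell's latent embedding.
#'
#' @param model A \code{sivae_model}.
#' @param x Matrix of cell measurements, one row per cell, \code{F} columns
#'   (plus the batch covariates appended as extra columns when the model was
#'   configured with \code{n_batch > 0}).
#' @return List with \code{mean} and \code{sd}, both \code{C x K}; \code{sd}
#'   is strictly positive.
#' @export
encode_cells <- function(model, x) {
  x <- as.matrix(x)
  want <- model$n_features + model$config$n_batch
  if (ncol(x) != want) {
    stop(sprintf("cell rows must have length %d, got %d", want, ncol(x)))
  }
  out <- plain_encode(model, x, "cenc")
  out[c("mean", "sd")]
}

#' Encode genes into the feature-embedding space
#'
#' Runs the feature-wise encoder on reduced per-gene profiles (one gene's
#' values across the reduced cell dimension) and returns the Gaussian
#' approximate posterior over each gene's latent loading.
#'
#' @param model A \code{sivae_model}.
#' @param x Matrix with one row per gene and \code{c_red} columns.
#' @return List with \code{mean} and \code{sd}, both \code{F x K}.
#' @export
encode_features <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$c_red) {
    stop(sprintf("feature rows must have length %d, got %d",
                 model$c_red, ncol(x)))
  }
  out <- plain_encode(model, x, "fenc")
  out[c("mean", "sd")]
}

#' Decode latent embeddings into predicted expression
#'
#' Pushes cell embeddings and feature embeddings through their respective
#' decoders and combines them by dot product into the predicted mean
#' (cells x genes), with the observation standard deviation from the variance
#' head. Under the linear observation model the decoders are bypassed and the
#' mean is the latent dot product itself.
#'
#' @param model A \code{sivae_model}.
#' @param z1 Cell embeddings, \code{C x K}.
#' @param v1 Feature embeddings, \code{G x K} (any subset of genes).
#' @param s Optional batch covariates, \code{C x b}.
#' @return List with \code{mean} (\code{C x G}) and \code{sd} (\code{C x F}
#'   or \code{C x 1} depending on \code{sd_mode}).
#' @export
decode <- function(model, z1, v1, s = NULL) {
  z1 <- as.matrix(z1); v1 <- as.matrix(v1)
  K <- model$config$n_latent
  if (ncol(z1) != K || ncol(v1) != K) {
    stop(sprintf("z1 and v1 must have K = %d columns", K))
  }
  if (!is.null(s) && model$config$n_batch == 0L) {
    stop("model has no batch covariates")
  }
  if (model$config$observation_model == "linear") {
    mean <- z1 %*% t(v1)
    sd <- softplus_floor(plain_affine(z1, model$par, "sdhead"))
  } else {
    zL <- plain_decoder(z1, model, "cdec", s = s)
    vL <- plain_decoder(v1, model, "fdec")
    mean <- zL %*% t(vL)
    sd <- softplus_floor(plain_affine(zL, model$par, "sdhead"))
  }
  list(mean = mean, sd = sd)
}
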