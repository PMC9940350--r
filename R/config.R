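#' Model configuration
#'
#' Collects every hyperparameter of the interpretable VAE: the latent
#' dimension shared by the cell-embedding and feature-embedding spaces, the
#' encoder/decoder architectures, the weight of the interpretability term, the
#' observation model, and optimization settings.
#'
#' @param n_latent Latent dimension \code{K} shared by scores and loadings.
#'   2 is typical for visualization; larger values (e.g. 64) for network
#'   analyses.
#' @param encoder_widths Integer vector of encoder hidden-layer widths,
#'   applied to both the cell-wise and feature-wise encoders.
#' @param decoder_widths Integer vector of decoder hidden-layer widths,
#'   applied to both decoders; the last width is the dimension in which the
#'   decoded cell and feature activations are combined by dot product. May be
#'   empty, in which case the decoders are the identity and the dot product
#'   acts on the latent vectors directly.
#' @param gamma Non-negative weight of the interpretability term, which pushes
#'   the latent dot product \eqn{v_{f,1}^T z_{c,1}} toward the observed data.
#'   Default 0.05, small enough not to dominate the reconstruction term.
#' @param observation_model One of \code{"gaussian"} (centered/scaled
#'   log-normalized input), \code{"nb"} (raw counts, negative binomial
#'   likelihood) or \code{"linear"} (Gaussian likelihood on the latent dot
#'   product itself; no separate interpretability term).
#' @param learning_rate Adam learning rate; the supported grid is
#'   1e-2, 1e-3, 1e-4.
#' @param l2_scale L2 regularization scale on network weights (not biases).
#' @param c_red Number of reduced input dimensions for the feature-wise
#'   encoder (its raw input is one gene's profile across all cells, length
#'   \code{C}). \code{NULL} means \code{min(C, 2000)} at fit time.
#' @param reduction_method \code{"pca"} (principal-component scores of the
#'   transposed data, no whitening) or \code{"downsample"} (stratified cell
#'   subsample; requires cell labels).
#' @param n_batch Number of batch covariates (0 = no batch correction).
#' @param activation Hidden-layer nonlinearity: \code{"tanh"} (default),
#'   \code{"softplus"} or \code{"identity"}. The decoders' terminal layer and
#'   all distribution heads are affine regardless.
#' @param sd_mode \code{"per_feature"}: the decoder variance head emits one
#'   standard deviation per gene per cell; \code{"scalar"}: one per cell.
#' @param epochs Length-3 integer vector: epochs for the cell-wise
#'   pre-training, feature-wise pre-training, and joint training steps.
#' @param kl_warmup Number of initial cell-pre-training epochs over which the
#'   KL weight ramps linearly from near 0 to 1 (guards against posterior
#'   collapse; 0 disables the warm-up).
#' @param batch_cells,batch_features Minibatch sizes over cells and features;
#'   per-step sums are rescaled to full-data scale.
#' @param seed Integer seed controlling initialization and training noise.
#'
#' @return An object of class \code{"sivae_config"}.
#' @export
sivae_config <- function(n_latent = 2L,
                         encoder_widths = c(1024L, 512L, 128L),
                         decoder_widths = rev(encoder_widths),
                         gamma = 0.05,
                         observation_model = c("gaussian", "nb", "linear"),
                         learning_rate = 1e-3,
                         l2_scale = 1e-3,
                         c_red = NULL,
                         reduction_method = c("pca", "downsample"),
                         n_batch = 0L,
                         activation = "tanh",
                         sd_mode = c("per_feature", "scalar"),
                         epochs = c(100L, 100L, 100L),
                         kl_warmup = 10L,
                         batch_cells = 128L,
                         batch_features = 256L,
                         seed = 1L) {
  observation_model <- match.arg(observation_model)
  reduction_method <- match.arg(reduction_method)
  sd_mode <- match.arg(sd_mode)
  n_latent <- as.integer(n_latent)
  if (is.na(n_latent) || n_latent < 1L) {
    stop("n_latent (K) must be a positive integer")
  }
  encoder_widths <- as.integer(encoder_widths)
  decoder_widths <- as.integer(decoder_widths)
  if (length(encoder_widths) == 0L || any(encoder_widths < 1L)) {
    stop("encoder_widths must all be >= 1")
  }
  if (any(decoder_widths < 1L)) stop("decoder_widths must all be >= 1")
  if (gamma < 0) stop("gamma must be non-negative")
  if (l2_scale < 0) stop("l2_scale must be non-negative")
  if (!is.null(c_red)) {
    c_red <- as.integer(c_red)
    if (c_red < 1L) stop("c_red must be a positive integer")
  }
  n_batch <- as.integer(n_batch)
  if (n_batch < 0L) stop("n_batch must be non-negative")
  if (n_batch > 0L && length(decoder_widths) == 0L) {
    stop("batch correction requires at least one decoder hidden layer")
  }
  epochs <- rep_len(as.integer(epochs), 3L)
  structure(list(
    n_latent = n_latent,
    encoder_widths = encoder_widths,
    decoder_widths = decoder_widths,
    gamma = gamma,
    observation_model = observation_model,
    learning_rate = learning_rate,
    l2_scale = l2_scale,
    c_red = c_red,
    reduction_method = reduction_method,
    n_batch = n_batch,
    activation = activation,
    sd_mode = sd_mode,
    epochs = epochs,
    kl_warmup = as.integer(kl_warmup),
    batch_cells = as.integer(batch_cells),
    batch_features = as.integer(batch_features),
    seed = as.integer(seed)
  ), class = "sivae_config")
}

#' @export
print.sivae_config <- function(x, ...) {
  cat("sivae model configuration\n")
  cat("  latent dimension K:", x$n_latent, "\n")
  cat("  encoder widths:", paste(x$encoder_widths, collapse = "-"), "\n")
  cat("  decoder widths:",
      if (length(x$decoder_widths)) paste(x$decoder_widths, collapse = "-")
      else "(identity)", "\n")
  cat("  observation model:", x$observation_model,
      " gamma:", x$gamma, "\n")
  cat("  lr:", x$learning_rate, " l2:", x$l2_scale,
      " epochs:", paste(x$epochs, collapse = "/"), "\n")
  invisible(x)
}
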