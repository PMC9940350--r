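# Loss construction for all observation models.
#
# Each builder assembles the evidence-lower-bound terms on the autodiff tape
# and returns the components plus (optionally) gradients w.r.t. a requested
# set of parameters. Sign convention: the library MINIMIZES
#   total = -reconstruction + kl - gamma * interpretability_raw + l2_penalty
# where `reconstruction` and `interpretability_raw` are expected
# log-likelihoods (one reparameterized sample, shared between the
# reconstruction and interpretability terms) and `kl` is the analytic
# Gaussian KL of the approximate posteriors against N(0, I_K).

LOG2PI <- log(2 * pi)

# wrap parameter matrices as tape nodes; names in `trainable` become leaves
# (gradients accumulated), everything else a constant
wrap_pars <- function(tape, par, trainable) {
  out <- new.env(parent = emptyenv())
  for (nm in names(par)) {
    out[[nm]] <- if (nm %in% trainable) ad_leaf(tape, par[[nm]])
                 else ad_const(tape, par[[nm]])
  }
  out
}

ad_affine <- function(tape, x, P, name) {
  ad_bias(tape, ad_mm(tape, x, P[[paste0(name, ".W")]]),
          P[[paste0(name, ".b")]])
}

ad_encode <- function(tape, x, P, prefix, cfg) {
  h <- x
  for (i in seq_along(cfg$encoder_widths)) {
    h <- ad_activation(tape, ad_affine(tape, h, P, sprintf("%s.h%d", prefix, i)),
                       cfg$activation)
  }
  list(
    mean = ad_affine(tape, h, P, paste0(prefix, ".mean")),
    sd = ad_positive(tape, ad_affine(tape, h, P, paste0(prefix, ".sd"))),
    hidden = h
  )
}

ad_decoder <- function(tape, z, P, prefix, cfg, s_node = NULL) {
  dw <- cfg$decoder_widths
  if (length(dw) == 0L) return(z)
  for (i in seq_along(dw)) {
    z <- ad_affine(tape, z, P, sprintf("%s.h%d", prefix, i))
    if (i == 1L && !is.null(s_node) && prefix == "cdec") {
      z <- ad_add(tape, z, ad_affine(tape, s_node, P, "mu_s"))
    }
    if (i < length(dw)) z <- ad_activation(tape, z, cfg$activation)
  }
  z
}

# analytic KL( N(mean, sd^2) || N(0, I) ), summed over all rows
ad_kl_std_normal <- function(tape, mean, sd) {
  m2 <- ad_sum(tape, ad_square(tape, mean))
  s2 <- ad_sum(tape, ad_square(tape, sd))
  ls <- ad_sum(tape, ad_log(tape, sd))
  n <- length(mean$value)
  ad_shift(tape,
           ad_sub(tape, ad_scale(tape, ad_add(tape, m2, s2), 0.5), ls),
           -n / 2)
}

# sum of log N(x; mean, sd) over all entries; x is a constant matrix,
# sd a node of matching shape
ad_gauss_loglik <- function(tape, x, mean, sd) {
  resid <- ad_sub(tape, ad_const(tape, x), mean)
  z2 <- ad_sum(tape, ad_square(tape, ad_div(tape, resid, sd)))
  ls <- ad_sum(tape, ad_log(tape, sd))
  n <- length(x)
  ad_shift(tape, ad_neg(tape, ad_add(tape, ad_scale(tape, z2, 0.5), ls)),
           -n * LOG2PI / 2)
}

# as above with unit variance
ad_gauss_loglik_unit <- function(tape, x, mean) {
  resid <- ad_sub(tape, ad_const(tape, x), mean)
  z2 <- ad_sum(tape, ad_square(tape, resid))
  ad_shift(tape, ad_scale(tape, z2, -0.5), -length(x) * LOG2PI / 2)
}

# negative binomial log-likelihood, mu = mean, theta = inverse dispersion
ad_nb_loglik <- function(tape, x, mu, theta) {
  xc <- ad_const(tape, x)
  tpm <- ad_add(tape, theta, mu)
  ll <- ad_sub(tape, ad_lgamma(tape, ad_add(tape, xc, theta)),
               ad_lgamma(tape, theta))
  ll <- ad_add(tape, ll, ad_mul(tape, theta,
    ad_sub(tape, ad_log(tape, theta), ad_log(tape, tpm))))
  ll <- ad_add(tape, ll, ad_mul(tape, xc,
    ad_sub(tape, ad_log(tape, mu), ad_log(tape, tpm))))
  ad_shift(tape, ad_sum(tape, ll), -sum(lgamma(x + 1)))
}

# expand an n x 1 head output to n x f by an outer product with ones
ad_expand_cols <- function(tape, a, f) {
  if (ncol(a$value) == f) return(a)
  ad_mm(tape, a, ad_const(tape, matrix(1, 1L, f)))
}

l2_penalty_node <- function(tape, P, par) {
  wnames <- grep("\\.W$|^J$", names(par), value = TRUE)
  tot <- NULL
  for (nm in wnames) {
    sq <- ad_sum(tape, ad_square(tape, P[[nm]]))
    tot <- if (is.null(tot)) sq else ad_add(tape, tot, sq)
  }
  tot
}

draw_noise <- function(noise, what, n, k) {
  if (!is.null(noise) && !is.null(noise[[what]])) {
    m <- as.matrix(noise[[what]])
    stopifnot(nrow(m) == n, ncol(m) == k)
    return(m)
  }
  matrix(stats::rnorm(n * k), n, k)
}

reparam <- function(tape, post, eps) {
  ad_add(tape, post$mean, ad_mul(tape, post$sd, ad_const(tape, eps)))
}

collect_grads <- function(P, trainable) {
  g <- list()
  for (nm in trainable) {
    gr <- P[[nm]]$grad
    g[[nm]] <- if (is.null(gr)) 0 * P[[nm]]$value else gr
  }
  g
}

loss_components <- function(kl, recon, interp_raw, gamma, l2) {
  total <- -recon + kl - gamma * interp_raw + l2
  structure(list(
    kl = kl,
    reconstruction = recon,
    interpretability_raw = interp_raw,
    interpretability = gamma * interp_raw,
    gamma = gamma,
    l2_penalty = l2,
    total = total
  ), class = "sivae_loss")
}

#' @export
print.sivae_loss <- function(x, ...) {
  cat(sprintf(
    "sivae loss: total %.4f  (kl %.4f, recon %.4f, interp %.4f, l2 %.4f)\n",
    x$total, x$kl, x$reconstruction, x$interpretability, x$l2_penalty))
  invisible(x)
}

# Joint loss for all three observation models.
# x: cells x genes batch (subset columns when feature-minibatching);
# xred: reduced profiles for those genes (genes x c_red);
# fidx: column indices of the genes within the full gene set;
# x_interp: values the interpretability term compares against (defaults to x;
#   the NB model compares against per-gene-centered log1p counts);
# sc, sf: rescaling factors to full-data scale for the cell and feature sums.
loss_joint <- function(model, x, xred, s = NULL, noise = NULL,
                       trainable = character(0), fidx = NULL,
                       x_interp = NULL, sc = 1, sf = 1,
                       want_grads = FALSE, beta = 1) {
  cfg <- model$config
  K <- cfg$n_latent
  x <- as.matrix(x); xred <- as.matrix(xred)
  nc <- nrow(x)
  if (ncol(x) != model$n_features) {
    stop(sprintf("x must have all %d gene columns (the cell encoder input)",
                 model$n_features))
  }
  if (is.null(fidx)) fidx <- seq_len(model$n_features)
  nf <- length(fidx)
  stopifnot(nrow(xred) == nf)
  if (!all(is.finite(x))) {
    stop("non-finite values in input batch (first bad row: ",
         which(!apply(is.finite(x), 1L, all))[1L], ")")
  }
  xr <- x[, fidx, drop = FALSE]   # observations entering the likelihood sums
  if (cfg$observation_model == "nb") {
    if (any(x < 0) || any(x != round(x))) {
      stop("nb observation model requires non-negative integer counts")
    }
  }
  tape <- ad_tape()
  P <- wrap_pars(tape, model$par, trainable)

  x_enc <- if (!is.null(s)) cbind(x_full_check(x, s)) else x
  xin <- ad_const(tape, x_enc)
  cell_post <- ad_encode(tape, xin, P, "cenc", cfg)
  feat_post <- ad_encode(tape, ad_const(tape, xred), P, "fenc", cfg)
  eps_z <- draw_noise(noise, "z", nc, K)
  eps_v <- draw_noise(noise, "v", nf, K)
  z1 <- reparam(tape, cell_post, eps_z)
  v1 <- reparam(tape, feat_post, eps_v)

  s_node <- if (!is.null(s)) ad_const(tape, as.matrix(s)) else NULL

  kl_z <- ad_kl_std_normal(tape, cell_post$mean, cell_post$sd)
  kl_v <- ad_kl_std_normal(tape, feat_post$mean, feat_post$sd)
  kl <- ad_add(tape, ad_scale(tape, kl_z, sc), ad_scale(tape, kl_v, sf))

  # interpretability mean: v1' z1 (+ J s)
  m1 <- ad_mm(tape, z1, ad_t(tape, v1))
  if (!is.null(s_node) && !is.null(model$par$J)) {
    jsub <- ad_cols(tape, ad_t(tape, P$J), fidx)        # b x nf -> slice genes
    m1 <- ad_add(tape, m1, ad_mm(tape, s_node, jsub))
  }
  interp_target <- if (is.null(x_interp)) xr
                   else as.matrix(x_interp)[, fidx, drop = FALSE]

  if (cfg$observation_model == "linear") {
    sd_raw <- ad_affine(tape, z1, P, "sdhead")
    sd_d <- ad_cols(tape, ad_expand_cols(tape, ad_positive(tape, sd_raw),
                                         model$n_features), fidx)
    recon <- ad_gauss_loglik(tape, xr, m1, sd_d)
    interp_raw_node <- NULL
  } else {
    zL <- ad_decoder(tape, z1, P, "cdec", cfg, s_node = s_node)
    vL <- ad_decoder(tape, v1, P, "fdec", cfg)
    mL <- ad_mm(tape, zL, ad_t(tape, vL))
    sd_raw <- ad_affine(tape, zL, P, "sdhead")
    sd_d <- ad_cols(tape, ad_expand_cols(tape, ad_positive(tape, sd_raw),
                                         model$n_features), fidx)
    if (cfg$observation_model == "gaussian") {
      recon <- ad_gauss_loglik(tape, xr, mL, sd_d)
    } else {
      # NB: amortized lognormal library, softmax mean proportions, the
      # Gamma-Poisson mixture marginalized analytically to a negative binomial
      lm <- ad_affine(tape, cell_post$hidden, P, "lib.mean")
      lsd <- ad_positive(tape, ad_affine(tape, cell_post$hidden, P, "lib.sd"))
      eps_l <- draw_noise(noise, "l", nc, 1L)
      logl <- ad_add(tape, lm, ad_mul(tape, lsd, ad_const(tape, eps_l)))
      lib <- ad_exp(tape, logl)
      rho <- ad_softmax_rows(tape, mL)
      mu <- ad_mul_col(tape, rho, lib)
      recon <- ad_nb_loglik(tape, xr, mu, sd_d)
      # KL of q(log l) = N(lm, lsd^2) against N(l_mu, l_sd^2)
      s0 <- model$l_sd
      dmean <- ad_shift(tape, lm, -model$l_mu)
      klq <- ad_add(tape,
        ad_scale(tape, ad_sum(tape, ad_add(tape, ad_square(tape, lsd),
                                           ad_square(tape, dmean))),
                 1 / (2 * s0^2)),
        ad_neg(tape, ad_sum(tape, ad_log(tape, lsd))))
      klq <- ad_shift(tape, klq, nc * (log(s0) - 0.5))
      kl <- ad_add(tape, kl, ad_scale(tape, klq, sc))
    }
    interp_raw_node <- ad_gauss_loglik_unit(tape, interp_target, m1)
  }
  if (cfg$observation_model == "linear") {
    interp_raw <- 0
  }

  recon <- ad_scale(tape, recon, sc * sf)
  total <- ad_sub(tape, ad_scale(tape, kl, beta), recon)
  if (!is.null(interp_raw_node) && cfg$gamma > 0) {
    interp_sc <- ad_scale(tape, interp_raw_node, sc * sf)
    total <- ad_sub(tape, total, ad_scale(tape, interp_sc, cfg$gamma))
  }
  l2_node <- NULL
  if (cfg$l2_scale > 0) {
    l2_node <- ad_scale(tape, l2_penalty_node(tape, P, model$par),
                        cfg$l2_scale)
    total <- ad_add(tape, total, l2_node)
  }

  grads <- NULL
  if (want_grads && length(trainable)) {
    ad_backward(tape, total)
    grads <- collect_grads(P, trainable)
  }
  if (!is.null(interp_raw_node)) {
    interp_raw <- interp_raw_node$value[1L] * sc * sf
  }
  comps <- loss_components(
    kl = kl$value[1L],
    recon = recon$value[1L],
    interp_raw = interp_raw,
    gamma = if (cfg$observation_model == "linear") 0 else cfg$gamma,
    l2 = if (is.null(l2_node)) 0 else l2_node$value[1L]
  )
  if (!all(is.finite(unlist(comps[c("kl", "reconstruction", "total")])))) {
    stop("non-finite loss encountered")
  }
  list(components = comps, grads = grads, total_node_value = total$value[1L])
}

x_full_check <- function(x, s) {
  s <- as.matrix(s)
  if (nrow(s) != nrow(x)) stop("batch covariates must have one row per cell")
  cbind(x, s)
}

# Step-1 pre-training loss: canonical VAE over the cell path with the decoded
# feature activations v_{f,L} treated as a free parameter matrix (par$v_tilde,
# n_features x d_last).
loss_pretrain_cell <- function(model, x, s = NULL, noise = NULL,
                               trainable = character(0), fidx = NULL,
                               sc = 1, sf = 1, want_grads = FALSE,
                               beta = 1) {
  cfg <- model$config
  x <- as.matrix(x)
  nc <- nrow(x)
  if (ncol(x) != model$n_features) {
    stop(sprintf("x must have all %d gene columns (the cell encoder input)",
                 model$n_features))
  }
  if (is.null(fidx)) fidx <- seq_len(model$n_features)
  xr <- x[, fidx, drop = FALSE]
  tape <- ad_tape()
  P <- wrap_pars(tape, model$par, trainable)
  x_enc <- if (!is.null(s)) x_full_check(x, s) else x
  cell_post <- ad_encode(tape, ad_const(tape, x_enc), P, "cenc", cfg)
  eps_z <- draw_noise(noise, "z", nc, cfg$n_latent)
  z1 <- reparam(tape, cell_post, eps_z)
  s_node <- if (!is.null(s)) ad_const(tape, as.matrix(s)) else NULL
  kl <- ad_scale(tape, ad_kl_std_normal(tape, cell_post$mean, cell_post$sd), sc)

  if (cfg$observation_model == "linear") {
    vt <- ad_node_rows(tape, P$v_tilde, fidx)
    mL <- ad_mm(tape, z1, ad_t(tape, vt))
    sd_raw <- ad_affine(tape, z1, P, "sdhead")
    sd_d <- ad_cols(tape, ad_expand_cols(tape, ad_positive(tape, sd_raw),
                                         model$n_features), fidx)
    recon <- ad_gauss_loglik(tape, xr, mL, sd_d)
  } else {
    zL <- ad_decoder(tape, z1, P, "cdec", cfg, s_node = s_node)
    vt <- ad_node_rows(tape, P$v_tilde, fidx)
    mL <- ad_mm(tape, zL, ad_t(tape, vt))
    sd_raw <- ad_affine(tape, zL, P, "sdhead")
    sd_d <- ad_cols(tape, ad_expand_cols(tape, ad_positive(tape, sd_raw),
                                         model$n_features), fidx)
    if (cfg$observation_model == "gaussian") {
      recon <- ad_gauss_loglik(tape, xr, mL, sd_d)
    } else {
      lm <- ad_affine(tape, cell_post$hidden, P, "lib.mean")
      lsd <- ad_positive(tape, ad_affine(tape, cell_post$hidden, P, "lib.sd"))
      eps_l <- draw_noise(noise, "l", nc, 1L)
      lib <- ad_exp(tape, ad_add(tape, lm, ad_mul(tape, lsd, ad_const(tape, eps_l))))
      rho <- ad_softmax_rows(tape, mL)
      mu <- ad_mul_col(tape, rho, lib)
      recon <- ad_nb_loglik(tape, xr, mu, sd_d)
      s0 <- model$l_sd
      dmean <- ad_shift(tape, lm, -model$l_mu)
      klq <- ad_add(tape,
        ad_scale(tape, ad_sum(tape, ad_add(tape, ad_square(tape, lsd),
                                           ad_square(tape, dmean))),
                 1 / (2 * s0^2)),
        ad_neg(tape, ad_sum(tape, ad_log(tape, lsd))))
      klq <- ad_shift(tape, klq, nc * (log(s0) - 0.5))
      kl <- ad_add(tape, kl, ad_scale(tape, klq, sc))
    }
  }
  recon <- ad_scale(tape, recon, sc * sf)
  total <- ad_sub(tape, ad_scale(tape, kl, beta), recon)
  l2_node <- NULL
  if (cfg$l2_scale > 0) {
    l2_node <- ad_scale(tape, l2_penalty_node(tape, P, model$par), cfg$l2_scale)
    total <- ad_add(tape, total, l2_node)
  }
  grads <- NULL
  if (want_grads && length(trainable)) {
    ad_backward(tape, total)
    grads <- collect_grads(P, trainable)
  }
  comps <- loss_components(kl$value[1L], recon$value[1L], 0, 0,
                           if (is.null(l2_node)) 0 else l2_node$value[1L])
  if (!is.finite(comps$total)) stop("non-finite loss encountered")
  list(components = comps, grads = grads)
}

# row subsetting (used for the free v_tilde parameter under feature batching)
ad_node_rows <- function(tape, a, idx) {
  dm <- dim(a$value)
  if (length(idx) == dm[1L] && all(idx == seq_len(dm[1L]))) return(a)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    full <- matrix(0, dm[1L], dm[2L])
    full[idx, ] <- full[idx, ] + g
    list(full)
  })
}

# Step-2 pre-training loss: a VAE over the feature path whose inputs are the
# reduced per-gene profiles and whose regression targets are the step-1
# estimates v_tilde (unit-variance Gaussian likelihood).
loss_pretrain_feat <- function(model, xred, targets, noise = NULL,
                               trainable = character(0), sf = 1,
                               want_grads = FALSE) {
  cfg <- model$config
  xred <- as.matrix(xred); targets <- as.matrix(targets)
  nf <- nrow(xred)
  tape <- ad_tape()
  P <- wrap_pars(tape, model$par, trainable)
  feat_post <- ad_encode(tape, ad_const(tape, xred), P, "fenc", cfg)
  eps_v <- draw_noise(noise, "v", nf, cfg$n_latent)
  v1 <- reparam(tape, feat_post, eps_v)
  vL <- ad_decoder(tape, v1, P, "fdec", cfg)
  kl <- ad_scale(tape, ad_kl_std_normal(tape, feat_post$mean, feat_post$sd), sf)
  recon <- ad_scale(tape, ad_gauss_loglik_unit(tape, targets, vL), sf)
  total <- ad_sub(tape, kl, recon)
  l2_node <- NULL
  if (cfg$l2_scale > 0) {
    l2_node <- ad_scale(tape, l2_penalty_node(tape, P, model$par), cfg$l2_scale)
    total <- ad_add(tape, total, l2_node)
  }
  grads <- NULL
  if (want_grads && length(trainable)) {
    ad_backward(tape, total)
    grads <- collect_grads(P, trainable)
  }
  comps <- loss_components(kl$value[1L], recon$value[1L], 0, 0,
                           if (is.null(l2_node)) 0 else l2_node$value[1L])
  if (!is.finite(comps$total)) stop("non-finite loss encountered")
  list(components = comps, grads = grads)
}

#' Evidence-lower-bound components under the Gaussian observation model
#'
#' Evaluates the loss on a batch: analytic KL of the cell and feature
#' posteriors against the standard normal prior, the Gaussian reconstruction
#' log-likelihood of the decoded dot-product means, and the
#' interpretability term comparing the latent dot product
#' \eqn{v_{f,1}^T z_{c,1}} to the data under unit variance. One shared
#' reparameterized sample of the latents is used for both expectation terms.
#'
#' @param model A \code{sivae_model} with \code{observation_model "gaussian"}.
#' @param x Centered/scaled expression batch, cells x genes.
#' @param xred Reduced per-gene profiles, genes x \code{c_red}.
#' @param s Optional batch covariates (cells x b).
#' @param noise Optional list with matrices \code{z} (cells x K) and \code{v}
#'   (genes x K) of standard-normal draws, for deterministic evaluation.
#' @return A \code{sivae_loss} with components \code{kl},
#'   \code{reconstruction}, \code{interpretability_raw},
#'   \code{interpretability} (gamma-weighted), \code{l2_penalty} and
#'   \code{total} in minimization form.
#' @export
gaussian_loss <- function(model, x, xred, s = NULL, noise = NULL) {
  stopifnot(model$config$observation_model == "gaussian")
  loss_joint(model, x, xred, s = s, noise = noise)$components
}

#' Evidence-lower-bound components under the negative binomial model
#'
#' As [gaussian_loss()], but for raw counts: the observation layer is the
#' Gamma-Poisson mixture marginalized analytically to a negative binomial with
#' per-cell library size drawn from an amortized lognormal posterior whose
#' prior moments are the empirical log library sizes. The interpretability
#' term compares the latent dot product to per-gene-centered log1p counts.
#'
#' @inheritParams gaussian_loss
#' @param x Non-negative integer count batch.
#' @export
nb_loss <- function(model, x, xred, s = NULL, noise = NULL) {
  stopifnot(model$config$observation_model == "nb")
  xi <- scale(log1p(as.matrix(x)), center = TRUE, scale = FALSE)
  loss_joint(model, x, xred, s = s, noise = noise, x_interp = xi)$components
}

#' Evidence-lower-bound components under the linear decoder variant
#'
#' The predicted mean is the latent dot product \eqn{v_{f,1}^T z_{c,1}}
#' directly (decoders bypassed), so the reconstruction term coincides with
#' the role of the interpretability term and no separate gamma term exists.
#'
#' @inheritParams gaussian_loss
#' @export
linear_loss <- function(model, x, xred, s = NULL, noise = NULL) {
  stopifnot(model$config$observation_model == "linear")
  loss_joint(model, x, xred, s = s, noise = noise)$components
}
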