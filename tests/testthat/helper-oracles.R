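# Independent oracles: direct-formula evaluations of the model's quantities,
# written with plain dense arithmetic (no autodiff, no package forward
# helpers). Used to pin the implementation's losses and posteriors.

softplus_ref <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
posify_ref <- function(x) softplus_ref(x) + 1e-4

affine_ref <- function(x, par, name) {
  sweep(x %*% par[[paste0(name, ".W")]], 2,
        as.numeric(par[[paste0(name, ".b")]]), "+")
}

encode_ref <- function(model, x, prefix) {
  cfg <- model$config
  h <- x
  for (i in seq_along(cfg$encoder_widths)) {
    h <- tanh(affine_ref(h, model$par, sprintf("%s.h%d", prefix, i)))
  }
  list(mean = affine_ref(h, model$par, paste0(prefix, ".mean")),
       sd = posify_ref(affine_ref(h, model$par, paste0(prefix, ".sd"))),
       hidden = h)
}

decode_ref <- function(model, z, prefix, s = NULL) {
  dw <- model$config$decoder_widths
  if (length(dw) == 0) return(z)
  for (i in seq_along(dw)) {
    z <- affine_ref(z, model$par, sprintf("%s.h%d", prefix, i))
    if (i == 1 && !is.null(s) && prefix == "cdec") {
      z <- z + affine_ref(s, model$par, "mu_s")
    }
    if (i < length(dw)) z <- tanh(z)
  }
  z
}

kl_ref <- function(mean, sd) sum(0.5 * (mean^2 + sd^2 - 1) - log(sd))

sd_matrix_ref <- function(model, zin, nf) {
  raw <- posify_ref(affine_ref(zin, model$par, "sdhead"))
  if (ncol(raw) == 1) matrix(raw, nrow(raw), nf) else raw
}

l2_ref <- function(model) {
  wn <- grep("\\.W$|^J$", names(model$par), value = TRUE)
  model$config$l2_scale * sum(vapply(wn, function(n) sum(model$par[[n]]^2), 0))
}

# full-batch loss oracles (scale 1), mirroring the stated objective from the
# distribution formulas alone
oracle_gaussian_loss <- function(model, x, xred, noise, s = NULL) {
  cz <- encode_ref(model, if (is.null(s)) x else cbind(x, s), "cenc")
  fv <- encode_ref(model, xred, "fenc")
  z1 <- cz$mean + cz$sd * noise$z
  v1 <- fv$mean + fv$sd * noise$v
  zL <- decode_ref(model, z1, "cdec", s = s)
  vL <- decode_ref(model, v1, "fdec")
  m <- zL %*% t(vL)
  sd <- sd_matrix_ref(model, zL, ncol(x))
  recon <- sum(dnorm(x, m, sd, log = TRUE))
  m1 <- z1 %*% t(v1)
  if (!is.null(s) && !is.null(model$par$J)) m1 <- m1 + s %*% t(model$par$J)
  interp <- sum(dnorm(x, m1, 1, log = TRUE))
  kl <- kl_ref(cz$mean, cz$sd) + kl_ref(fv$mean, fv$sd)
  l2 <- l2_ref(model)
  list(kl = kl, reconstruction = recon, interpretability_raw = interp,
       l2_penalty = l2,
       total = -recon + kl - model$config$gamma * interp + l2)
}

oracle_nb_loss <- function(model, x, xred, noise) {
  cz <- encode_ref(model, x, "cenc")
  fv <- encode_ref(model, xred, "fenc")
  z1 <- cz$mean + cz$sd * noise$z
  v1 <- fv$mean + fv$sd * noise$v
  zL <- decode_ref(model, z1, "cdec")
  vL <- decode_ref(model, v1, "fdec")
  eta <- zL %*% t(vL)
  rho <- exp(eta - apply(eta, 1, max))
  rho <- rho / rowSums(rho)
  lm <- affine_ref(cz$hidden, model$par, "lib.mean")
  lsd <- posify_ref(affine_ref(cz$hidden, model$par, "lib.sd"))
  lib <- exp(lm + lsd * noise$l)
  mu <- rho * as.numeric(lib)
  theta <- sd_matrix_ref(model, zL, ncol(x))
  recon <- sum(dnbinom(x, size = theta, mu = mu, log = TRUE))
  xi <- scale(log1p(x), center = TRUE, scale = FALSE)
  interp <- sum(dnorm(xi, z1 %*% t(v1), 1, log = TRUE))
  kl_l <- sum(log(model$l_sd / lsd) +
                (lsd^2 + (lm - model$l_mu)^2) / (2 * model$l_sd^2) - 0.5)
  kl <- kl_ref(cz$mean, cz$sd) + kl_ref(fv$mean, fv$sd) + kl_l
  l2 <- l2_ref(model)
  list(kl = kl, reconstruction = recon, interpretability_raw = interp,
       l2_penalty = l2,
       total = -recon + kl - model$config$gamma * interp + l2)
}

oracle_linear_loss <- function(model, x, xred, noise) {
  cz <- encode_ref(model, x, "cenc")
  fv <- encode_ref(model, xred, "fenc")
  z1 <- cz$mean + cz$sd * noise$z
  v1 <- fv$mean + fv$sd * noise$v
  m <- z1 %*% t(v1)
  sd <- sd_matrix_ref(model, z1, ncol(x))
  recon <- sum(dnorm(x, m, sd, log = TRUE))
  kl <- kl_ref(cz$mean, cz$sd) + kl_ref(fv$mean, fv$sd)
  l2 <- l2_ref(model)
  list(kl = kl, reconstruction = recon, l2_penalty = l2,
       total = -recon + kl + l2)
}

# principal angles (degrees) between the column spans of two matrices
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(t(qa) %*% qb)$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

std_noise <- function(nc, nf, K, seed, lib = FALSE) {
  set.seed(seed)
  out <- list(z = matrix(rnorm(nc * K), nc, K),
              v = matrix(rnorm(nf * K), nf, K))
  if (lib) out$l <- matrix(rnorm(nc), nc, 1)
  out
}
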