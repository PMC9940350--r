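ad <- asNamespace("sivae")

test_that("initialization honors the configured architecture and seed", {
  cfg <- sivae_config(n_latent = 2L, encoder_widths = c(1024L, 512L, 128L),
                      c_red = 50L, seed = 7L)
  m <- sivae_init(cfg, n_features = 60L)
  expect_equal(dim(m$par$cenc.h1.W), c(60L, 1024L))
  expect_equal(dim(m$par$cenc.h2.W), c(1024L, 512L))
  expect_equal(dim(m$par$cenc.h3.W), c(512L, 128L))
  expect_equal(dim(m$par$cenc.mean.W), c(128L, 2L))
  expect_equal(dim(m$par$fenc.h1.W), c(50L, 1024L))
  expect_equal(dim(m$par$cdec.h3.W), c(512L, 1024L))
  expect_equal(dim(m$par$sdhead.W), c(1024L, 60L))

  m2 <- sivae_init(cfg, n_features = 60L)
  expect_identical(m$par, m2$par)

  cfgb <- sivae_config(n_latent = 2L, encoder_widths = c(8L),
                       decoder_widths = c(6L), c_red = 10L, n_batch = 3L,
                       seed = 1L)
  mb <- sivae_init(cfgb, n_features = 12L)
  expect_equal(dim(mb$par$mu_s.W), c(3L, 6L))
  expect_equal(dim(mb$par$J), c(12L, 3L))
  expect_equal(dim(mb$par$cenc.h1.W), c(15L, 8L))

  expect_error(sivae_config(n_latent = 0L), "positive")
  expect_error(sivae_config(encoder_widths = c(8L, 0L)), ">= 1")
})

test_that("cell and feature encoders match hand-computed posteriors", {
  # single hidden layer, K = 1, weights set by hand
  cfg <- sivae_config(n_latent = 1L, encoder_widths = 2L,
                      decoder_widths = integer(0), c_red = 3L, seed = 1L)
  m <- sivae_init(cfg, n_features = 3L)
  m$par$cenc.h1.W <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  m$par$cenc.h1.b <- matrix(c(0.1, -0.2), 1, 2)
  m$par$cenc.mean.W <- matrix(c(1.5, -0.5), 2, 1)
  m$par$cenc.mean.b <- matrix(0.3, 1, 1)
  m$par$cenc.sd.W <- matrix(c(0.2, 0.4), 2, 1)
  m$par$cenc.sd.b <- matrix(-0.1, 1, 1)

  x <- matrix(c(0.5, -1, 2), 1, 3)
  h <- tanh(c(0.5 * 1 + (-1) * 0 + 2 * (-1) + 0.1,
              0.5 * 0.5 + (-1) * 2 + 2 * 0 - 0.2))
  mean_exp <- 1.5 * h[1] - 0.5 * h[2] + 0.3
  sd_raw <- 0.2 * h[1] + 0.4 * h[2] - 0.1
  sd_exp <- log1p(exp(-abs(sd_raw))) + max(sd_raw, 0) + 1e-4

  post <- encode_cells(m, x)
  expect_equal(as.numeric(post$mean), mean_exp, tolerance = 1e-12)
  expect_equal(as.numeric(post$sd), sd_exp, tolerance = 1e-12)

  # positivity and determinism across the feature encoder too
  xr <- matrix(rnorm(12), 4, 3)
  pf <- encode_features(m, xr)
  expect_true(all(pf$sd > 0))
  expect_identical(encode_features(m, xr), pf)
  expect_identical(pf$mean[1, ], encode_features(m, xr[c(1, 1), ])$mean[2, ])
  expect_error(encode_cells(m, matrix(0, 1, 4)), "length")
  expect_error(encode_features(m, matrix(0, 1, 5)), "length")
})

test_that("decode is the dot product of decoded activations", {
  # identity decoders: mean is v' z directly
  cfg <- sivae_config(n_latent = 2L, encoder_widths = 4L,
                      decoder_widths = integer(0), c_red = 3L, seed = 2L)
  m <- sivae_init(cfg, n_features = 2L)
  out <- decode(m, matrix(c(2, 3), 1, 2), matrix(c(1, 0, 0, 0), 2, 2,
                                                 byrow = TRUE))
  expect_equal(out$mean[1, 1], 2)
  expect_equal(out$mean[1, 2], 0)   # zero loading -> zero mean everywhere
  expect_true(all(out$sd > 0))

  # two-layer decoder with hand-set weights
  cfg2 <- sivae_config(n_latent = 1L, encoder_widths = 3L,
                       decoder_widths = c(2L, 2L), c_red = 3L, seed = 3L)
  m2 <- sivae_init(cfg2, n_features = 1L)
  m2$par$cdec.h1.W <- matrix(c(1, -1), 1, 2)
  m2$par$cdec.h1.b <- matrix(c(0.5, 0), 1, 2)
  m2$par$cdec.h2.W <- matrix(c(1, 2, 3, 4), 2, 2)
  m2$par$cdec.h2.b <- matrix(0, 1, 2)
  m2$par$fdec.h1.W <- matrix(c(2, 0.5), 1, 2)
  m2$par$fdec.h1.b <- matrix(0, 1, 2)
  m2$par$fdec.h2.W <- diag(2)
  m2$par$fdec.h2.b <- matrix(c(0.1, 0.2), 1, 2)
  z <- 0.7; v <- -0.3
  zh <- tanh(c(z * 1 + 0.5, z * (-1)))
  zL <- c(zh[1] * 1 + zh[2] * 2, zh[1] * 3 + zh[2] * 4)
  vh <- tanh(c(v * 2, v * 0.5))
  vL <- c(vh[1] + 0.1, vh[2] + 0.2)
  out2 <- decode(m2, matrix(z, 1, 1), matrix(v, 1, 1))
  expect_equal(out2$mean[1, 1], sum(zL * vL), tolerance = 1e-12)
  expect_error(decode(m2, matrix(0, 1, 2), matrix(0, 1, 1)), "K = 1")
})

test_that("loss components match direct-formula oracles for all variants", {
  tb <- toy_batch(nc = 10L, nf = 5L, seed = 29L)
  noise <- std_noise(10L, 5L, 2L, seed = 31L)

  m <- toy_gaussian_model(seed = 13L)
  got <- gaussian_loss(m, tb$x, tb$xred, noise = noise)
  want <- oracle_gaussian_loss(m, tb$x, tb$xred, noise)
  for (f in c("kl", "reconstruction", "interpretability_raw", "l2_penalty",
              "total")) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-6, label = f)
  }
  expect_gte(got$kl, 0)

  cfgn <- sivae_config(n_latent = 2L, encoder_widths = c(6L),
                       decoder_widths = c(5L), observation_model = "nb",
                       c_red = 6L, l2_scale = 1e-3, seed = 17L)
  mn <- sivae_init(cfgn, n_features = 5L)
  mn$l_mu <- 2; mn$l_sd <- 0.5
  set.seed(41)
  cx <- matrix(rpois(50, 5), 10, 5)
  nn <- std_noise(10L, 5L, 2L, seed = 43L, lib = TRUE)
  gotn <- nb_loss(mn, cx, tb$xred, noise = nn)
  wantn <- oracle_nb_loss(mn, cx, tb$xred, nn)
  for (f in c("kl", "reconstruction", "interpretability_raw", "total")) {
    expect_equal(gotn[[f]], wantn[[f]], tolerance = 1e-6, label = f)
  }
  cx_bad <- cx; cx_bad[1, 1] <- -1L
  expect_error(nb_loss(mn, cx_bad, tb$xred), "non-negative")
  expect_error(nb_loss(mn, cx + 0.5, tb$xred), "integer")

  cfgl <- sivae_config(n_latent = 2L, encoder_widths = c(6L),
                       decoder_widths = integer(0),
                       observation_model = "linear", c_red = 6L,
                       l2_scale = 1e-3, seed = 19L)
  ml <- sivae_init(cfgl, n_features = 5L)
  gotl <- linear_loss(ml, tb$x, tb$xred, noise = noise)
  wantl <- oracle_linear_loss(ml, tb$x, tb$xred, noise)
  for (f in c("kl", "reconstruction", "total")) {
    expect_equal(gotl[[f]], wantl[[f]], tolerance = 1e-6, label = f)
  }
  expect_equal(gotl$interpretability, 0)
})

test_that("posterior equal to the prior yields zero KL", {
  m <- toy_gaussian_model(seed = 23L)
  # zero the encoder heads and set the sd bias so softplus(b) + floor = 1
  b <- log(expm1(1 - 1e-4))
  for (p in c("cenc", "fenc")) {
    m$par[[paste0(p, ".mean.W")]][] <- 0
    m$par[[paste0(p, ".mean.b")]][] <- 0
    m$par[[paste0(p, ".sd.W")]][] <- 0
    m$par[[paste0(p, ".sd.b")]][] <- b
  }
  tb <- toy_batch(seed = 47L)
  got <- gaussian_loss(m, tb$x, tb$xred,
                       noise = std_noise(10L, 5L, 2L, seed = 49L))
  expect_equal(got$kl, 0, tolerance = 1e-10)
})

test_that("standard normal log-density at zero residual is -log(2*pi)/2", {
  # K=1 identity paths, unit variance, v'z reproducing x exactly
  cfg <- sivae_config(n_latent = 1L, encoder_widths = 2L,
                      decoder_widths = integer(0),
                      observation_model = "linear", c_red = 1L,
                      l2_scale = 0, seed = 5L)
  m <- sivae_init(cfg, n_features = 1L)
  for (p in c("cenc", "fenc")) {
    m$par[[paste0(p, ".mean.W")]][] <- 0
    m$par[[paste0(p, ".sd.W")]][] <- 0
    m$par[[paste0(p, ".sd.b")]][] <- -30      # sd -> floor, ~deterministic
  }
  m$par$cenc.mean.b[] <- 3
  m$par$fenc.mean.b[] <- 2
  m$par$sdhead.W[] <- 0
  m$par$sdhead.b[] <- log(expm1(1 - 1e-4))    # unit observation sd
  got <- linear_loss(m, matrix(6, 1, 1), matrix(0, 1, 1),
                     noise = list(z = matrix(0, 1, 1), v = matrix(0, 1, 1)))
  expect_equal(got$reconstruction, -0.5 * log(2 * pi), tolerance = 1e-6)
})

test_that("the gamma identity holds exactly and gamma = 0 removes the term", {
  tb <- toy_batch(seed = 53L)
  noise <- std_noise(10L, 5L, 2L, seed = 59L)
  m1 <- toy_gaussian_model(seed = 13L, gamma = 0.05)
  m2 <- toy_gaussian_model(seed = 13L, gamma = 0.3)
  l1 <- gaussian_loss(m1, tb$x, tb$xred, noise = noise)
  l2 <- gaussian_loss(m2, tb$x, tb$xred, noise = noise)
  expect_equal(l1$interpretability_raw, l2$interpretability_raw)
  expect_equal(l2$total - l1$total,
               (0.05 - 0.3) * l1$interpretability_raw, tolerance = 1e-10)

  m0 <- toy_gaussian_model(seed = 13L, gamma = 0)
  l0 <- gaussian_loss(m0, tb$x, tb$xred, noise = noise)
  expect_equal(l0$interpretability, 0)
  expect_equal(l0$total, l0$kl - l0$reconstruction + l0$l2_penalty)
})

test_that("NB mean proportions form a simplex per cell", {
  cfgn <- sivae_config(n_latent = 2L, encoder_widths = c(6L),
                       decoder_widths = c(5L), observation_model = "nb",
                       c_red = 6L, seed = 17L)
  mn <- sivae_init(cfgn, n_features = 5L)
  zL <- decode_ref(mn, matrix(rnorm(8), 4, 2), "cdec")
  vL <- decode_ref(mn, matrix(rnorm(10), 5, 2), "fdec")
  eta <- zL %*% t(vL)
  rho <- exp(eta - apply(eta, 1, max))
  rho <- rho / rowSums(rho)
  expect_equal(rowSums(rho), rep(1, 4), tolerance = 1e-12)
})

test_that("non-finite input is rejected with a useful error", {
  m <- toy_gaussian_model()
  tb <- toy_batch()
  tb$x[3, 2] <- NA
  expect_error(gaussian_loss(m, tb$x, tb$xred), "non-finite")
})
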