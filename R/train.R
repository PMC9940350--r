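# Three-step training: (1) pre-train the cell path as a canonical VAE with
# free feature activations v_tilde, (2) pre-train the feature path as a VAE
# regressing decoded feature activations onto v_tilde, (3) joint training of
# the full objective. Minibatches are taken over cells and (except for the NB
# model, whose softmax couples all genes) over features, with sums rescaled
# to full-data scale.

adam_new <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

adam_step <- function(opt, par, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- 0 * g
      opt$v[[nm]] <- 0 * g
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    par[[nm]] <- par[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  par
}

#' Reduce the feature-wise encoder input
#'
#' The raw input to the feature-wise encoder is one gene's profile across all
#' \code{C} cells; this shrinks that input to length \code{c_red} either by a
#' stratified subsample of cells (label proportions preserved with
#' largest-remainder rounding) or by PCA without whitening on the transposed
#' data, retaining the first \code{c_red} principal-component scores.
#'
#' @param x Expression matrix, cells x genes.
#' @param method \code{"pca"} or \code{"downsample"}.
#' @param c_red Reduced length; must not exceed the number of cells.
#' @param labels Cell labels, required for \code{"downsample"}.
#' @return List with \code{reduced} (genes x \code{c_red}) and
#'   \code{reducer}, a fitted mapping applicable to new gene profiles via
#'   [apply_reducer()].
#' @export
reduce_feature_input <- function(x, method = c("pca", "downsample"),
                                 c_red, labels = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  C <- nrow(x)
  c_red <- as.integer(c_red)
  if (c_red > C) stop("c_red must not exceed the number of cells")
  if (method == "downsample") {
    if (is.null(labels)) stop("downsample reduction requires cell labels")
    labels <- as.factor(labels)
    tab <- table(labels)
    quota <- c_red * as.numeric(tab) / C
    base <- floor(quota)
    rem <- c_red - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    idx <- integer(0)
    for (i in seq_along(tab)) {
      pool <- which(labels == names(tab)[i])
      if (base[i] > 0) idx <- c(idx, sample(pool, base[i]))
    }
    idx <- sort(idx)
    reducer <- list(method = "downsample", idx = idx)
  } else {
    xt <- t(x)                       # genes x cells
    ctr <- colMeans(xt)              # per-cell mean across genes
    xc <- sweep(xt, 2L, ctr)
    sv <- svd(xc, nu = 0, nv = c_red)
    if (ncol(sv$v) < c_red) stop("c_red exceeds the rank of the data")
    reducer <- list(method = "pca", center = ctr, rotation = sv$v)
  }
  list(reduced = apply_reducer_mat(reducer, x), reducer = reducer)
}

apply_reducer_mat <- function(reducer, x) {
  x <- as.matrix(x)
  if (reducer$method == "downsample") {
    t(x[reducer$idx, , drop = FALSE])
  } else {
    sweep(t(x), 2L, reducer$center) %*% reducer$rotation
  }
}

#' Apply a fitted feature-input reducer to new data
#'
#' @param reducer The \code{reducer} element returned by
#'   [reduce_feature_input()].
#' @param x Expression matrix, cells x genes, with the same cell dimension the
#'   reducer was fitted on.
#' @return Reduced gene profiles, genes x \code{c_red}.
#' @export
apply_reducer <- function(reducer, x) apply_reducer_mat(reducer, x)

trainable_cell <- function(model) {
  nms <- names(model$par)
  keep <- grepl("^cenc\\.|^cdec\\.|^sdhead\\.|^lib\\.|^mu_s\\.", nms) |
    nms == "v_tilde"
  nms[keep]
}

trainable_feat <- function(model) {
  nms <- names(model$par)
  nms[grepl("^fenc\\.|^fdec\\.", nms)]
}

trainable_joint <- function(model) {
  setdiff(names(model$par), "v_tilde")
}

# generic epoch loop; step_fn(model, cidx, fidx, sc, sf) must return
# list(components, grads)
train_loop <- function(model, trainable, epochs, n_cells, n_feats, step_fn,
                       batch_cells, batch_features, feature_batching = TRUE,
                       stage = "joint", verbose = FALSE,
                       beta_schedule = NULL) {
  if (epochs < 1L) return(list(model = model, log = NULL))
  opt <- adam_new(model$config$learning_rate)
  bc <- min(batch_cells, n_cells)
  bf <- if (feature_batching) min(batch_features, n_feats) else n_feats
  log <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    beta <- if (is.null(beta_schedule)) 1 else beta_schedule[ep]
    perm <- sample.int(n_cells)
    starts <- seq(1L, n_cells, by = bc)
    comp_sum <- c(kl = 0, reconstruction = 0, interpretability = 0, total = 0)
    nsteps <- 0L
    for (st in starts) {
      cidx <- perm[st:min(st + bc - 1L, n_cells)]
      fidx <- if (bf < n_feats) sort(sample.int(n_feats, bf)) else seq_len(n_feats)
      sc <- n_cells / length(cidx)
      sf <- n_feats / length(fidx)
      res <- step_fn(model, cidx, fidx, sc, sf, beta)
      model$par <- adam_step(opt, model$par, res$grads)
      cc <- res$components
      comp_sum <- comp_sum + c(cc$kl, cc$reconstruction, cc$interpretability,
                               cc$total)
      nsteps <- nsteps + 1L
    }
    avg <- comp_sum / nsteps
    log[[ep]] <- data.frame(stage = stage, epoch = ep, kl = avg[1L],
                            reconstruction = avg[2L],
                            interpretability = avg[3L], total = avg[4L],
                            row.names = NULL)
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d  total %.3f", stage, ep, epochs,
                      avg[4L]))
    }
  }
  list(model = model, log = do.call(rbind, log))
}

#' Pre-train the cell-wise encoder-decoder (step 1)
#'
#' Trains the cell path as a canonical VAE, treating the decoded feature
#' activations as a free parameter matrix \code{v_tilde}
#' (genes x last-decoder-width) that is optimized jointly and returned for
#' use as the step-2 regression target.
#'
#' @param model A \code{sivae_model}.
#' @param x Full expression matrix (cells x genes).
#' @param s Optional batch covariates.
#' @param epochs Number of epochs (default from the model config).
#' @param verbose Print per-epoch losses.
#' @return List with the updated \code{model}, the estimated \code{v_tilde}
#'   and the per-epoch training \code{log}.
#' @export
pretrain_cellwise <- function(model, x, s = NULL,
                              epochs = model$config$epochs[1L],
                              verbose = FALSE) {
  x <- as.matrix(x)
  cfg <- model$config
  if (is.null(model$par$v_tilde)) {
    model$par$v_tilde <- glorot(model$n_features, model$d_last)
  }
  if (cfg$observation_model == "nb") {
    libsz <- log(pmax(rowSums(x), 1))
    model$l_mu <- mean(libsz)
    model$l_sd <- max(stats::sd(libsz), 1e-3)
  }
  trainable <- trainable_cell(model)
  step_fn <- function(m, cidx, fidx, sc, sf, beta) {
    loss_pretrain_cell(m, x[cidx, , drop = FALSE],
                       s = if (!is.null(s)) s[cidx, , drop = FALSE],
                       trainable = trainable, fidx = fidx,
                       sc = sc, sf = sf, want_grads = TRUE, beta = beta)
  }
  warm <- min(cfg$kl_warmup, epochs)
  beta_schedule <- if (warm > 0) {
    pmin(seq_len(epochs) / warm, 1)
  } else NULL
  out <- train_loop(model, trainable, epochs, nrow(x), model$n_features,
                    step_fn, cfg$batch_cells, cfg$batch_features,
                    feature_batching = cfg$observation_model != "nb",
                    stage = "pretrain_cell", verbose = verbose,
                    beta_schedule = beta_schedule)
  list(model = out$model, v_tilde = out$model$par$v_tilde, log = out$log)
}

#' Pre-train the feature-wise encoder-decoder (step 2)
#'
#' Trains the feature path as a VAE whose inputs are the reduced per-gene
#' profiles and whose decoded outputs regress (unit-variance Gaussian) onto
#' the step-1 estimates \code{v_tilde}.
#'
#' @param model A \code{sivae_model} (after step 1).
#' @param xred Reduced per-gene profiles, genes x \code{c_red}.
#' @param v_tilde Step-1 target matrix, genes x last-decoder-width.
#' @inheritParams pretrain_cellwise
#' @return List with the updated \code{model} and the training \code{log}.
#' @export
pretrain_featurewise <- function(model, xred, v_tilde,
                                 epochs = model$config$epochs[2L],
                                 verbose = FALSE) {
  xred <- as.matrix(xred)
  v_tilde <- as.matrix(v_tilde)
  stopifnot(nrow(xred) == model$n_features,
            nrow(v_tilde) == model$n_features,
            ncol(v_tilde) == model$d_last)
  cfg <- model$config
  trainable <- trainable_feat(model)
  step_fn <- function(m, cidx, fidx, sc, sf, beta) {
    # cells play no role here; the "cell" loop is over features instead
    loss_pretrain_feat(m, xred[cidx, , drop = FALSE],
                       v_tilde[cidx, , drop = FALSE],
                       trainable = trainable, sf = sc, want_grads = TRUE)
  }
  out <- train_loop(model, trainable, epochs, model$n_features, 1L, step_fn,
                    cfg$batch_features, 1L, feature_batching = FALSE,
                    stage = "pretrain_feature", verbose = verbose)
  list(model = out$model, log = out$log)
}

#' Jointly train all model parameters (step 3)
#'
#' Optimizes the full objective (reconstruction, both KL terms and the
#' gamma-weighted interpretability term) over every parameter of the four
#' networks.
#'
#' @inheritParams pretrain_cellwise
#' @param xred Reduced per-gene profiles, genes x \code{c_red}.
#' @return List with the updated \code{model} and the training \code{log}.
#' @export
train_joint <- function(model, x, xred, s = NULL,
                        epochs = model$config$epochs[3L], verbose = FALSE) {
  x <- as.matrix(x); xred <- as.matrix(xred)
  cfg <- model$config
  trainable <- trainable_joint(model)
  x_interp <- NULL
  if (cfg$observation_model == "nb") {
    x_interp <- scale(log1p(x), center = TRUE, scale = FALSE)
  }
  step_fn <- function(m, cidx, fidx, sc, sf, beta) {
    loss_joint(m, x[cidx, , drop = FALSE], xred[fidx, , drop = FALSE],
               s = if (!is.null(s)) s[cidx, , drop = FALSE],
               trainable = trainable, fidx = fidx,
               x_interp = if (!is.null(x_interp))
                 x_interp[cidx, , drop = FALSE],
               sc = sc, sf = sf, want_grads = TRUE)
  }
  out <- train_loop(model, trainable, epochs, nrow(x), model$n_features,
                    step_fn, cfg$batch_cells, cfg$batch_features,
                    feature_batching = cfg$observation_model != "nb",
                    stage = "joint", verbose = verbose)
  list(model = out$model, log = out$log)
}

#' Fit the interpretable VAE
#'
#' End-to-end fit: reduces the feature-wise input, runs the three training
#' steps, and returns the trained model bundle.
#'
#' @param x Expression matrix, cells x genes (centered/scaled values for the
#'   Gaussian and linear models, raw counts for the NB model), or a
#'   [expression_matrix()] object.
#' @param config A [sivae_config()].
#' @param s Optional batch covariate matrix (cells x b).
#' @param labels Optional cell labels (used for stratified downsampling when
#'   \code{reduction_method = "downsample"}).
#' @param verbose Print per-epoch losses.
#' @param n_restarts Number of independently seeded fits (seeds
#'   \code{config$seed}, \code{config$seed + 1}, ...); the fit with the
#'   lowest final joint-training loss is returned. Restarts guard against
#'   initializations that end in a poor local optimum.
#' @return An object of class \code{"sivae_fit"} containing the trained
#'   \code{model}, the fitted \code{reducer} and reduced input \code{xred},
#'   the step-1 \code{pretrained_v_tilde}, and the concatenated
#'   \code{training_log}.
#' @export
sivae_fit <- function(x, config, s = NULL, labels = NULL, verbose = FALSE,
                      n_restarts = 1L) {
  if (n_restarts > 1L) {
    fits <- lapply(seq_len(n_restarts) - 1L, function(i) {
      cfg_i <- config
      cfg_i$seed <- config$seed + i
      sivae_fit(x, cfg_i, s = s, labels = labels, verbose = verbose)
    })
    finals <- vapply(fits, function(f) utils::tail(f$training_log$total, 1L),
                     numeric(1))
    return(fits[[which.min(finals)]])
  }
  if (inherits(x, "expression_matrix")) {
    if (is.null(labels)) labels <- x$cell_labels
    if (is.null(s) && !is.null(x$batch)) s <- x$batch
    gene_ids <- x$gene_ids
    cell_ids <- x$cell_ids
    x <- x$values
  } else {
    x <- as.matrix(x)
    gene_ids <- colnames(x)
    cell_ids <- rownames(x)
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(x)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(x)))
  c_red <- if (is.null(config$c_red)) min(nrow(x), 2000L) else config$c_red
  c_red <- min(c_red, nrow(x))
  model <- sivae_init(config, n_features = ncol(x), c_red = c_red)

  red <- reduce_feature_input(x, method = config$reduction_method,
                              c_red = c_red, labels = labels)
  s1 <- pretrain_cellwise(model, x, s = s, verbose = verbose)
  s2 <- pretrain_featurewise(s1$model, red$reduced, s1$v_tilde,
                             verbose = verbose)
  s3 <- train_joint(s2$model, x, red$reduced, s = s, verbose = verbose)
  model <- s3$model
  model$trained <- TRUE
  structure(list(
    model = model,
    config = config,
    reducer = red$reducer,
    xred = red$reduced,
    x_dim = dim(x),
    gene_ids = gene_ids,
    cell_ids = cell_ids,
    pretrained_v_tilde = s1$v_tilde,
    training_log = rbind(s1$log, s2$log, s3$log)
  ), class = "sivae_fit")
}

#' @export
print.sivae_fit <- function(x, ...) {
  cat("sivae fit:", x$x_dim[1L], "cells x", x$x_dim[2L], "genes, K =",
      x$config$n_latent, "(", x$config$observation_model, ")\n")
  if (!is.null(x$training_log)) {
    last <- utils::tail(x$training_log, 1L)
    cat(sprintf("  final %s loss: %.4f\n", last$stage, last$total))
  }
  invisible(x)
}

#' Extract scores, loadings and per-gene reconstruction error
#'
#' Scores are the posterior means of the cell embeddings (\code{C x K}),
#' loadings the posterior means of the feature embeddings (\code{F x K});
#' per-gene reconstruction error is the mean over cells of the squared error
#' between the observed values and the decoded dot-product mean (for the NB
#' model, the mean negative-binomial deviance instead).
#'
#' @param fit A trained \code{sivae_fit}.
#' @param x Data to embed; defaults to requiring the training data to be
#'   passed explicitly.
#' @param s Optional batch covariates matching \code{x}.
#' @return An object of class \code{"sivae_embedding"} with elements
#'   \code{scores}, \code{loadings}, \code{per_gene_recon_error} and
#'   \code{gene_ids}.
#' @export
extract_embeddings <- function(fit, x, s = NULL) {
  stopifnot(inherits(fit, "sivae_fit"))
  if (!fit$model$trained) stop("model has not been trained")
  x <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  model <- fit$model
  x_enc <- if (!is.null(s)) cbind(x, as.matrix(s)) else x
  zpost <- encode_cells(model, x_enc)
  vpost <- encode_features(model, fit$xred)
  dec <- decode(model, zpost$mean, vpost$mean, s = s)
  if (model$config$observation_model == "nb") {
    lib <- rowSums(x)
    rho <- t(apply(dec$mean, 1L, function(r) {
      e <- exp(r - max(r)); e / sum(e)
    }))
    mu <- rho * lib
    theta <- if (ncol(dec$sd) == 1L) {
      matrix(dec$sd, nrow(x), ncol(x))
    } else dec$sd
    t1 <- ifelse(x > 0, x * log(x / mu), 0)
    t2 <- (x + theta) * log((x + theta) / (mu + theta))
    err <- colMeans(2 * (t1 - t2))
  } else {
    err <- colMeans((x - dec$mean)^2)
  }
  structure(list(
    scores = zpost$mean,
    loadings = vpost$mean,
    per_gene_recon_error = as.numeric(err),
    gene_ids = fit$gene_ids,
    cell_ids = rownames(x) %||% fit$cell_ids[seq_len(nrow(x))]
  ), class = "sivae_embedding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sivae_embedding <- function(x, ...) {
  cat("sivae embedding:", nrow(x$scores), "cells x", ncol(x$scores),
      "dims;", nrow(x$loadings), "gene loadings\n")
  invisible(x)
}

#' Sample a synthetic expression matrix from a trained model
#'
#' Draws cell embeddings from the standard-normal prior, pairs them with the
#' fitted posterior-mean gene loadings, decodes through both decoders, and
#' samples observations from the fitted observation distribution. Used by the
#' generative route to network inference: sample data matching the training
#' set, then run a co-expression inference method on the sample.
#'
#' @param fit A trained \code{sivae_fit}.
#' @param n_cells Number of cells to sample.
#' @param seed Integer seed.
#' @return Matrix \code{n_cells x F} with the training gene identifiers.
#' @export
sample_from_model <- function(fit, n_cells, seed = 1L) {
  stopifnot(inherits(fit, "sivae_fit"))
  if (!fit$model$trained) stop("model has not been trained")
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be positive")
  model <- fit$model
  K <- model$config$n_latent
  set.seed(seed)
  z <- matrix(stats::rnorm(n_cells * K), n_cells, K)
  v <- encode_features(model, fit$xred)$mean
  dec <- decode(model, z, v)
  obs <- model$config$observation_model
  if (obs == "nb") {
    lib <- exp(stats::rnorm(n_cells, model$l_mu, model$l_sd))
    rho <- t(apply(dec$mean, 1L, function(r) {
      e <- exp(r - max(r)); e / sum(e)
    }))
    mu <- rho * lib
    theta <- if (ncol(dec$sd) == 1L) {
      matrix(dec$sd, n_cells, model$n_features)
    } else dec$sd
    x <- matrix(stats::rnbinom(length(mu), size = as.numeric(theta),
                               mu = as.numeric(mu)),
                n_cells, model$n_features)
  } else {
    sd <- if (ncol(dec$sd) == 1L) {
      matrix(dec$sd, n_cells, model$n_features)
    } else dec$sd
    x <- dec$mean + sd * matrix(stats::rnorm(length(dec$mean)),
                                n_cells, model$n_features)
  }
  colnames(x) <- fit$gene_ids
  rownames(x) <- paste0("sampled_cell", seq_len(n_cells))
  x
}
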