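# Convolutional variational deep embedding with a Gaussian-mixture latent
# prior. Cells are represented as stacked band matrices (k strata x genome
# bins); the encoder maps each image to a diagonal Gaussian q(z|x), the prior
# is a learned mixture of diagonal Gaussians over mixture components, and the
# decoder emits per-pixel Poisson rates (or Bernoulli probabilities).
#
# Training maximizes the evidence lower bound
#   E_q[log p(x|z)] - sum_c gamma_c KL(q(z|x) || p(z|c))
#                   + sum_c gamma_c (log pi_c - log gamma_c)
# where gamma = q(c|x) is set to its variational optimum
# gamma_c  %prop%  pi_c exp(-KL(q(z|x) || p(z|c))), which makes treating it as
# constant in the network gradients exact (envelope argument). Network
# weights follow AdamW; the mixture parameters take closed-form
# coordinate-ascent (M-step) updates once per epoch from the accumulated
# responsibilities.

#' Configuration for the convolutional mixture VAE
#'
#' @param latent_dim Latent dimensionality.
#' @param components Number of mixture components; overparameterizing (more
#'   components than expected populations) is encouraged — unused components
#'   have their prior weight driven toward zero during training.
#' @param likelihood `"poisson"` (count reconstruction, default) or
#'   `"bernoulli"` (presence/absence).
#' @param enc_filters,dec_filters Filters of the 4 encoder/decoder blocks,
#'   each block being two 3x3 convolutions; the second encoder convolution of
#'   each block has stride (1, 2).
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled weight decay on convolution/dense weights.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param warmup_frac Fraction of epochs trained on reconstruction only
#'   before the mixture prior is initialized from the latents.
#' @param seed Integer seed controlling initialization, batching, and
#'   sampling.
#' @return A `va3de_config` list.
#' @export
va3de_config <- function(latent_dim = 10, components = 10,
                         likelihood = c("poisson", "bernoulli"),
                         enc_filters = c(4, 8, 16, 32),
                         dec_filters = c(32, 16, 8, 4),
                         lr = 3e-4, weight_decay = 1e-4, epochs = 50,
                         batch_size = 32, warmup_frac = 0.2, seed = 1L) {
  likelihood <- match.arg(likelihood)
  if (components < 1) abort("`components` must be >= 1.")
  if (lr <= 0) abort("`lr` must be > 0.")
  structure(list(latent_dim = as.integer(latent_dim),
                 components = as.integer(components),
                 likelihood = likelihood,
                 enc_filters = as.integer(enc_filters),
                 dec_filters = as.integer(dec_filters),
                 lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 warmup_frac = warmup_frac, seed = as.integer(seed)),
            class = "va3de_config")
}

#' Build stacked band images
#'
#' Lays the first `k` strata of each cell's per-chromosome contact matrices
#' into a `k x L` image (`L` = total genome bins, chromosomes concatenated in
#' order, positions past a chromosome's end left at zero).
#'
#' @param contacts Contact tibble.
#' @param bins Named integer vector of bins per chromosome.
#' @param k Number of strata (rows).
#' @param resolution Bin size in bp.
#' @return A `schic_band_images` object (list of `k x L` matrices, one per
#'   cell, plus layout metadata).
#' @export
build_band_images <- function(contacts, bins, k, resolution = NULL) {
  res <- contacts_resolution(contacts, resolution)
  if (k < 1) abort("`k` must be >= 1.")
  if (k > min(bins)) {
    abort(sprintf("k = %d exceeds the smallest chromosome (%d bins); use a smaller k.",
                  k, min(bins)))
  }
  ids <- cell_ids(contacts)
  L <- sum(bins)
  offs <- c(0L, cumsum(bins))[seq_along(bins)]
  names(offs) <- names(bins)
  df <- contacts[contacts$bin2 - contacts$bin1 < k, , drop = FALSE]
  imgs <- lapply(ids, function(id) {
    sub <- df[df$cell_id == id, , drop = FALSE]
    img <- matrix(0, k, L)
    if (nrow(sub)) {
      img[cbind(sub$bin2 - sub$bin1 + 1L, offs[sub$chrom] + sub$bin1 + 1L)] <-
        sub$count
    }
    img
  })
  structure(list(images = imgs, cell_ids = ids, k = as.integer(k),
                 bins = bins, resolution = res),
            class = "schic_band_images")
}

#' @export
print.schic_band_images <- function(x, ...) {
  cat(sprintf("<schic_band_images> %d cells, %d x %d strata images\n",
              length(x$images), x$k, ncol(x$images[[1]])))
  invisible(x)
}

# ---- architecture ---------------------------------------------------------

va3de_architecture <- function(cfg, k, L) {
  enc <- list()
  cin <- 1L
  W <- L
  for (b in seq_along(cfg$enc_filters)) {
    f <- cfg$enc_filters[b]
    enc[[length(enc) + 1]] <- nn_conv(sprintf("enc_b%d_c1_W", b),
                                      sprintf("enc_b%d_c1_b", b), cin, f)
    enc[[length(enc) + 1]] <- nn_conv(sprintf("enc_b%d_c2_W", b),
                                      sprintf("enc_b%d_c2_b", b), f, f,
                                      sh = 1L, sw = 2L)
    cin <- f
    W <- ceiling(W / 2)
  }
  dec <- list()
  cin <- cfg$dec_filters[1]
  for (b in seq_along(cfg$dec_filters)) {
    f <- cfg$dec_filters[b]
    dec[[length(dec) + 1]] <- nn_upsample_w()
    dec[[length(dec) + 1]] <- nn_conv(sprintf("dec_b%d_c1_W", b),
                                      sprintf("dec_b%d_c1_b", b), cin, f)
    dec[[length(dec) + 1]] <- nn_conv(sprintf("dec_b%d_c2_W", b),
                                      sprintf("dec_b%d_c2_b", b), f, f)
    cin <- f
  }
  dec[[length(dec) + 1]] <- nn_crop_w(L)
  dec[[length(dec) + 1]] <- nn_conv("dec_out_W", "dec_out_b", cin, 1L,
                                    act = "linear", kh = 1L, kw = 1L)
  list(enc = enc, dec = dec, bottleneck = c(k, W, utils::tail(cfg$enc_filters, 1)))
}

va3de_init_params <- function(cfg, arch, flat_dim) {
  params <- list()
  rgen <- function(n) rnorm(n)
  for (l in c(arch$enc, arch$dec)) {
    if (l$type == "conv") params <- nn_init_conv(params, l, rgen)
  }
  dz <- cfg$latent_dim
  params$enc_dense_W <- matrix(rnorm(2 * dz * flat_dim) * sqrt(2 / flat_dim),
                               2 * dz, flat_dim)
  params$enc_dense_b <- numeric(2 * dz)
  params$dec_dense_W <- matrix(rnorm(flat_dim * dz) * sqrt(2 / dz),
                               flat_dim, dz)
  params$dec_dense_b <- numeric(flat_dim)
  params
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- mixture prior --------------------------------------------------------

# KL(q(z|x_i) || p(z|c)) for diagonal Gaussians; returns B x C.
gmm_kl_matrix <- function(mu, logv, gmm) {
  v <- exp(logv)
  B <- nrow(mu)
  C <- length(gmm$pi)
  out <- matrix(0, B, C)
  for (c in seq_len(C)) {
    vc <- exp(gmm$logvar[c, ])
    dmu <- sweep(mu, 2, gmm$mu[c, ])
    out[, c] <- 0.5 * (sum(gmm$logvar[c, ]) - rowSums(logv) +
                         (v + dmu^2) %*% (1 / vc) - ncol(mu))
  }
  out
}

# Variational optimum q(c|x): softmax of log pi_c - KL_c.
gmm_responsibilities <- function(klm, gmm) {
  lg <- sweep(-klm, 2, log(pmax(gmm$pi, 1e-300)), "+")
  lg <- lg - apply(lg, 1, max)
  g <- exp(lg)
  g / rowSums(g)
}

# Bayes posterior p(c|z) under the mixture prior for point latents z.
gmm_posterior <- function(z, gmm) {
  C <- length(gmm$pi)
  lp <- matrix(0, nrow(z), C)
  for (c in seq_len(C)) {
    vc <- exp(gmm$logvar[c, ])
    dmu <- sweep(z, 2, gmm$mu[c, ])
    lp[, c] <- log(pmax(gmm$pi[c], 1e-300)) -
      0.5 * (sum(gmm$logvar[c, ]) + rowSums(sweep(dmu^2, 2, vc, "/")))
  }
  lp <- lp - apply(lp, 1, max)
  g <- exp(lp)
  g / rowSums(g)
}

# Small diagonal-covariance EM used to initialize the prior from warm-up
# latents.
gmm_em_fit <- function(x, C, iters = 30, var_floor = 1e-3) {
  N <- nrow(x)
  km <- kmeans(x, centers = min(C, N), nstart = 5, iter.max = 50)
  mu <- km$centers
  if (nrow(mu) < C) mu <- mu[rep(seq_len(nrow(mu)), length.out = C), , drop = FALSE]
  gmm <- list(pi = rep(1 / C, C), mu = mu,
              logvar = matrix(log(max(mean(apply(x, 2, var)), var_floor)),
                              C, ncol(x)))
  for (it in seq_len(iters)) {
    g <- gmm_posterior(x, gmm)
    nk <- colSums(g)
    keep <- nk > 1e-8
    gmm$pi <- pmax(nk / N, 1e-10)
    gmm$pi <- gmm$pi / sum(gmm$pi)
    for (c in which(keep)) {
      gmm$mu[c, ] <- colSums(g[, c] * x) / nk[c]
      vc <- colSums(g[, c] * sweep(x, 2, gmm$mu[c, ])^2) / nk[c]
      gmm$logvar[c, ] <- log(pmax(vc, var_floor))
    }
  }
  gmm
}

# ---- forward / backward passes -------------------------------------------

encode_batch <- function(model, imgs, want_cache = FALSE) {
  k <- model$k
  L <- model$L
  expo <- image_exposures(model, imgs)
  xs <- lapply(seq_along(imgs),
               function(i) array(imgs[[i]] / expo[i], c(k, L, 1)))
  fw <- stack_forward_batch(xs, model$arch$enc, model$params)
  H <- t(vapply(fw$out, as.vector, numeric(model$flat_dim)))
  caches <- if (want_cache) fw$caches
  A <- H %*% t(model$params$enc_dense_W)
  A <- sweep(A, 2, model$params$enc_dense_b, "+")
  dz <- model$config$latent_dim
  list(mu = A[, seq_len(dz), drop = FALSE],
       logv = pmin(pmax(A[, dz + seq_len(dz), drop = FALSE], -10), 10),
       H = H, caches = caches)
}

decode_batch <- function(model, z, want_cache = FALSE) {
  pre <- z %*% t(model$params$dec_dense_W)
  pre <- sweep(pre, 2, model$params$dec_dense_b, "+")
  Hd <- pmax(pre, 0)
  bo <- model$arch$bottleneck
  B <- nrow(z)
  xs <- lapply(seq_len(B), function(i) array(Hd[i, ], bo))
  fw <- stack_forward_batch(xs, model$arch$dec, model$params)
  outs <- lapply(fw$out, function(o) o[, , 1])
  caches <- if (want_cache) fw$caches
  list(o = outs, pre = pre, caches = caches)
}

# `s` is the per-cell exposure (size factor): the decoder emits a
# depth-free rate map and the likelihood scales it by `s`, so the latent
# space is not spent on sequencing depth.
recon_nll <- function(x, o, likelihood, s = 1) {
  if (likelihood == "poisson") {
    rate <- s * (softplus(o) + 1e-6)
    sum(rate - x * log(rate) + lgamma(x + 1))
  } else {
    xb <- as.numeric(x > 0)
    sum(softplus(o) - xb * o)
  }
}

recon_grad <- function(x, o, likelihood, s = 1) {
  if (likelihood == "poisson") {
    rate <- s * (softplus(o) + 1e-6)
    (s - x * s / rate) * sigmoid(o)
  } else {
    sigmoid(o) - as.numeric(x > 0)
  }
}

# Exposures relative to the model's training mean depth; encoder inputs are
# divided by them, decoder rates multiplied.
image_exposures <- function(model, imgs) {
  tot <- vapply(imgs, sum, numeric(1))
  pmax(tot, 1) / model$exposure_mean
}

# ---- training -------------------------------------------------------------

#' Train the convolutional mixture VAE
#'
#' Trains with Adam (decoupled weight decay) on the negative ELBO. The first
#' `warmup_frac` of epochs optimize reconstruction only (deterministic
#' latents); the mixture prior is then initialized by EM on the warm-up
#' latents and trained jointly, its parameters taking closed-form M-step
#' updates once per epoch. Fully deterministic under the config seed.
#'
#' @param images A `schic_band_images` object.
#' @param config A [va3de_config()].
#' @return A `schic_va3de` model with the training log (tibble of epoch,
#'   loss, nll, kl; loss = -ELBO per cell) in `$log`.
#' @export
va3de_train <- function(images, config = va3de_config()) {
  imgs <- images$images
  N <- length(imgs)
  k <- images$k
  L <- ncol(imgs[[1]])
  arch <- va3de_architecture(config, k, L)
  flat_dim <- prod(arch$bottleneck)
  expo_mean <- mean(vapply(imgs, sum, numeric(1)))
  dz <- config$latent_dim
  C <- config$components
  warm_epochs <- ceiling(config$epochs * config$warmup_frac)
  model <- NULL
  log_rows <- list()
  with_seed(config$seed, {
    params <- va3de_init_params(config, arch, flat_dim)
    model <- structure(list(config = config, arch = arch, params = params,
                            k = k, L = L, flat_dim = flat_dim,
                            exposure_mean = expo_mean, gmm = NULL),
                       class = "schic_va3de")
    state <- adam_state(params)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(N)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_nll <- 0
      ep_kl <- 0
      resp_n <- numeric(C)
      resp_mu <- matrix(0, C, dz)
      resp_m2 <- matrix(0, C, dz)
      for (bi in batches) {
        st <- va3de_step(model, imgs[bi], state,
                         joint = epoch > warm_epochs)
        model$params <- st$params
        state <- st$state
        ep_nll <- ep_nll + st$nll_sum
        ep_kl <- ep_kl + st$kl_sum
        if (!is.null(st$resp)) {
          resp_n <- resp_n + colSums(st$resp$g)
          resp_mu <- resp_mu + t(st$resp$g) %*% st$resp$mu
          resp_m2 <- resp_m2 + t(st$resp$g) %*% (st$resp$mu^2 +
                                                   exp(st$resp$logv))
        }
        if (!is.finite(st$nll_sum) || !is.finite(st$kl_sum)) {
          abort(sprintf(
            "Training diverged (non-finite loss) at epoch %d, seed %d.",
            epoch, config$seed))
        }
      }
      if (epoch == warm_epochs) {
        lat <- encode_batch(model, imgs)
        model$gmm <- gmm_em_fit(lat$mu, C)
      } else if (epoch > warm_epochs && sum(resp_n) > 0) {
        # closed-form coordinate ascent on the mixture parameters
        gmm <- model$gmm
        upd <- resp_n > 1e-8
        gmm$pi <- pmax(resp_n / sum(resp_n), 1e-10)
        gmm$pi <- gmm$pi / sum(gmm$pi)
        for (c in which(upd)) {
          gmm$mu[c, ] <- resp_mu[c, ] / resp_n[c]
          vc <- resp_m2[c, ] / resp_n[c] - gmm$mu[c, ]^2
          gmm$logvar[c, ] <- log(pmax(vc, 1e-3))
        }
        model$gmm <- gmm
      }
      log_rows[[epoch]] <- tibble(epoch = epoch, nll = ep_nll / N,
                                  kl = ep_kl / N,
                                  loss = (ep_nll + ep_kl) / N,
                                  elbo = -(ep_nll + ep_kl) / N)
    }
  })
  model$log <- bind_rows(log_rows)
  model
}

# One minibatch gradient step. Returns updated params/state plus loss sums
# and (joint phase) responsibility statistics for the epoch-level M-step.
va3de_step <- function(model, imgs, state, joint) {
  cfg <- model$config
  B <- length(imgs)
  dz <- cfg$latent_dim
  enc <- encode_batch(model, imgs, want_cache = TRUE)
  mu <- enc$mu
  logv <- enc$logv
  if (joint) {
    eps <- matrix(rnorm(B * dz), B, dz)
    z <- mu + exp(0.5 * logv) * eps
    klm <- gmm_kl_matrix(mu, logv, model$gmm)
    g <- gmm_responsibilities(klm, model$gmm)
    lpi <- log(pmax(model$gmm$pi, 1e-300))
    kl_i <- rowSums(g * klm) +
      rowSums(g * (log(pmax(g, 1e-300)) - rep(lpi, each = B)))
  } else {
    z <- mu
    kl_i <- numeric(B)
  }
  dec <- decode_batch(model, z, want_cache = TRUE)
  grads <- new.env(parent = emptyenv())
  expo <- image_exposures(model, imgs)
  nll_sum <- 0
  das <- vector("list", B)
  for (i in seq_len(B)) {
    nll_sum <- nll_sum + recon_nll(imgs[[i]], dec$o[[i]], cfg$likelihood,
                                   expo[i])
    do <- recon_grad(imgs[[i]], dec$o[[i]], cfg$likelihood, expo[i])
    das[[i]] <- array(do, c(dim(do), 1))
  }
  dxs <- stack_backward_batch(das, model$arch$dec, model$params, dec$caches,
                              grads)
  dHd <- t(vapply(dxs, as.vector, numeric(model$flat_dim)))
  dHd_pre <- dHd * (dec$pre > 0)
  grads$dec_dense_W <- t(dHd_pre) %*% z
  grads$dec_dense_b <- colSums(dHd_pre)
  dz_grad <- dHd_pre %*% model$params$dec_dense_W
  if (joint) {
    # KL gradients on the variational Gaussian (responsibilities constant)
    dmu_kl <- matrix(0, B, dz)
    inv_sum <- matrix(0, B, dz)
    for (c in seq_along(model$gmm$pi)) {
      vc <- exp(model$gmm$logvar[c, ])
      dmu_kl <- dmu_kl + g[, c] * sweep(mu, 2, model$gmm$mu[c, ]) /
        rep(vc, each = B)
      inv_sum <- inv_sum + g[, c] %o% (1 / vc)
    }
    dlogv <- 0.5 * (exp(logv) * inv_sum - 1)
    dmu <- dz_grad + dmu_kl
    dlogv <- dlogv + dz_grad * eps * 0.5 * exp(0.5 * logv)
  } else {
    dmu <- dz_grad
    dlogv <- matrix(0, B, dz)
  }
  dlogv[abs(logv) >= 10] <- 0 # clamped
  dA <- cbind(dmu, dlogv)
  grads$enc_dense_W <- t(dA) %*% enc$H
  grads$enc_dense_b <- colSums(dA)
  dH <- dA %*% model$params$enc_dense_W
  bo <- model$arch$bottleneck
  stack_backward_batch(lapply(seq_len(B), function(i) array(dH[i, ], bo)),
                       model$arch$enc, model$params, enc$caches, grads)
  glist <- as.list(grads)
  glist <- lapply(glist, function(g) g / B)
  st <- adam_step(model$params, glist, state, lr = cfg$lr,
                  weight_decay = cfg$weight_decay,
                  decay_on = grep("_W$", names(glist), value = TRUE))
  list(params = st$params, state = st$state, nll_sum = nll_sum,
       kl_sum = sum(kl_i),
       resp = if (joint) list(g = g, mu = mu, logv = logv))
}

# ---- inference ------------------------------------------------------------

check_images <- function(model, images) {
  if (images$k != model$k || ncol(images$images[[1]]) != model$L) {
    abort(sprintf("Image shape %d x %d does not match the trained model (%d x %d).",
                  images$k, ncol(images$images[[1]]), model$k, model$L))
  }
}

#' Encode band images to latent Gaussians
#'
#' @param model A trained `schic_va3de`.
#' @param images A `schic_band_images` with the training layout.
#' @return List with `mu` and `logvar` matrices (cells x latent dims).
#' @export
va3de_encode <- function(model, images) {
  check_images(model, images)
  enc <- encode_batch(model, images$images)
  list(mu = enc$mu, logvar = enc$logv)
}

#' Decode latent points to reconstruction parameters
#'
#' @param model A trained `schic_va3de`.
#' @param z Matrix of latent points (rows = cells).
#' @return List of `k x L` matrices of raw decoder outputs (pre-likelihood
#'   link).
#' @export
va3de_decode <- function(model, z) {
  decode_batch(model, as.matrix(z))$o
}

#' Evidence lower bound of a batch
#'
#' Deterministic bound using the posterior means as latents: per-cell Poisson
#' (or Bernoulli) reconstruction NLL plus the mixture KL term. With a single
#' unit component the KL reduces to the standard Gaussian VAE term.
#'
#' @param model A trained (or freshly initialized) `schic_va3de` whose `gmm`
#'   field is set.
#' @param images A `schic_band_images`.
#' @return List with `elbo`, `nll`, `kl` (means per cell) and `per_cell`, a
#'   tibble of per-cell terms.
#' @export
va3de_elbo <- function(model, images) {
  check_images(model, images)
  if (is.null(model$gmm)) abort("Model has no mixture prior yet.")
  enc <- encode_batch(model, images$images)
  dec <- decode_batch(model, enc$mu)
  expo <- image_exposures(model, images$images)
  nll_i <- vapply(seq_along(images$images), function(i) {
    recon_nll(images$images[[i]], dec$o[[i]], model$config$likelihood,
              expo[i])
  }, numeric(1))
  klm <- gmm_kl_matrix(enc$mu, enc$logv, model$gmm)
  g <- gmm_responsibilities(klm, model$gmm)
  lpi <- log(pmax(model$gmm$pi, 1e-300))
  kl_i <- rowSums(g * klm) +
    rowSums(g * (log(pmax(g, 1e-300)) - rep(lpi, each = nrow(g))))
  if (any(!is.finite(nll_i))) abort("Non-finite reconstruction NLL term.")
  if (any(!is.finite(kl_i))) abort("Non-finite KL term.")
  list(elbo = -mean(nll_i + kl_i), nll = mean(nll_i), kl = mean(kl_i),
       per_cell = tibble(cell_id = images$cell_ids, nll = nll_i, kl = kl_i))
}

#' Embed cells with a trained model
#'
#' Coordinates are the posterior means of `q(z|x)`; soft cluster
#' responsibilities are the Bayes posterior over mixture components at those
#' points.
#'
#' @param model A trained `schic_va3de`.
#' @param images A `schic_band_images` with the training layout.
#' @return List with `embedding` (a `schic_embedding`) and `responsibilities`
#'   (cells x components matrix, rows summing to 1).
#' @export
va3de_embed <- function(model, images) {
  check_images(model, images)
  enc <- encode_batch(model, images$images)
  resp <- if (!is.null(model$gmm)) gmm_posterior(enc$mu, model$gmm)
  e <- new_embedding(enc$mu, images$cell_ids,
                     list(backend = "va3de", resolution = images$resolution,
                          d = model$config$latent_dim,
                          seed = model$config$seed,
                          k = images$k))
  list(embedding = e, responsibilities = resp)
}

#' @export
print.schic_va3de <- function(x, ...) {
  cat(sprintf(
    "<schic_va3de> %d x %d images -> %d latent dims, %d mixture components\n",
    x$k, x$L, x$config$latent_dim, x$config$components))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d epochs, final loss %.2f per cell\n",
                nrow(x$log), x$log$loss[nrow(x$log)]))
  }
  invisible(x)
}

#' Save / load a trained model
#'
#' The model is an ordinary R list (configuration, parameter arrays, mixture
#' prior, training log) serialized with `saveRDS`.
#'
#' @param model A `schic_va3de`.
#' @param path File path.
#' @return `va3de_load` returns the model; `va3de_save` its path, invisibly.
#' @export
va3de_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname va3de_save
#' @export
va3de_load <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "schic_va3de")) abort("Not a saved schic_va3de model.")
  m
}
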