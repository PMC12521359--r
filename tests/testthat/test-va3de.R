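small_images <- function(n = 8, k = 4, L = 16, seed = 3, equal_depth = TRUE) {
  set.seed(seed)
  imgs <- lapply(seq_len(n), function(i) {
    m <- matrix(rpois(k * L, 1.2), k, L)
    if (equal_depth) {
      # equalize totals so per-cell exposures are exactly 1
      while (sum(m) > 60) m[which(m > 0)[1]] <- m[which(m > 0)[1]] - 1
      while (sum(m) < 60) m[1, 1] <- m[1, 1] + 1
    }
    m
  })
  structure(list(images = imgs, cell_ids = sprintf("c%02d", seq_len(n)),
                 k = as.integer(k), bins = c(chr1 = L), resolution = 1e5),
            class = "schic_band_images")
}

tiny_model <- function(images, C = 1, dz = 3, seed = 2) {
  cfg <- va3de_config(latent_dim = dz, components = C, epochs = 1,
                      batch_size = 4, seed = seed)
  arch <- schicbench:::va3de_architecture(cfg, images$k,
                                          ncol(images$images[[1]]))
  flat <- prod(arch$bottleneck)
  set.seed(seed)
  params <- schicbench:::va3de_init_params(cfg, arch, flat)
  structure(list(config = cfg, arch = arch, params = params, k = images$k,
                 L = ncol(images$images[[1]]), flat_dim = flat,
                 exposure_mean = mean(vapply(images$images, sum, numeric(1))),
                 gmm = list(pi = rep(1 / C, C), mu = matrix(0, C, dz),
                            logvar = matrix(0, C, dz))),
            class = "schic_va3de")
}

test_that("band images lay strata out deterministically and conserve counts", {
  cells <- dplyr::bind_rows(
    ct("a", "chr1", c(2, 0, 5), c(3, 0, 9), c(1, 2, 7)),
    ct("b", "chr2", 1, 2, 4)
  )
  bins <- c(chr1 = 12L, chr2 = 10L)
  im <- build_band_images(cells, bins, k = 2, resolution = 1e5)
  a <- im$images[[1]]
  expect_equal(a[2, 3], 1)           # contact (2,3): stratum 1, column bin 2
  expect_equal(a[1, 1], 2)           # intra-bin contact at bin 0
  expect_equal(sum(a), 3)            # the d=4 contact is beyond k strata
  b <- im$images[[2]]
  expect_equal(b[2, 12 + 2], 4)      # chr2 offset by chr1's 12 bins
  # identical cells yield identical images
  cells2 <- dplyr::bind_rows(cells, dplyr::mutate(
    cells[cells$cell_id == "a", ], cell_id = "a2"))
  im2 <- build_band_images(cells2, bins, k = 2, resolution = 1e5)
  expect_identical(im2$images[[1]], im2$images[[3]])
  expect_error(build_band_images(cells, bins, k = 11, resolution = 1e5),
               "smaller k")
})

test_that("truncating then imaging equals imaging then zeroing distal rows", {
  d <- tiny_dataset(seed = 16, n = 3, bins_per_chrom = 30)
  k <- 6
  tr <- truncate_distance(d$contacts, 0, 4 * d$resolution, d$resolution)
  im1 <- build_band_images(tr, d$bins, k, d$resolution)
  im2 <- build_band_images(d$contacts, d$bins, k, d$resolution)
  im2$images <- lapply(im2$images, function(m) {
    m[5:6, ] <- 0
    m
  })
  expect_equal(im1$images, im2$images)
})

test_that("the mixture ELBO reduces to the plain VAE bound for one unit component", {
  im <- small_images()
  model <- tiny_model(im, C = 1)
  got <- va3de_elbo(model, im)
  # independent computation from encoder/decoder outputs
  enc <- va3de_encode(model, im)
  dec <- va3de_decode(model, enc$mu)
  nll <- vapply(seq_along(im$images), function(i) {
    rate <- log1p(exp(dec[[i]])) + 1e-6
    x <- im$images[[i]]
    sum(rate - x * log(rate) + lgamma(x + 1))
  }, numeric(1))
  kl <- rowSums(-0.5 * (1 + enc$logvar - enc$mu^2 - exp(enc$logvar)))
  expect_equal(got$nll, mean(nll), tolerance = 1e-6)
  expect_equal(got$kl, mean(kl), tolerance = 1e-6)
  expect_equal(got$elbo, -mean(nll + kl), tolerance = 1e-6)
})

test_that("likelihood terms match closed forms", {
  # Poisson NLL of observing 0 under rate 1 is 1 nat
  o <- log(expm1(1 - 1e-6))
  expect_equal(schicbench:::recon_nll(matrix(0), matrix(o), "poisson"), 1,
               tolerance = 1e-9)
  # KL between identical Gaussians is 0
  gmm <- list(pi = 1, mu = matrix(c(0.3, -1), 1), logvar = matrix(c(0.2, 0.1), 1))
  klm <- schicbench:::gmm_kl_matrix(matrix(c(0.3, -1), 1),
                                    matrix(c(0.2, 0.1), 1), gmm)
  expect_equal(as.numeric(klm), 0, tolerance = 1e-12)
})

test_that("training is deterministic, loss decreases, and ELBO ignores cell order", {
  im <- small_images(n = 12, equal_depth = FALSE)
  cfg <- va3de_config(latent_dim = 3, components = 2, epochs = 4,
                      batch_size = 4, lr = 1e-3, seed = 5)
  fit1 <- va3de_train(im, cfg)
  fit2 <- va3de_train(im, cfg)
  expect_equal(fit1$log$loss[4], fit2$log$loss[4], tolerance = 1e-6)
  expect_lt(fit1$log$nll[4], fit1$log$nll[1])

  # per-cell ELBO terms are invariant to batch order
  perm <- c(5:12, 1:4)
  imp <- im
  imp$images <- im$images[perm]
  imp$cell_ids <- im$cell_ids[perm]
  e1 <- va3de_elbo(fit1, im)$per_cell
  e2 <- va3de_elbo(fit1, imp)$per_cell
  expect_equal(e2$nll, e1$nll[perm], tolerance = 1e-9)

  # embedding contract
  out <- va3de_embed(fit1, im)
  expect_equal(rowSums(out$responsibilities), rep(1, 12), tolerance = 1e-6)
  imdup <- im
  imdup$images[[2]] <- imdup$images[[1]]
  e <- va3de_embed(fit1, imdup)$embedding
  x <- embedding_coords(e)
  expect_equal(x[1, ], x[2, ], ignore_attr = TRUE)

  imbad <- small_images(k = 5, L = 16)
  expect_error(va3de_embed(fit1, imbad), "shape")
})
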