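# A compact configuration used throughout: 256-bin histograms on 16x16
# images with a two-level network keeps every training run in seconds.
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(side = 16, depth = 2, base_channels = 8, n_pairs = 60,
         epochs = 4, batch_size = 8, learning_rate = 2e-3, seed = 77),
    list(...))
  do.call(denoiser_spec, args)
}
tiny_gt <- small_gt(bins = 256, cps = 800)

test_that("backpropagation matches finite-difference gradients", {
  spec <- denoiser_spec(side = 8, depth = 2, base_channels = 3, seed = 5)
  set.seed(8)
  p <- cnstherm:::unet_init(spec)
  g <- cnstherm:::unet_geometry(8, 2, 2L)
  X <- matrix(runif(128), ncol = 1)
  Y <- matrix(runif(128), ncol = 1)
  fw <- cnstherm:::unet_forward(p, X, g, keep_cache = TRUE)
  dOut <- 2 * (fw$out - Y) / length(Y)
  gr <- cnstherm:::unet_backward(p, fw$cache, g, dOut)
  loss <- function(p) mean((cnstherm:::unet_forward(p, X, g)$out - Y)^2)
  eps <- 1e-6
  paths <- list(
    list(g = function(p) p$enc[[1]]$a$W,
         s = function(p, v) { p$enc[[1]]$a$W[] <- v; p },
         a = gr$enc[[1]]$a$W),
    list(g = function(p) p$enc[[2]]$b$W,
         s = function(p, v) { p$enc[[2]]$b$W[] <- v; p },
         a = gr$enc[[2]]$b$W),
    list(g = function(p) p$dec[[1]]$up$W,
         s = function(p, v) { p$dec[[1]]$up$W[] <- v; p },
         a = gr$dec[[1]]$up$W),
    list(g = function(p) p$out$W,
         s = function(p, v) { p$out$W[] <- v; p },
         a = gr$out$W),
    list(g = function(p) p$dec[[1]]$a$b,
         s = function(p, v) { p$dec[[1]]$a$b[] <- v; p },
         a = gr$dec[[1]]$a$b))
  for (ck in paths) {
    v0 <- ck$g(p)
    ii <- sample(length(v0), min(4, length(v0)))
    for (i in ii) {
      pp <- p; v <- ck$g(pp); v[i] <- v[i] + eps; pp <- ck$s(pp, v)
      pm <- p; v <- ck$g(pm); v[i] <- v[i] - eps; pm <- ck$s(pm, v)
      fd <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(ck$a[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training on identical input/target pairs drives the loss to ~0", {
  spec <- tiny_spec(epochs = 6)
  pairs <- make_training_pairs(tiny_gt, spec, n_pairs = 40, seed = 31)
  pairs$x <- pairs$y   # identity task on clean images
  dn <- train_denoiser(spec, pairs = pairs)
  expect_lt(utils::tail(dn$val_rmse, 1), 0.02)
})

test_that("validation loss decreases over the first epochs", {
  spec <- tiny_spec(epochs = 5)
  dn <- train_denoiser(spec, gt = tiny_gt)
  expect_lt(dn$val_rmse[5], dn$val_rmse[1])
  expect_lt(min(diff(dn$val_rmse)), 0)  # improving, not flat
})

test_that("training is seed-reproducible", {
  spec <- tiny_spec(n_pairs = 20, epochs = 2)
  d1 <- train_denoiser(spec, gt = tiny_gt)
  d2 <- train_denoiser(spec, gt = tiny_gt)
  expect_identical(d1$params, d2$params)
  expect_identical(d1$val_rmse, d2$val_rmse)
})

test_that("denoise validates shapes, preserves metadata and flags zero images", {
  spec <- tiny_spec(n_pairs = 20, epochs = 1)
  dn <- train_denoiser(spec, gt = tiny_gt)
  cv <- simulate_decay(tiny_gt, 614, 36.5, integration_time = 0.1,
                       seed = 9)
  img <- spiral_encode(cv, 16)
  out <- denoise(dn, img)
  expect_s3_class(out, "spiral_image")
  expect_true(all(out$pixels >= 0))
  expect_equal(out$bin_width, img$bin_width)
  expect_equal(out$scale, img$scale)
  expect_equal(out$path_spec, img$path_spec)
  img32 <- spiral_encode(simulate_decay(fx_gt, 614, 36.5, seed = 2), 32)
  expect_error(denoise(dn, img32), "does not match")
  zero <- img; zero$pixels[] <- 0
  expect_warning(z <- denoise(dn, zero), "all-zero")
  expect_equal(z$pixels, zero$pixels)
})

test_that("a trained model denoises: lower image RMSE and near-identity on clean input", {
  # single short integration time: the photon-starved regime where
  # denoising has something to gain
  spec <- tiny_spec(n_pairs = 200, epochs = 15, integration_times = 0.1)
  pairs <- make_training_pairs(tiny_gt, spec, seed = 55)
  dn <- train_denoiser(spec, pairs = pairs)
  # held-out noisy/clean pairs
  test_pairs <- make_training_pairs(tiny_gt, spec, n_pairs = 30,
                                    seed = 991)
  g1 <- cnstherm:::unet_geometry(16, 2, 1L)
  rmse_in <- rmse_out <- clean_dev <- numeric(30)
  for (i in seq_len(30)) {
    x <- test_pairs$x[i, ]; y <- test_pairs$y[i, ]
    o <- cnstherm:::unet_forward(dn$params, matrix(x, ncol = 1), g1)$out
    rmse_in[i] <- sqrt(mean((x - y)^2))
    rmse_out[i] <- sqrt(mean((pmax(o, 0) - y)^2))
    oc <- cnstherm:::unet_forward(dn$params, matrix(y, ncol = 1), g1)$out
    clean_dev[i] <- sqrt(mean((pmax(oc, 0) - y)^2))
  }
  expect_gt(mean(rmse_in > rmse_out), 0.9)   # denoising helps
  expect_lt(mean(clean_dev), 0.05)           # near-identity on clean data
})

test_that("trained models serialize and reload", {
  spec <- tiny_spec(n_pairs = 20, epochs = 1)
  dn <- train_denoiser(spec, gt = tiny_gt)
  p <- withr::local_tempfile(fileext = ".rds")
  save_denoiser(dn, p)
  dn2 <- load_denoiser(p)
  expect_identical(dn2$params, dn$params)
})

test_that("degenerate training sets are rejected", {
  spec <- tiny_spec()
  expect_error(train_denoiser(spec, pairs = list(x = matrix(0, 2, 256),
                                                 y = matrix(0, 2, 256))),
               "degenerate")
  expect_error(train_denoiser(spec), "supply")
})
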