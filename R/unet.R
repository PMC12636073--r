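# U-shaped convolutional denoiser for spiral-encoded decay images,
# implemented natively on BLAS matrix operations. Feature maps are stored
# as (batch * side^2) x channels matrices in image-column-major pixel
# order; 3x3 convolutions are evaluated by gathering the nine shifted
# copies of the map (im2col) and a single matrix multiplication.

#' Denoiser training specification
#'
#' Architecture and training hyper-parameters of the spiral-image
#' denoiser: a U-shaped encoder/decoder with 3x3 convolutions, 2x2 max
#' pooling, nearest-neighbour upsampling and skip connections, trained
#' with root-mean-square error against long-integration ground-truth
#' images.
#'
#' @param side Input image side in pixels (divisible by `2^(depth-1)`).
#' @param depth Number of resolution levels (>= 2; default 3).
#' @param base_channels Channels at the finest level; doubled per level.
#' @param temperatures Training temperatures in degrees C.
#' @param integration_times Noisy-acquisition integration times in s.
#' @param wavelength Emission wavelength in nm.
#' @param ground_truth_integration Integration time in s whose noiseless
#'   expectation serves as the clean reference (default 300).
#' @param n_pairs Number of training pairs to generate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param val_fraction Fraction of pairs held out for validation.
#' @param seed Integer seed for pair generation, weight initialization and
#'   shuffling.
#' @return An object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(side = 32, depth = 3, base_channels = 16,
                          temperatures = seq(36, 39, by = 0.5),
                          integration_times = c(0.1, 0.3, 1.1),
                          wavelength = 614,
                          ground_truth_integration = 300,
                          n_pairs = 2000, epochs = 12, batch_size = 16,
                          learning_rate = 1e-3, val_fraction = 0.15,
                          seed = 1) {
  if (depth < 2) stop("`depth` must be >= 2", call. = FALSE)
  if (side %% 2^(depth - 1) != 0) {
    stop("`side` must be divisible by 2^(depth-1)", call. = FALSE)
  }
  structure(list(side = side, depth = depth, base_channels = base_channels,
                 temperatures = temperatures,
                 integration_times = integration_times,
                 wavelength = wavelength,
                 ground_truth_integration = ground_truth_integration,
                 n_pairs = n_pairs, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 val_fraction = val_fraction, loss = "rmse", seed = seed),
            class = "denoiser_spec")
}

#' @export
print.denoiser_spec <- function(x, ...) {
  cat(sprintf(
    "<denoiser_spec: %dx%d input, depth %d, base %d ch; %d pairs, %d epochs, lr %g, RMSE loss>\n",
    x$side, x$side, x$depth, x$base_channels, x$n_pairs, x$epochs,
    x$learning_rate))
  invisible(x)
}

# ---- geometry -------------------------------------------------------------

conv_indices <- function(side, batch) {
  pix <- seq_len(side * side)
  r <- ((pix - 1L) %% side) + 1L
  cc <- ((pix - 1L) %/% side) + 1L
  off <- rep((seq_len(batch) - 1L) * side * side, each = side * side)
  lapply(seq_len(9L), function(o) {
    dr <- ((o - 1L) %% 3L) - 1L
    dc <- ((o - 1L) %/% 3L) - 1L
    rn <- r + dr; cn <- cc + dc
    ok <- rn >= 1L & rn <= side & cn >= 1L & cn <= side
    n <- ifelse(ok, rn + (cn - 1L) * side, 0L)
    nb <- rep(n, batch)
    pos <- nb > 0L
    nb[pos] <- nb[pos] + off[pos]
    nb
  })
}

pool_indices <- function(side, batch) {
  half <- side %/% 2L
  po <- seq_len(half * half)
  ro <- ((po - 1L) %% half) + 1L
  co <- ((po - 1L) %/% half) + 1L
  off <- rep((seq_len(batch) - 1L) * side * side, each = half * half)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
    rep(2L * ro - 1L + d[1] + (2L * co - 2L + d[2]) * side, batch) + off
  })
}

upsample_indices <- function(coarse_side, batch) {
  fine <- 2L * coarse_side
  pf <- seq_len(fine * fine)
  rf <- ((pf - 1L) %% fine) + 1L
  cf <- ((pf - 1L) %/% fine) + 1L
  u <- (rf + 1L) %/% 2L + (((cf + 1L) %/% 2L) - 1L) * coarse_side
  rep(u, batch) +
    rep((seq_len(batch) - 1L) * coarse_side * coarse_side, each = fine * fine)
}

unet_geometry <- function(side, depth, batch) {
  sides <- side / 2^(seq_len(depth) - 1L)
  list(batch = batch, sides = sides,
       conv = lapply(sides, conv_indices, batch = batch),
       pool = lapply(sides[-depth], pool_indices, batch = batch),
       up = lapply(sides[-1L], upsample_indices, batch = batch))
}

# ---- layers ---------------------------------------------------------------

conv_fwd <- function(X, W, b, idx) {
  C <- ncol(X)
  Xp <- rbind(0, X)
  cols <- matrix(0, nrow(X), 9L * C)
  for (o in seq_len(9L)) {
    cols[, ((o - 1L) * C + 1L):(o * C)] <- Xp[idx[[o]] + 1L, , drop = FALSE]
  }
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cols = cols)
}

conv_bwd <- function(dY, W, cache, idx, c_in) {
  grad_W <- crossprod(cache$cols, dY)
  grad_b <- colSums(dY)
  dcols <- dY %*% t(W)
  dX <- matrix(0, nrow(dY), c_in)
  for (o in seq_len(9L)) {
    v <- idx[[o]]
    pos <- which(v > 0L)
    block <- dcols[pos, ((o - 1L) * c_in + 1L):(o * c_in), drop = FALSE]
    dX[v[pos], ] <- dX[v[pos], ] + block
  }
  list(dX = dX, dW = grad_W, db = grad_b)
}

pool_fwd <- function(X, pidx) {
  M <- X[pidx[[1]], , drop = FALSE]
  sel <- matrix(1L, nrow(M), ncol(M))
  for (k in 2:4) {
    A <- X[pidx[[k]], , drop = FALSE]
    upd <- A > M
    M[upd] <- A[upd]
    sel[upd] <- k
  }
  list(out = M, sel = sel)
}

pool_bwd <- function(dY, sel, pidx, n_in) {
  dX <- matrix(0, n_in, ncol(dY))
  n_out <- nrow(dY)
  for (k in 1:4) {
    w <- which(sel == k)
    if (!length(w)) next
    r <- ((w - 1L) %% n_out) + 1L
    cc <- (w - 1L) %/% n_out
    dX[pidx[[k]][r] + cc * n_in] <- dY[w]
  }
  dX
}

up_fwd <- function(X, u) X[u, , drop = FALSE]

up_bwd <- function(dY, u) {
  out <- rowsum(dY, group = u)
  # rowsum sorts by group; groups cover 1..n_coarse completely
  out
}

# ---- parameters -----------------------------------------------------------

unet_init <- function(spec) {
  ch <- spec$base_channels * 2^(seq_len(spec$depth) - 1L)
  mk <- function(c_in, c_out, k = 9L) {
    list(W = matrix(stats::rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))),
                    k * c_in, c_out),
         b = rep(0, c_out))
  }
  p <- list(enc = list(), dec = list())
  c_prev <- 1L
  for (i in seq_len(spec$depth)) {
    p$enc[[i]] <- list(a = mk(c_prev, ch[i]), b = mk(ch[i], ch[i]))
    c_prev <- ch[i]
  }
  for (i in rev(seq_len(spec$depth - 1L))) {
    p$dec[[i]] <- list(up = mk(ch[i + 1L], ch[i]),
                       a = mk(2L * ch[i], ch[i]),
                       b = mk(ch[i], ch[i]))
  }
  p$out <- mk(ch[1L], 1L, k = 1L)
  p
}

# 1x1 convolution is a plain matrix product
conv1_fwd <- function(X, W, b) {
  out <- X %*% W
  list(out = out + rep(b, each = nrow(out)))
}

unet_forward <- function(p, X, g, keep_cache = FALSE) {
  d <- length(p$enc)
  cache <- list(enc = vector("list", d), dec = vector("list", d - 1L),
                X = X)
  skips <- vector("list", d)
  H <- X
  for (i in seq_len(d)) {
    ca <- conv_fwd(H, p$enc[[i]]$a$W, p$enc[[i]]$a$b, g$conv[[i]])
    ra <- pmax(ca$out, 0)
    cb <- conv_fwd(ra, p$enc[[i]]$b$W, p$enc[[i]]$b$b, g$conv[[i]])
    rb <- pmax(cb$out, 0)
    skips[[i]] <- rb
    if (keep_cache) {
      cache$enc[[i]] <- list(ca = ca, ra = ra, cb = cb, rb = rb)
    }
    if (i < d) {
      pl <- pool_fwd(rb, g$pool[[i]])
      if (keep_cache) cache$enc[[i]]$pool <- pl
      H <- pl$out
    } else H <- rb
  }
  for (i in rev(seq_len(d - 1L))) {
    uu <- up_fwd(H, g$up[[i]])
    cu <- conv_fwd(uu, p$dec[[i]]$up$W, p$dec[[i]]$up$b, g$conv[[i]])
    ru <- pmax(cu$out, 0)
    cat_in <- cbind(ru, skips[[i]])
    ca <- conv_fwd(cat_in, p$dec[[i]]$a$W, p$dec[[i]]$a$b, g$conv[[i]])
    ra <- pmax(ca$out, 0)
    cb <- conv_fwd(ra, p$dec[[i]]$b$W, p$dec[[i]]$b$b, g$conv[[i]])
    rb <- pmax(cb$out, 0)
    if (keep_cache) {
      cache$dec[[i]] <- list(uu = uu, cu = cu, ru = ru, cat_in = cat_in,
                             ca = ca, ra = ra, cb = cb, rb = rb)
    }
    H <- rb
  }
  outc <- conv1_fwd(H, p$out$W, p$out$b)
  if (keep_cache) {
    cache$head_in <- H
    list(out = outc$out, cache = cache)
  } else list(out = outc$out)
}

unet_backward <- function(p, cache, g, dOut) {
  d <- length(p$enc)
  grads <- list(enc = vector("list", d), dec = vector("list", d - 1L))
  grads$out <- list(W = crossprod(cache$head_in, dOut), b = colSums(dOut))
  dH <- dOut %*% t(p$out$W)
  dskips <- vector("list", d)
  for (i in seq_len(d - 1L)) {
    dc <- cache$dec[[i]]
    dH <- dH * (dc$cb$out > 0)
    gb <- conv_bwd(dH, p$dec[[i]]$b$W, dc$cb, g$conv[[i]],
                   c_in = ncol(dc$ra))
    dra <- gb$dX * (dc$ca$out > 0)
    ga <- conv_bwd(dra, p$dec[[i]]$a$W, dc$ca, g$conv[[i]],
                   c_in = ncol(dc$cat_in))
    half <- ncol(dc$ru)
    dru <- ga$dX[, seq_len(half), drop = FALSE]
    dskips[[i]] <- ga$dX[, half + seq_len(ncol(ga$dX) - half), drop = FALSE]
    dru <- dru * (dc$cu$out > 0)
    gu <- conv_bwd(dru, p$dec[[i]]$up$W, dc$cu, g$conv[[i]],
                   c_in = ncol(dc$uu))
    grads$dec[[i]] <- list(up = list(W = gu$dW, b = gu$db),
                           a = list(W = ga$dW, b = ga$db),
                           b = list(W = gb$dW, b = gb$db))
    # decoder levels are processed fine-to-coarse; dH moves to level i+1
    dH <- up_bwd(gu$dX, g$up[[i]])
  }
  # dH now carries the gradient into the bottleneck output (level d)
  for (i in rev(seq_len(d))) {
    ec <- cache$enc[[i]]
    if (i < d) {
      dpool <- pool_bwd(dH, ec$pool$sel, g$pool[[i]],
                        n_in = nrow(ec$rb))
      drb <- dpool + dskips[[i]]
    } else drb <- dH
    drb <- drb * (ec$cb$out > 0)
    gb <- conv_bwd(drb, p$enc[[i]]$b$W, ec$cb, g$conv[[i]],
                   c_in = ncol(ec$ra))
    dra <- gb$dX * (ec$ca$out > 0)
    ga <- conv_bwd(dra, p$enc[[i]]$a$W, ec$ca, g$conv[[i]],
                   c_in = ncol(cache_enc_input(cache, i)))
    grads$enc[[i]] <- list(a = list(W = ga$dW, b = ga$db),
                           b = list(W = gb$dW, b = gb$db))
    dH <- ga$dX
  }
  grads
}

cache_enc_input <- function(cache, i) {
  if (i == 1L) cache$X else cache$enc[[i - 1L]]$pool$out
}

# Flatten/apply utilities for the optimizer: walk the nested param list.
param_walk <- function(p, g, s1, s2, f) {
  rec <- function(p, g, s1, s2) {
    if (is.list(p) && !is.null(p$W)) return(f(p, g, s1, s2))
    out <- p
    for (nm in seq_along(p)) {
      r <- rec(p[[nm]], g[[nm]], s1[[nm]], s2[[nm]])
      out[[nm]] <- r$p
      s1[[nm]] <- r$s1
      s2[[nm]] <- r$s2
    }
    list(p = out, s1 = s1, s2 = s2)
  }
  rec(p, g, s1, s2)
}

zero_like <- function(p) {
  if (is.list(p) && !is.null(p$W)) {
    return(list(W = p$W * 0, b = p$b * 0))
  }
  lapply(p, zero_like)
}

adam_step <- function(p, grads, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  param_walk(p, grads, m, v, function(pp, gg, mm, vv) {
    mm$W <- beta1 * mm$W + (1 - beta1) * gg$W
    mm$b <- beta1 * mm$b + (1 - beta1) * gg$b
    vv$W <- beta2 * vv$W + (1 - beta2) * gg$W^2
    vv$b <- beta2 * vv$b + (1 - beta2) * gg$b^2
    pp$W <- pp$W - lr * (mm$W / corr1) / (sqrt(vv$W / corr2) + eps)
    pp$b <- pp$b - lr * (mm$b / corr1) / (sqrt(vv$b / corr2) + eps)
    list(p = pp, s1 = mm, s2 = vv)
  })
}

# ---- training -------------------------------------------------------------

#' Generate spiral-image training pairs
#'
#' Draws `n_pairs` (noisy, clean) image pairs from the generator: the
#' noisy member is a Poisson acquisition at a short integration time and
#' a temperature sampled from the spec's grids; the clean member is the
#' noiseless expected curve (equivalent, after per-image normalization,
#' to the long-integration ground-truth reference). Both are encoded as
#' square-spiral images and normalized to unit maximum.
#'
#' @param gt A [ground_truth_config()].
#' @param spec A [denoiser_spec()].
#' @param n_pairs Number of pairs (default `spec$n_pairs`).
#' @param seed Integer seed (default `spec$seed`).
#' @return List with matrices `x` and `y` (`n_pairs` x `side^2`, pixels in
#'   image order) and data frame `meta` (`temperature_C`,
#'   `integration_time_s`, `tau_true_ns`).
#' @export
make_training_pairs <- function(gt, spec, n_pairs = NULL, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_config"),
            inherits(spec, "denoiser_spec"))
  if (is.null(n_pairs)) n_pairs <- spec$n_pairs
  if (is.null(seed)) seed <- spec$seed
  npix <- spec$side^2
  with_seed(seed, {
    temps <- sample(spec$temperatures, n_pairs, replace = TRUE)
    dts <- sample(spec$integration_times, n_pairs, replace = TRUE)
    x <- matrix(0, n_pairs, npix)
    y <- matrix(0, n_pairs, npix)
    tau_true <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      noisy <- simulate_decay(gt, spec$wavelength, temps[i],
                              integration_time = dts[i])
      clean <- simulate_decay(gt, spec$wavelength, temps[i],
                              integration_time = spec$ground_truth_integration,
                              noiseless = TRUE)
      xi <- as.vector(spiral_encode(noisy, spec$side)$pixels)
      yi <- as.vector(spiral_encode(clean, spec$side)$pixels)
      x[i, ] <- xi / max(xi, 1e-12)
      y[i, ] <- yi / max(yi, 1e-12)
      tau_true[i] <- average_lifetime(clean)
    }
    list(x = x, y = y,
         meta = data.frame(temperature_C = temps,
                           integration_time_s = dts,
                           tau_true_ns = tau_true))
  })
}

unet_batch_rmse <- function(p, x, y, spec, batch = 64L) {
  n <- nrow(x)
  sse <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch - 1L, n)
    b <- j - i + 1L
    g <- unet_geometry(spec$side, spec$depth, b)
    X <- matrix(as.vector(t(x[i:j, , drop = FALSE])), ncol = 1L)
    Y <- matrix(as.vector(t(y[i:j, , drop = FALSE])), ncol = 1L)
    out <- unet_forward(p, X, g)$out
    sse <- sse + sum((out - Y)^2)
    i <- j + 1L
  }
  sqrt(sse / (n * ncol(x)))
}

#' Train the spiral-image denoiser
#'
#' Minimizes the root-mean-square error between the network output and
#' the clean reference images with Adam on minibatches. Training is
#' seed-reproducible; per-epoch training and validation RMSE curves are
#' recorded on the returned model.
#'
#' @param spec A [denoiser_spec()].
#' @param pairs Training pairs from [make_training_pairs()] (generated
#'   from `gt` if omitted).
#' @param gt A [ground_truth_config()]; required when `pairs` is `NULL`.
#' @param verbose Print per-epoch losses.
#' @return An object of class `cns_denoiser` with elements `params`,
#'   `spec`, `train_rmse`, `val_rmse`.
#' @export
train_denoiser <- function(spec, pairs = NULL, gt = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "denoiser_spec"))
  if (is.null(pairs)) {
    if (is.null(gt)) stop("supply `pairs` or `gt`", call. = FALSE)
    pairs <- make_training_pairs(gt, spec)
  }
  n <- nrow(pairs$x)
  if (n < 4L) stop("degenerate training set: need >= 4 pairs", call. = FALSE)
  with_seed(spec$seed + 1L, {
    n_val <- max(2L, round(spec$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    p <- unet_init(spec)
    m <- zero_like(p); v <- zero_like(p)
    t_step <- 0L
    bs <- spec$batch_size
    geoms <- list()
    train_rmse <- val_rmse <- numeric(spec$epochs)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(tr_idx)
      ep_sse <- 0; ep_n <- 0
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + bs - 1L, length(ord))
        ids <- ord[i:j]
        b <- length(ids)
        key <- as.character(b)
        if (is.null(geoms[[key]])) {
          geoms[[key]] <- unet_geometry(spec$side, spec$depth, b)
        }
        g <- geoms[[key]]
        X <- matrix(as.vector(t(pairs$x[ids, , drop = FALSE])), ncol = 1L)
        Y <- matrix(as.vector(t(pairs$y[ids, , drop = FALSE])), ncol = 1L)
        fw <- unet_forward(p, X, g, keep_cache = TRUE)
        err <- fw$out - Y
        ep_sse <- ep_sse + sum(err^2); ep_n <- ep_n + length(err)
        dOut <- 2 * err / length(err)
        grads <- unet_backward(p, fw$cache, g, dOut)
        t_step <- t_step + 1L
        st <- adam_step(p, grads, m, v, spec$learning_rate, t_step)
        p <- st$p; m <- st$s1; v <- st$s2
        i <- j + 1L
      }
      train_rmse[ep] <- sqrt(ep_sse / ep_n)
      val_rmse[ep] <- unet_batch_rmse(p, pairs$x[val_idx, , drop = FALSE],
                                      pairs$y[val_idx, , drop = FALSE], spec)
      if (verbose) {
        message(sprintf("epoch %d: train RMSE %.5f, val RMSE %.5f",
                        ep, train_rmse[ep], val_rmse[ep]))
      }
    }
    structure(list(params = p, spec = spec, train_rmse = train_rmse,
                   val_rmse = val_rmse),
              class = "cns_denoiser")
  })
}

#' @export
print.cns_denoiser <- function(x, ...) {
  cat(sprintf(
    "<cns_denoiser: %dx%d input, depth %d, base %d ch; final val RMSE %.4g>\n",
    x$spec$side, x$spec$side, x$spec$depth, x$spec$base_channels,
    utils::tail(x$val_rmse, 1)))
  invisible(x)
}

#' Denoise a spiral image
#'
#' Applies the trained network to a spiral image: the image is normalized
#' to unit maximum, passed through the U-shaped network, clamped to
#' non-negative intensities and rescaled; all spiral metadata (bin width,
#' scale, path) is preserved so [lifetime_from_image()] applies directly.
#'
#' @param model A trained `cns_denoiser`.
#' @param img A `spiral_image` whose side matches the model input.
#' @return A denoised `spiral_image`.
#' @export
denoise <- function(model, img) {
  stopifnot(inherits(model, "cns_denoiser"), inherits(img, "spiral_image"))
  if (img$side != model$spec$side) {
    stop(sprintf("image side %d does not match model input %d",
                 img$side, model$spec$side), call. = FALSE)
  }
  x <- as.vector(img$pixels)
  mx <- max(x)
  if (mx <= 0) {
    warning("all-zero image; returning it unchanged")
    return(img)
  }
  g <- unet_geometry(model$spec$side, model$spec$depth, 1L)
  out <- unet_forward(model$params, matrix(x / mx, ncol = 1L), g)$out
  out <- pmax(out, 0) * mx
  res <- img
  res$pixels <- matrix(out, img$side, img$side)
  res
}

#' Save / load a trained denoiser
#'
#' Weights and the training spec are stored in R's native serialization
#' format.
#'
#' @param model A `cns_denoiser`.
#' @param path File path.
#' @return `save_denoiser` returns `path` invisibly; `load_denoiser`
#'   returns the model.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "cns_denoiser"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cns_denoiser"))
  model
}
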