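# Common contract for all reconstruction models: a training configuration,
# a `reconstruct()` generic (same-shape output, clipped to [0, 1],
# deterministic at inference), checkpoint round-trip, and the shared small
# convolutional encoder/decoder used by the AE, VAE and f-AnoGAN encoder.

#' Training configuration for reconstruction models
#'
#' One configuration object drives all five model families; model-specific
#' fields are ignored by the others. One `seed` controls weight
#' initialization, data order and corruption noise, so equal seed + config
#' gives equal final weights.
#'
#' @param epochs Passes over the training set.
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam learning rate.
#' @param latent_dim Bottleneck dimension `d` (AE/VAE code, GAN latent).
#' @param corruption_noise_sigma Std of the additive Gaussian corruption
#'   applied to training inputs (targets stay clean); 0 recovers plain
#'   autoencoding.
#' @param p_norm Reconstruction-loss norm, 1 (default, robust to cell
#'   texture) or 2.
#' @param base_width Channels of the first convolution level.
#' @param kl_weight VAE only: weight of the KL term.
#' @param kappa f-AnoGAN only: weight of the critic-feature residual.
#' @param critic_steps,gp_weight f-AnoGAN only: critic updates per generator
#'   update and gradient-penalty weight.
#' @param seed Integer seed for all randomness during training.
#' @export
train_config <- function(epochs = 40L, batch_size = 8L, learning_rate = 2e-3,
                         latent_dim = 64L, corruption_noise_sigma = 0.1,
                         p_norm = 1L, base_width = 16L, kl_weight = 1e-3,
                         kappa = 1, critic_steps = 5L, gp_weight = 10,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, latent_dim >= 1,
            corruption_noise_sigma >= 0, p_norm %in% c(1L, 2L),
            base_width >= 1, kl_weight >= 0, kappa >= 0, critic_steps >= 1,
            gp_weight >= 0)
  structure(as.list(environment()), class = "autoqc_train_config")
}

validate_training_images <- function(images) {
  if (!is.list(images)) images <- list(images)
  if (length(images) < 1) stop_autoqc("need at least one training image")
  images <- lapply(images, function(x) {
    x <- unclass(as.matrix(x)); attributes(x) <- list(dim = dim(x)); x
  })
  d <- dim(images[[1]])
  for (x in images)
    if (!identical(dim(x), d))
      stop_autoqc("all training images must share one shape")
  if (d[1] < 32 || d[2] < 32)
    stop_autoqc("images must be at least 32 x 32")
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0)
    stop_autoqc("image sides must be divisible by 4")
  images
}

check_shape <- function(model, x) {
  if (nrow(x) != model$H || ncol(x) != model$W)
    stop_autoqc("image shape ", nrow(x), "x", ncol(x),
                " does not match the trained model (", model$H, "x",
                model$W, ")")
}

new_model <- function(kind, cfg, H, W, params, ..., subclass) {
  structure(list(kind = kind, cfg = cfg, H = H, W = W, params = params, ...),
            class = c(subclass, "autoqc_model"))
}

#' Reconstruct an image with a trained model
#'
#' All models return a same-shape reconstruction in \[0, 1\]. Inference is
#' deterministic: stochastic encoders use the posterior mean, and diffusion
#' models draw their corruption noise from `seed` (defaulting to the
#' model's training seed).
#'
#' @param model A trained `autoqc_model`.
#' @param image H x W matrix in \[0, 1\], matching the training shape.
#' @param ... Model-specific arguments (e.g. `seed`, `t_test`).
#' @export
reconstruct <- function(model, image, ...) UseMethod("reconstruct")

#' Pixel-wise anomaly map of an image under a model
#'
#' Default: the reconstruction-error [score_map()] between the image and
#' `reconstruct(model, image)`.
#'
#' @inheritParams reconstruct
#' @param loss `"absolute"` or `"squared"` per-pixel error.
#' @export
anomaly_map <- function(model, image, loss = "absolute", ...)
  UseMethod("anomaly_map")

#' @export
anomaly_map.default <- function(model, image, loss = "absolute", ...) {
  score_map(image, reconstruct(model, image, ...), loss = loss)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration and weights; loading
#' restores a model whose reconstructions are identical.
#'
#' @param model A trained `autoqc_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "autoqc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "autoqc_model"))
    stop_autoqc("'", path, "' is not an autoqc checkpoint")
  m
}

#' @export
print.autoqc_model <- function(x, ...) {
  n_par <- sum(unlist(tree_map(length, x$params)))
  cat("autoqc reconstruction model <", x$kind, ">\n", sep = "")
  cat("  image shape: ", x$H, "x", x$W, "   parameters: ", n_par, "\n")
  if (!is.null(x$final_loss))
    cat("  final training loss: ", signif(x$final_loss, 4), "\n")
  invisible(x)
}

## ---- shared encoder / decoder ----------------------------------------
# Encoder: conv(1->w) relu pool, conv(w->2w) relu pool, dense -> d
# (optionally two dense heads, for the VAE mean/log-variance).
# Decoder: dense(d -> H/4*W/4*2w) relu, up, conv(2w->w) relu, up,
# conv(w->w) relu, conv(w->1) sigmoid.

enc_init <- function(H, W, w, d, heads = 1L) {
  p <- list(c1 = conv_init(1L, w), c2 = conv_init(w, 2L * w),
            f = dense_init((H %/% 4L) * (W %/% 4L) * 2L * w, d, gain = 1))
  if (heads == 2L)
    p$f2 <- dense_init((H %/% 4L) * (W %/% 4L) * 2L * w, d, gain = 1)
  p
}

enc_fwd <- function(p, x, heads = 1L) {
  s1 <- conv_fwd(p$c1, array(x, c(nrow(x), ncol(x), 1L)))
  r1 <- relu_fwd(s1$y)
  p1 <- avgpool2_fwd(r1$y)
  s2 <- conv_fwd(p$c2, p1$y)
  r2 <- relu_fwd(s2$y)
  p2 <- avgpool2_fwd(r2$y)
  f1 <- dense_fwd(p$f, p2$y)
  out <- list(z = f1$y,
              cache = list(s1 = s1$cache, r1 = r1$cache, p1d = p1$cache,
                           s2 = s2$cache, r2 = r2$cache, p2d = p2$cache,
                           f1 = f1$cache, zin_dim = dim(p2$y)))
  if (heads == 2L) out$z2 <- dense_fwd(p$f2, p2$y)$y
  out
}

enc_bwd <- function(p, cache, dz, dz2 = NULL) {
  b1 <- dense_bwd(p$f, cache$f1, dz)
  dflat <- b1$dx
  g_f2 <- NULL
  if (!is.null(dz2)) {
    b2 <- dense_bwd(p$f2, cache$f1, dz2)   # both heads share the input
    g_f2 <- list(W = b2$dW, b = b2$db)
    dflat <- dflat + b2$dx
  }
  dp2 <- array(dflat, cache$zin_dim)
  dr2 <- avgpool2_bwd(cache$p2d, dp2)
  ds2 <- relu_bwd(cache$r2, dr2)
  cb2 <- conv_bwd(p$c2, cache$s2, ds2)
  dr1 <- avgpool2_bwd(cache$p1d, cb2$dx)
  ds1 <- relu_bwd(cache$r1, dr1)
  cb1 <- conv_bwd(p$c1, cache$s1, ds1)
  g <- list(c1 = list(W = cb1$dW, b = cb1$db),
            c2 = list(W = cb2$dW, b = cb2$db),
            f = list(W = b1$dW, b = b1$db))
  if (!is.null(g_f2)) g$f2 <- g_f2
  g
}

dec_init <- function(H, W, w, d) {
  list(f = dense_init(d, (H %/% 4L) * (W %/% 4L) * 2L * w),
       c1 = conv_init(2L * w, w), c2 = conv_init(w, w),
       c3 = conv_init(w, 1L))
}

dec_fwd <- function(p, z, H, W, w) {
  f1 <- dense_fwd(p$f, z)
  r0 <- relu_fwd(array(f1$y, c(H %/% 4L, W %/% 4L, 2L * w)))
  u1 <- upsample2_fwd(r0$y)
  s1 <- conv_fwd(p$c1, u1$y)
  r1 <- relu_fwd(s1$y)
  u2 <- upsample2_fwd(r1$y)
  s2 <- conv_fwd(p$c2, u2$y)
  r2 <- relu_fwd(s2$y)
  s3 <- conv_fwd(p$c3, r2$y)
  sg <- sigmoid_fwd(s3$y)
  list(xhat = matrix(sg$y, H, W),
       cache = list(f1 = f1$cache, r0 = r0$cache, u1 = u1$cache,
                    s1 = s1$cache, r1 = r1$cache, u2 = u2$cache,
                    s2 = s2$cache, r2 = r2$cache, s3 = s3$cache,
                    sg = sg$cache))
}

dec_bwd <- function(p, cache, dxhat) {
  ds3 <- sigmoid_bwd(cache$sg, array(dxhat, c(dim(dxhat)[1], dim(dxhat)[2], 1L)))
  cb3 <- conv_bwd(p$c3, cache$s3, ds3)
  dr2 <- relu_bwd(cache$r2, cb3$dx)
  cb2 <- conv_bwd(p$c2, cache$s2, dr2)
  du2 <- upsample2_bwd(cache$u2, cb2$dx)
  dr1 <- relu_bwd(cache$r1, du2)
  cb1 <- conv_bwd(p$c1, cache$s1, dr1)
  du1 <- upsample2_bwd(cache$u1, cb1$dx)
  dr0 <- relu_bwd(cache$r0, du1)
  fb <- dense_bwd(p$f, cache$f1, as.numeric(dr0))
  list(grads = list(f = list(W = fb$dW, b = fb$db),
                    c1 = list(W = cb1$dW, b = cb1$db),
                    c2 = list(W = cb2$dW, b = cb2$db),
                    c3 = list(W = cb3$dW, b = cb3$db)),
       dz = fb$dx)
}

## ---- reconstruction-loss helpers -------------------------------------

recon_loss_grad <- function(xhat, x, p_norm) {
  n <- length(x)
  diff <- xhat - x
  if (p_norm == 1L) list(loss = mean(abs(diff)), grad = sign(diff) / n)
  else list(loss = mean(diff^2), grad = 2 * diff / n)
}

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Cosine decay from lr to lr/10 across training; reduces late-training
# optimizer noise, which otherwise sets the reconstruction-error floor.
lr_at <- function(lr, ep, epochs) {
  lr * (0.55 + 0.45 * cos(pi * (ep - 1) / max(1, epochs - 1)))
}
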