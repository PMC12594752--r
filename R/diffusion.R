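# Diffusion-based reconstruction. The forward process corrupts an image
# with Gaussian noise under a monotone variance schedule; the denoiser is a
# small U-Net trained to predict the clean image x0 directly from x_t (not
# the noise), and reconstruction happens in a single evaluation at a fixed
# timestep t_test rather than by iterative ancestral sampling. The
# patch-conditioned variant (pDDPM) noises one patch at a time, keeps the
# surrounding context clean, and merges sliding-patch reconstructions by
# per-pixel averaging. Model internals use the [-1, 1] intensity frame;
# reconstructions are reported in the canonical [0, 1] frame.

#' Linear noise schedule for diffusion
#'
#' Builds a monotone `beta_t` ramp with `alpha_t = 1 - beta_t` and
#' `alpha_bar_t = prod(alpha_1..t)`. The endpoints are specified on a
#' reference grid of `reference_steps` (the conventional 1000-step linear
#' schedule); for shorter schedules each step absorbs proportionally more
#' corruption (`beta` scaled by `reference_steps / n_steps`, capped below
#' 1), so the cumulative signal level `alpha_bar` at a given fraction
#' `t / T` is approximately independent of `T`. Set
#' `reference_steps = n_steps` for an unscaled ramp.
#'
#' @param n_steps Number of diffusion steps `T` (>= 2).
#' @param beta_start,beta_end Endpoints of the linear beta ramp on the
#'   reference grid, in (0, 1).
#' @param reference_steps Grid on which the endpoints are defined.
#' @export
noise_schedule <- function(n_steps = 1000L, beta_start = 1e-4,
                           beta_end = 2e-2, reference_steps = 1000L) {
  stopifnot(n_steps >= 2, beta_start > 0, beta_end < 1,
            beta_start <= beta_end, reference_steps >= 2)
  s <- reference_steps / n_steps
  beta <- pmin(seq(beta_start * s, beta_end * s, length.out = n_steps),
               0.999)
  alpha <- 1 - beta
  structure(list(n_steps = as.integer(n_steps), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha)),
            class = "autoqc_noise_schedule")
}

#' Diffusion model configuration
#'
#' @param n_steps,beta_start,beta_end,reference_steps Passed to
#'   [noise_schedule()].
#' @param t_test Fixed reconstruction timestep (default `n_steps / 2`).
#' @param patch_size,patch_stride pDDPM patch grid; defaults (chosen at
#'   training time) are half the image side and half the patch size.
#' @param seed Seed for inference-time corruption noise.
#' @export
diffusion_config <- function(n_steps = 1000L, beta_start = 1e-4,
                             beta_end = 2e-2, reference_steps = 1000L,
                             t_test = NULL, patch_size = NULL,
                             patch_stride = NULL, seed = 1L) {
  schedule <- noise_schedule(n_steps, beta_start, beta_end, reference_steps)
  t_test <- as.integer(t_test %||% round(n_steps / 2))
  if (t_test < 1 || t_test > n_steps)
    stop_autoqc("t_test must lie in [1, n_steps]")
  if (!is.null(patch_size) && !is.null(patch_stride) &&
      patch_stride > patch_size)
    stop_autoqc("patch_stride must not exceed patch_size (coverage gap)")
  structure(list(schedule = schedule, n_steps = schedule$n_steps,
                 t_test = t_test, patch_size = patch_size,
                 patch_stride = patch_stride, seed = as.integer(seed)),
            class = "autoqc_diffusion_config")
}

#' Forward diffusion of an image
#'
#' Computes `sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`. The
#' noise field can be supplied explicitly for determinism; otherwise it is
#' drawn from the standard normal.
#'
#' @param x0 Clean image (any numeric array).
#' @param t Step index in `[1, T]`.
#' @param schedule A [noise_schedule()].
#' @param eps Optional noise field, same shape as `x0`.
#' @export
forward_diffuse <- function(x0, t, schedule, eps = NULL) {
  stopifnot(inherits(schedule, "autoqc_noise_schedule"))
  if (t < 1 || t > schedule$n_steps)
    stop_autoqc("t = ", t, " outside the schedule range [1, ",
                schedule$n_steps, "]")
  if (is.null(eps)) eps <- array(rnorm(length(x0)), dim(x0) %||% length(x0))
  if (!identical(dim(eps) %||% length(eps), dim(x0) %||% length(x0)))
    stop_autoqc("eps must have the same shape as x0")
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Sliding-patch start positions along one axis
#'
#' Positions `1, 1 + stride, ...` up to the last full window; the final
#' window is edge-aligned (shifted inward) so every pixel is covered.
#'
#' @param n Axis length.
#' @param size Window size (`<= n`).
#' @param stride Step between windows (`1 <= stride <= size`).
#' @export
patch_positions <- function(n, size, stride) {
  stopifnot(size >= 1, size <= n, stride >= 1)
  if (stride > size) stop_autoqc("stride must not exceed size (coverage gap)")
  pos <- seq(1L, n - size + 1L, by = stride)
  if (pos[length(pos)] != n - size + 1L) pos <- c(pos, n - size + 1L)
  as.integer(pos)
}

## ---- U-Net denoiser ---------------------------------------------------
# Input: 2 channels (x_t in the [-1,1] frame; binary mask of the noised
# region). Timestep enters through sinusoidal embeddings projected to
# per-channel biases at each resolution level. Output: 1 channel, linear.

unet_init <- function(w, emb_dim = 16L) {
  list(c1 = conv_init(2L, w), c2 = conv_init(w, w),
       c3 = conv_init(w, 2L * w), c4 = conv_init(2L * w, 2L * w),
       c5 = conv_init(2L * w, 2L * w),
       c6 = conv_init(4L * w, w), c7 = conv_init(2L * w, w),
       c8 = conv_init(w, 1L),
       t1 = dense_init(emb_dim, w, gain = 1),
       t2 = dense_init(emb_dim, 2L * w, gain = 1),
       t3 = dense_init(emb_dim, 2L * w, gain = 1))
}

add_chan_bias <- function(x, b) {
  d <- dim(x)
  x + array(rep(b, each = d[1] * d[2]), d)
}

chan_bias_grad <- function(dy) apply(dy, 3, sum)

unet_fwd <- function(p, x2, emb) {
  tb1 <- dense_fwd(p$t1, emb); tb2 <- dense_fwd(p$t2, emb)
  tb3 <- dense_fwd(p$t3, emb)
  s1 <- conv_fwd(p$c1, x2); a1 <- relu_fwd(add_chan_bias(s1$y, tb1$y))
  s2 <- conv_fwd(p$c2, a1$y); a2 <- relu_fwd(s2$y)
  p1 <- avgpool2_fwd(a2$y)
  s3 <- conv_fwd(p$c3, p1$y); a3 <- relu_fwd(add_chan_bias(s3$y, tb2$y))
  s4 <- conv_fwd(p$c4, a3$y); a4 <- relu_fwd(s4$y)
  p2 <- avgpool2_fwd(a4$y)
  s5 <- conv_fwd(p$c5, p2$y); a5 <- relu_fwd(add_chan_bias(s5$y, tb3$y))
  u1 <- upsample2_fwd(a5$y)
  k1 <- array(c(u1$y, a4$y), dim(u1$y) * c(1L, 1L, 2L))
  s6 <- conv_fwd(p$c6, k1); a6 <- relu_fwd(s6$y)
  u2 <- upsample2_fwd(a6$y)
  k2 <- array(c(u2$y, a2$y), dim(u2$y) * c(1L, 1L, 2L))
  s7 <- conv_fwd(p$c7, k2); a7 <- relu_fwd(s7$y)
  s8 <- conv_fwd(p$c8, a7$y)
  list(out = matrix(s8$y, dim(s8$y)[1], dim(s8$y)[2]),
       cache = list(emb = emb, s1 = s1$cache, a1 = a1$cache, s2 = s2$cache,
                    a2 = a2$cache, p1 = p1$cache, s3 = s3$cache,
                    a3 = a3$cache, s4 = s4$cache, a4 = a4$cache,
                    p2 = p2$cache, s5 = s5$cache, a5 = a5$cache,
                    u1 = u1$cache, s6 = s6$cache, a6 = a6$cache,
                    u2 = u2$cache, s7 = s7$cache, a7 = a7$cache,
                    s8 = s8$cache,
                    nc = c(dim(u1$y)[3], dim(u2$y)[3])))
}

unet_bwd <- function(p, cache, dout) {
  d8 <- conv_bwd(p$c8, cache$s8,
                 array(dout, c(dim(dout)[1], dim(dout)[2], 1L)))
  da7 <- relu_bwd(cache$a7, d8$dx)
  d7 <- conv_bwd(p$c7, cache$s7, da7)
  ncs <- cache$nc
  dk2 <- d7$dx
  du2 <- dk2[, , seq_len(ncs[2]), drop = FALSE]
  da2_skip <- dk2[, , ncs[2] + seq_len(ncs[2]), drop = FALSE]
  da6 <- relu_bwd(cache$a6, upsample2_bwd(cache$u2, du2))
  d6 <- conv_bwd(p$c6, cache$s6, da6)
  dk1 <- d6$dx
  du1 <- dk1[, , seq_len(ncs[1]), drop = FALSE]
  da4_skip <- dk1[, , ncs[1] + seq_len(ncs[1]), drop = FALSE]
  da5 <- relu_bwd(cache$a5, upsample2_bwd(cache$u1, du1))
  d5 <- conv_bwd(p$c5, cache$s5, da5)
  dtb3 <- chan_bias_grad(da5)
  da4 <- relu_bwd(cache$a4, avgpool2_bwd(cache$p2, d5$dx) + da4_skip)
  d4 <- conv_bwd(p$c4, cache$s4, da4)
  da3 <- relu_bwd(cache$a3, d4$dx)
  d3 <- conv_bwd(p$c3, cache$s3, da3)
  dtb2 <- chan_bias_grad(da3)
  da2 <- relu_bwd(cache$a2, avgpool2_bwd(cache$p1, d3$dx) + da2_skip)
  d2 <- conv_bwd(p$c2, cache$s2, da2)
  da1 <- relu_bwd(cache$a1, d2$dx)
  d1 <- conv_bwd(p$c1, cache$s1, da1)
  dtb1 <- chan_bias_grad(da1)
  t1b <- dense_bwd(p$t1, cache$emb, dtb1)
  t2b <- dense_bwd(p$t2, cache$emb, dtb2)
  t3b <- dense_bwd(p$t3, cache$emb, dtb3)
  list(c1 = list(W = d1$dW, b = d1$db), c2 = list(W = d2$dW, b = d2$db),
       c3 = list(W = d3$dW, b = d3$db), c4 = list(W = d4$dW, b = d4$db),
       c5 = list(W = d5$dW, b = d5$db), c6 = list(W = d6$dW, b = d6$db),
       c7 = list(W = d7$dW, b = d7$db), c8 = list(W = d8$dW, b = d8$db),
       t1 = list(W = t1b$dW, b = t1b$db),
       t2 = list(W = t2b$dW, b = t2b$db),
       t3 = list(W = t3b$dW, b = t3b$db))
}

## ---- training ---------------------------------------------------------

resolve_patch <- function(dcfg, H, W) {
  ps <- dcfg$patch_size %||% (min(H, W) %/% 2L)
  st <- dcfg$patch_stride %||% max(1L, ps %/% 2L)
  if (ps > min(H, W)) stop_autoqc("patch_size exceeds the image side")
  if (st > ps) stop_autoqc("patch_stride must not exceed patch_size")
  dcfg$patch_size <- as.integer(ps)
  dcfg$patch_stride <- as.integer(st)
  dcfg
}

train_denoiser <- function(images, cfg, diffusion, patch_mode) {
  images <- validate_training_images(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  Tn <- diffusion$n_steps
  sched <- diffusion$schedule
  diffusion <- resolve_patch(diffusion, H, W)
  ps <- diffusion$patch_size
  emb_dim <- 16L
  withr::with_seed(cfg$seed, {
    params <- unet_init(cfg$base_width, emb_dim)
    st <- adam_init(params)
    final_loss <- NA_real_
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- lr_at(cfg$learning_rate, ep, cfg$epochs)
      ep_loss <- 0; n_img <- 0
      for (batch in make_batches(length(images), cfg$batch_size)) {
        grads <- NULL
        b_loss <- 0
        for (i in batch) {
          x0 <- 2 * images[[i]] - 1
          t <- sample.int(Tn, 1)
          if (patch_mode) {
            i0 <- sample.int(H - ps + 1L, 1); j0 <- sample.int(W - ps + 1L, 1)
            ri <- i0:(i0 + ps - 1L); rj <- j0:(j0 + ps - 1L)
            mask <- matrix(0, H, W); mask[ri, rj] <- 1
            x_in <- x0
            x_in[ri, rj] <- forward_diffuse(x0[ri, rj], t, sched,
                                            matrix(rnorm(ps * ps), ps, ps))
          } else {
            mask <- matrix(1, H, W)
            x_in <- forward_diffuse(x0, t, sched, matrix(rnorm(H * W), H, W))
          }
          fw <- unet_fwd(params, array(c(x_in, mask), c(H, W, 2L)),
                         time_embedding(t, emb_dim))
          diff <- (fw$out - x0) * mask
          n_eff <- sum(mask)
          b_loss <- b_loss + sum(diff^2) / n_eff
          g <- unet_bwd(params, fw$cache, 2 * diff / n_eff)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        if (!is.finite(b_loss))
          stop_autoqc("diffusion training diverged (non-finite loss)")
        upd <- adam_step(params, tree_scale(grads, 1 / length(batch)), st,
                         lr_ep)
        params <- upd$params; st <- upd$state
        ep_loss <- ep_loss + b_loss; n_img <- n_img + length(batch)
      }
      final_loss <- ep_loss / n_img
    }
    new_model(if (patch_mode) "pddpm" else "ddpm", cfg, H, W, params,
              diffusion = diffusion, final_loss = final_loss,
              subclass = if (patch_mode) "autoqc_pddpm" else "autoqc_ddpm")
  })
}

#' Train a clean-image-predicting diffusion model
#'
#' Fits a U-Net denoiser `f(x_t, t)` minimizing `E ||x0 - f(x_t, t)||^2`
#' with `t ~ Uniform(1, T)` and `x_t` from [forward_diffuse()] — the
#' standard simple diffusion objective with the noise target replaced by
#' the clean image. Reconstruction ([reconstruct()]) corrupts the input to
#' the single fixed timestep `t_test` and runs one denoiser evaluation (no
#' iterative sampling chain).
#'
#' @inheritParams train_ae
#' @param diffusion A [diffusion_config()].
#' @export
train_ddpm <- function(images, cfg = train_config(),
                       diffusion = diffusion_config()) {
  train_denoiser(images, cfg, diffusion, patch_mode = FALSE)
}

#' Train a patch-conditioned diffusion model (pDDPM)
#'
#' During training, one random patch per sample is noised while the
#' surrounding context stays clean; the denoiser sees the whole image (plus
#' a noised-region indicator channel) and the loss applies on the patch.
#' [reconstruct()] slides a patch grid over the image (edge-aligned final
#' rows/columns), denoises each patch with clean context at `t_test`, and
#' merges overlapping patch predictions by per-pixel averaging.
#'
#' @inheritParams train_ddpm
#' @export
train_pddpm <- function(images, cfg = train_config(),
                        diffusion = diffusion_config()) {
  train_denoiser(images, cfg, diffusion, patch_mode = TRUE)
}

denoise_once <- function(model, x_in, mask, t) {
  fw <- unet_fwd(model$params,
                 array(c(x_in, mask), c(nrow(x_in), ncol(x_in), 2L)),
                 time_embedding(t, 16L))
  fw$out
}

#' @export
reconstruct.autoqc_ddpm <- function(model, image, t_test = NULL,
                                    seed = NULL, ...) {
  x <- unclass(as.matrix(image))
  check_shape(model, x)
  dc <- model$diffusion
  t <- as.integer(t_test %||% dc$t_test)
  if (t < 1 || t > dc$n_steps) stop_autoqc("t_test outside [1, T]")
  H <- model$H; W <- model$W
  x0 <- 2 * x - 1
  withr::with_seed(seed %||% dc$seed, {
    x_t <- forward_diffuse(x0, t, dc$schedule, matrix(rnorm(H * W), H, W))
    clip01((denoise_once(model, x_t, matrix(1, H, W), t) + 1) / 2)
  })
}

#' @export
reconstruct.autoqc_pddpm <- function(model, image, t_test = NULL,
                                     seed = NULL, ...) {
  x <- unclass(as.matrix(image))
  check_shape(model, x)
  dc <- model$diffusion
  t <- as.integer(t_test %||% dc$t_test)
  if (t < 1 || t > dc$n_steps) stop_autoqc("t_test outside [1, T]")
  H <- model$H; W <- model$W
  ps <- dc$patch_size; stride <- dc$patch_stride
  x0 <- 2 * x - 1
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  withr::with_seed(seed %||% dc$seed, {
    for (i0 in patch_positions(H, ps, stride)) {
      for (j0 in patch_positions(W, ps, stride)) {
        ri <- i0:(i0 + ps - 1L); rj <- j0:(j0 + ps - 1L)
        mask <- matrix(0, H, W); mask[ri, rj] <- 1
        x_in <- x0
        x_in[ri, rj] <- forward_diffuse(x0[ri, rj], t, dc$schedule,
                                        matrix(rnorm(ps * ps), ps, ps))
        pred <- denoise_once(model, x_in, mask, t)
        acc[ri, rj] <- acc[ri, rj] + pred[ri, rj]
        cnt[ri, rj] <- cnt[ri, rj] + 1
      }
    }
  })
  clip01((acc / cnt + 1) / 2)
}
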