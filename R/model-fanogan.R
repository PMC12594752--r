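# f-AnoGAN baseline. Step 1 trains generator G and critic D as a WGAN with
# gradient penalty on normal images; step 2 freezes G and D and trains an
# encoder E minimizing the izi_f loss, which combines the image residual
# with the residual in the critic's penultimate feature layer f(.).
# The critic is a leaky-ReLU MLP on the flattened image, which permits an
# exact closed-form gradient of the gradient-penalty term (the activation
# second derivative is zero a.e., so freezing the gates is exact).

critic_init <- function(HW) {
  list(l1 = dense_init(HW, 128L), l2 = dense_init(128L, 64L),
       l3 = dense_init(64L, 1L, gain = 1))
}

critic_fwd <- function(p, xv) {
  h1 <- dense_fwd(p$l1, xv); a1 <- lrelu_fwd(h1$y)
  h2 <- dense_fwd(p$l2, a1$y); a2 <- lrelu_fwd(h2$y)
  h3 <- dense_fwd(p$l3, a2$y)
  list(out = h3$y, feat = a2$y,
       cache = list(in1 = xv, in2 = a1$y, in3 = a2$y,
                    g1 = a1$cache, g2 = a2$cache))
}

critic_bwd <- function(p, cache, dout) {
  d3 <- dense_bwd(p$l3, cache$in3, dout)
  dh2 <- lrelu_bwd(cache$g2, d3$dx)
  d2 <- dense_bwd(p$l2, cache$in2, dh2)
  dh1 <- lrelu_bwd(cache$g1, d2$dx)
  d1 <- dense_bwd(p$l1, cache$in1, dh1)
  list(grads = list(l1 = list(W = d1$dW, b = d1$db),
                    l2 = list(W = d2$dW, b = d2$db),
                    l3 = list(W = d3$dW, b = d3$db)),
       dx = d1$dx)
}

# Gradient into the critic input via the feature layer only (for izi_f).
critic_feat_dx <- function(p, cache, dfeat) {
  dh2 <- lrelu_bwd(cache$g2, dfeat)
  d2x <- drop(p$l2$W %*% dh2)
  dh1 <- lrelu_bwd(cache$g1, d2x)
  drop(p$l1$W %*% dh1)
}

# Input gradient a = dD/dx and its frozen-gate intermediates.
critic_input_grad <- function(p, cache) {
  u2 <- cache$g2 * p$l3$W[, 1]
  u1 <- cache$g1 * drop(p$l2$W %*% u2)
  list(a = drop(p$l1$W %*% u1), u1 = u1, u2 = u2)
}

# d(a^T v)/d(weights) with gates frozen; biases do not enter a.
critic_gp_grads <- function(p, cache, ig, v) {
  t1 <- drop(crossprod(p$l1$W, v))
  gt1 <- cache$g1 * t1
  t2 <- drop(crossprod(p$l2$W, gt1))
  list(l1 = list(W = outer(v, ig$u1), b = numeric(length(p$l1$b))),
       l2 = list(W = outer(gt1, ig$u2), b = numeric(length(p$l2$b))),
       l3 = list(W = matrix(cache$g2 * t2, ncol = 1),
                 b = numeric(1)))
}

#' The f-AnoGAN izi_f encoder loss
#'
#' `(1/n) ||x - xhat||^2 + (kappa/n_d) ||f(x) - f(xhat)||^2` where `n` is
#' the pixel count and `n_d` the critic-feature dimensionality.
#'
#' @param x,xhat Image and reconstruction (equal length).
#' @param f_x,f_xhat Critic feature vectors of `x` and `xhat`.
#' @param kappa Feature-residual weight.
#' @export
fanogan_izi_loss <- function(x, xhat, f_x, f_xhat, kappa = 1) {
  stopifnot(length(x) == length(xhat), length(f_x) == length(f_xhat))
  mean((as.numeric(x) - as.numeric(xhat))^2) +
    kappa * mean((as.numeric(f_x) - as.numeric(f_xhat))^2)
}

#' Train an f-AnoGAN model on normal images
#'
#' Two-stage training: (1) WGAN-GP fitting of generator and critic
#' (`cfg$critic_steps` critic updates per generator update, gradient
#' penalty `cfg$gp_weight`); (2) encoder fitting with generator and critic
#' frozen, minimizing [fanogan_izi_loss()] with weight `cfg$kappa`.
#' `reconstruct()` then maps an image through encoder and generator.
#'
#' @inheritParams train_ae
#' @export
train_fanogan <- function(images, cfg = train_config()) {
  images <- validate_training_images(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  w <- cfg$base_width; d <- cfg$latent_dim
  n <- H * W
  N <- length(images)
  m <- min(cfg$batch_size, N)
  withr::with_seed(cfg$seed, {
    pg <- dec_init(H, W, w, d)
    pc <- critic_init(n)
    pe <- enc_init(H, W, w, d)
    sg <- adam_init(pg); sc <- adam_init(pc); se <- adam_init(pe)
    adam_b1 <- 0.5  # standard WGAN-GP optimizer setting

    gen_image <- function(z) dec_fwd(pg, z, H, W, w)
    n_steps <- cfg$epochs * ceiling(N / m)
    for (step in seq_len(n_steps)) {
      for (cs in seq_len(cfg$critic_steps)) {
        grads <- NULL
        west <- 0
        for (j in seq_len(m)) {
          xr <- as.numeric(images[[sample.int(N, 1)]])
          xf <- as.numeric(gen_image(rnorm(d))$xhat)
          cf <- critic_fwd(pc, xf)
          gf <- critic_bwd(pc, cf$cache, 1 / m)$grads
          cr <- critic_fwd(pc, xr)
          gr <- critic_bwd(pc, cr$cache, -1 / m)$grads
          west <- west + (cr$out - cf$out) / m
          u <- runif(1)
          ct <- critic_fwd(pc, u * xr + (1 - u) * xf)
          ig <- critic_input_grad(pc, ct$cache)
          na <- sqrt(sum(ig$a^2))
          v <- if (na > 0) (2 * (na - 1) / na) * ig$a else 0 * ig$a
          gp <- tree_scale(critic_gp_grads(pc, ct$cache, ig, v),
                           cfg$gp_weight / m)
          g <- tree_add(tree_add(gf, gr), gp)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        if (!is.finite(west))
          stop_autoqc("f-AnoGAN critic collapsed (non-finite Wasserstein estimate)")
        upd <- adam_step(pc, grads, sc, cfg$learning_rate, beta1 = adam_b1)
        pc <- upd$params; sc <- upd$state
      }
      grads <- NULL
      for (j in seq_len(m)) {
        gfwd <- gen_image(rnorm(d))
        cf <- critic_fwd(pc, as.numeric(gfwd$xhat))
        dx <- critic_bwd(pc, cf$cache, -1 / m)$dx
        g <- dec_bwd(pg, gfwd$cache, matrix(dx, H, W))$grads
        grads <- if (is.null(grads)) g else tree_add(grads, g)
      }
      upd <- adam_step(pg, grads, sg, cfg$learning_rate, beta1 = adam_b1)
      pg <- upd$params; sg <- upd$state
    }

    # Stage 2: encoder with G and D frozen (izi_f).
    final_loss <- NA_real_
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; n_img <- 0
      for (batch in make_batches(N, cfg$batch_size)) {
        grads <- NULL
        b_loss <- 0
        for (i in batch) {
          x <- images[[i]]
          ef <- enc_fwd(pe, x)
          gfwd <- gen_image(ef$z)
          fx <- critic_fwd(pc, as.numeric(x))$feat
          ch <- critic_fwd(pc, as.numeric(gfwd$xhat))
          b_loss <- b_loss + fanogan_izi_loss(x, gfwd$xhat, fx, ch$feat,
                                              cfg$kappa)
          dxhat <- 2 * (as.numeric(gfwd$xhat) - as.numeric(x)) / n +
            critic_feat_dx(pc, ch$cache,
                           2 * cfg$kappa * (ch$feat - fx) / length(fx))
          dz <- dec_bwd(pg, gfwd$cache, matrix(dxhat, H, W))$dz
          g <- enc_bwd(pe, ef$cache, dz)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        if (!is.finite(b_loss))
          stop_autoqc("f-AnoGAN encoder training diverged (non-finite loss)")
        upd <- adam_step(pe, tree_scale(grads, 1 / length(batch)), se,
                         cfg$learning_rate)
        pe <- upd$params; se <- upd$state
        ep_loss <- ep_loss + b_loss; n_img <- n_img + length(batch)
      }
      final_loss <- ep_loss / n_img
    }
    new_model("fanogan", cfg, H, W,
              list(gen = pg, critic = pc, enc = pe),
              final_loss = final_loss, subclass = "autoqc_fanogan")
  })
}

#' @export
reconstruct.autoqc_fanogan <- function(model, image, ...) {
  x <- unclass(as.matrix(image))
  check_shape(model, x)
  ef <- enc_fwd(model$params$enc, x)
  clip01(dec_fwd(model$params$gen, ef$z, model$H, model$W,
                 model$cfg$base_width)$xhat)
}
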