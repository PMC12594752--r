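# Variational autoencoder baseline. The encoder emits a diagonal-Gaussian
# posterior (mu, log sigma^2); training minimizes the p-norm reconstruction
# term plus a weighted closed-form KL divergence to the standard-normal
# prior, with the reparameterization z = mu + sigma * eps. Inference uses
# the posterior mean, so score maps are deterministic.

#' Closed-form KL divergence of a diagonal Gaussian to N(0, I)
#'
#' `0.5 * sum(mu^2 + sigma2 - log(sigma2) - 1)` over latent dimensions.
#'
#' @param mu Posterior mean vector.
#' @param sigma2 Posterior variance vector (positive).
#' @export
kl_gaussian <- function(mu, sigma2) {
  stopifnot(length(mu) == length(sigma2), all(sigma2 > 0))
  0.5 * sum(mu^2 + sigma2 - log(sigma2) - 1)
}

#' Train a variational autoencoder on normal images
#'
#' As [train_ae()], with the encoder constrained to a Gaussian posterior
#' and the loss augmented by `cfg$kl_weight` times the KL divergence to the
#' standard-normal prior. Variances are parameterized through an
#' exponential map (the encoder head predicts log sigma^2), so positivity
#' is structural.
#'
#' @inheritParams train_ae
#' @export
train_vae <- function(images, cfg = train_config()) {
  images <- validate_training_images(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  w <- cfg$base_width; d <- cfg$latent_dim
  withr::with_seed(cfg$seed, {
    params <- list(enc = enc_init(H, W, w, d, heads = 2L),
                   dec = dec_init(H, W, w, d))
    st <- adam_init(params)
    final_loss <- NA_real_
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- lr_at(cfg$learning_rate, ep, cfg$epochs)
      ep_loss <- 0; n_img <- 0
      for (batch in make_batches(length(images), cfg$batch_size)) {
        grads <- NULL
        b_loss <- 0
        for (i in batch) {
          x <- images[[i]]
          xc <- x
          if (cfg$corruption_noise_sigma > 0)
            xc <- x + matrix(rnorm(H * W, sd = cfg$corruption_noise_sigma),
                             H, W)
          ef <- enc_fwd(params$enc, xc, heads = 2L)
          mu <- ef$z; logvar <- ef$z2
          eps <- rnorm(d)
          z <- mu + exp(logvar / 2) * eps
          df <- dec_fwd(params$dec, z, H, W, w)
          lg <- recon_loss_grad(df$xhat, x, cfg$p_norm)
          kl <- kl_gaussian(mu, exp(logvar))
          b_loss <- b_loss + lg$loss + cfg$kl_weight * kl
          db <- dec_bwd(params$dec, df$cache, lg$grad)
          dmu <- db$dz + cfg$kl_weight * mu
          dlogvar <- db$dz * eps * exp(logvar / 2) / 2 +
            cfg$kl_weight * 0.5 * (exp(logvar) - 1)
          ge <- enc_bwd(params$enc, ef$cache, dmu, dlogvar)
          g <- list(enc = ge, dec = db$grads)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(batch))
        if (!is.finite(b_loss))
          stop_autoqc("VAE training diverged (non-finite loss)")
        upd <- adam_step(params, grads, st, lr_ep)
        params <- upd$params; st <- upd$state
        ep_loss <- ep_loss + b_loss; n_img <- n_img + length(batch)
      }
      final_loss <- ep_loss / n_img
    }
    new_model("vae", cfg, H, W, params, final_loss = final_loss,
              subclass = "autoqc_vae")
  })
}

#' @export
reconstruct.autoqc_vae <- function(model, image, ...) {
  x <- unclass(as.matrix(image))
  check_shape(model, x)
  ef <- enc_fwd(model$params$enc, x, heads = 2L)  # z = posterior mean
  clip01(dec_fwd(model$params$dec, ef$z, model$H, model$W,
                 model$cfg$base_width)$xhat)
}
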