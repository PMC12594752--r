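# Denoising autoencoder baseline: a small convolutional encoder/decoder
# trained to reproduce clean normal images from Gaussian-corrupted inputs
# by minimizing the mean per-pixel p-norm reconstruction error.

#' Train an autoencoder on normal images
#'
#' Fits encoder `E: image -> d`-dim code and decoder `D: code -> image` by
#' minimizing the mean per-pixel p-norm between the clean image and the
#' reconstruction of its noise-corrupted version (corruption std
#' `cfg$corruption_noise_sigma`; 0 gives plain autoencoding).
#'
#' @param images List of same-shape H x W matrices in \[0, 1\].
#' @param cfg A [train_config()].
#' @return A trained model for [reconstruct()].
#' @export
train_ae <- function(images, cfg = train_config()) {
  images <- validate_training_images(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  w <- cfg$base_width; d <- cfg$latent_dim
  withr::with_seed(cfg$seed, {
    params <- list(enc = enc_init(H, W, w, d), dec = dec_init(H, W, w, d))
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
          ef <- enc_fwd(params$enc, xc)
          df <- dec_fwd(params$dec, ef$z, H, W, w)
          lg <- recon_loss_grad(df$xhat, x, cfg$p_norm)
          b_loss <- b_loss + lg$loss
          db <- dec_bwd(params$dec, df$cache, lg$grad)
          ge <- enc_bwd(params$enc, ef$cache, db$dz)
          g <- list(enc = ge, dec = db$grads)
          grads <- if (is.null(grads)) g else tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(batch))
        if (!is.finite(b_loss))
          stop_autoqc("autoencoder training diverged (non-finite loss)")
        upd <- adam_step(params, grads, st, lr_ep)
        params <- upd$params; st <- upd$state
        ep_loss <- ep_loss + b_loss; n_img <- n_img + length(batch)
      }
      final_loss <- ep_loss / n_img
    }
    new_model("ae", cfg, H, W, params, final_loss = final_loss,
              subclass = "autoqc_ae")
  })
}

#' @export
reconstruct.autoqc_ae <- function(model, image, ...) {
  x <- unclass(as.matrix(image))
  check_shape(model, x)
  ef <- enc_fwd(model$params$enc, x)
  clip01(dec_fwd(model$params$dec, ef$z, model$H, model$W,
                 model$cfg$base_width)$xhat)
}
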