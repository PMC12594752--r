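# One-call benchmark study: train each requested model family on the
# training normals of a manifest, fit its thresholds on the validation
# split, and evaluate on the test split — the comparison table workflow.

default_model_cfg <- function(model, seed) {
  switch(model,
    ae = train_config(epochs = 60L, seed = seed),
    vae = train_config(epochs = 60L, seed = seed),
    fanogan = train_config(epochs = 60L, latent_dim = 48L, seed = seed),
    ddpm = train_config(epochs = 100L, seed = seed),
    pddpm = train_config(epochs = 100L, seed = seed),
    stop_autoqc("unknown model '", model, "'"))
}

#' Select the reconstruction timestep on the validation split
#'
#' The fixed inference timestep `t_test` trades corruption strength against
#' reconstruction fidelity, and no single value suits every data regime.
#' This scans a small grid of candidate timesteps, scores the manifest's
#' validation images at each, and returns the one maximizing validation
#' AUROC (ties go to the smaller timestep, i.e. the cheaper corruption).
#' Only validation data is touched.
#'
#' @param model A trained diffusion model (`ddpm` or `pddpm`).
#' @param manifest An `autoqc_manifest` with a two-class validation split.
#' @param t_grid Candidate timesteps; default `T * c(1/8, 1/4, 1/2, 3/4)`.
#' @inheritParams fit_thresholds
#' @return `list(t_test, val_auc)`.
#' @export
select_t_test <- function(model, manifest, t_grid = NULL,
                          method = "patch_max", patch_size = NULL,
                          patch_stride = NULL, loss = "absolute") {
  stopifnot(inherits(model, c("autoqc_ddpm", "autoqc_pddpm")))
  val <- manifest$validation
  if (nrow(val) == 0 || length(unique(val$label)) < 2)
    stop_autoqc("manifest validation split must contain both classes")
  Tn <- model$diffusion$n_steps
  t_grid <- as.integer(t_grid %||% unique(pmax(1, round(
    Tn * c(1 / 8, 1 / 4, 1 / 2, 3 / 4)))))
  imgs <- lapply(val$image, load_image)
  aucs <- vapply(t_grid, function(tt) {
    sc <- vapply(imgs, function(x)
      aggregate_score(score_map(x, reconstruct(model, x, t_test = tt),
                                loss = loss),
                      method, patch_size, patch_stride), 0)
    auroc(sc, val$label)
  }, 0)
  best <- which.max(aucs)  # first max = smallest t on ties
  list(t_test = t_grid[best], val_auc = aucs[best])
}

train_model <- function(model, images, cfg, diffusion) {
  switch(model,
    ae = train_ae(images, cfg),
    vae = train_vae(images, cfg),
    fanogan = train_fanogan(images, cfg),
    ddpm = train_ddpm(images, cfg, diffusion),
    pddpm = train_pddpm(images, cfg, diffusion))
}

#' Train and evaluate model families on one benchmark
#'
#' For each requested model family: train on the manifest's training
#' normals, fit AS* and lambda* on its validation split, and evaluate on
#' the test split. For the diffusion families the inference timestep is
#' first chosen on the validation split via [select_t_test()]. Returns the trained models, thresholds and one
#' evaluation report per family, ready to tabulate into a method
#' comparison.
#'
#' @param manifest An `autoqc_manifest` (e.g. from [make_benchmark()] or
#'   [read_manifest()]) with training, validation and test data.
#' @param models Character vector out of `"ae"`, `"vae"`, `"fanogan"`,
#'   `"ddpm"`, `"pddpm"`.
#' @param seed Seed applied to every model's training configuration.
#' @param configs Optional named list of [train_config()] overrides per
#'   model.
#' @param diffusion A [diffusion_config()] for the diffusion families.
#' @inheritParams fit_thresholds
#' @return `list(models =, thresholds =, reports =, table =)`, where
#'   `table` is a data.frame with one metric row per model.
#' @export
benchmark_study <- function(manifest,
                            models = c("ae", "vae", "fanogan", "ddpm",
                                       "pddpm"),
                            seed = 1L, configs = list(),
                            diffusion = diffusion_config(n_steps = 100L,
                                                         seed = seed),
                            method = "patch_max", patch_size = NULL,
                            patch_stride = NULL, loss = "absolute") {
  models <- match.arg(models, several.ok = TRUE)
  images <- lapply(manifest$train_normal, load_image)
  out <- list(models = list(), thresholds = list(), reports = list())
  for (mo in models) {
    cfg <- configs[[mo]] %||% default_model_cfg(mo, seed)
    fit <- train_model(mo, images, cfg, diffusion)
    if (mo %in% c("ddpm", "pddpm") && nrow(manifest$validation) > 0 &&
        length(unique(manifest$validation$label)) > 1) {
      sel <- select_t_test(fit, manifest, method = method,
                           patch_size = patch_size,
                           patch_stride = patch_stride, loss = loss)
      fit$diffusion$t_test <- sel$t_test
    }
    th <- fit_thresholds(fit, manifest, method = method,
                         patch_size = patch_size,
                         patch_stride = patch_stride, loss = loss)
    out$models[[mo]] <- fit
    out$thresholds[[mo]] <- th
    out$reports[[mo]] <- evaluate_method(manifest, fit, th, method = method,
                                         patch_size = patch_size,
                                         patch_stride = patch_stride,
                                         loss = loss)
  }
  out$table <- do.call(rbind, lapply(out$reports, function(r)
    data.frame(method = r$method, acc = r$acc, auc = r$auc, dice = r$dice,
               auprc = r$auprc, stringsAsFactors = FALSE)))
  rownames(out$table) <- NULL
  out
}
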