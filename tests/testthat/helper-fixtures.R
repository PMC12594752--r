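# Shared fixtures, built once per test run and cached across test files.
# All fixtures are generated in code at test time; nothing is stored on
# disk beyond the session's tempdir.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small brightfield scene for fast module tests.
small_scene <- function(seed = 1L, cell_count = 4L) {
  scene_spec(32L, 32L, cell_count = cell_count, cell_radius_range = c(2, 4),
             noise_sigma = 0.02, seed = seed)
}

small_normals <- function(n = 8L, offset = 0L) {
  lapply(seq_len(n) + offset, function(i) generate_normal(small_scene(i)))
}

# A small on-disk benchmark (32x32 scenes) shared by io / evaluation /
# curation tests.
small_benchmark <- function() {
  fixture("small_benchmark", {
    dir <- file.path(tempdir(), "autoqc-small-bench")
    make_benchmark(dir, n_train = 6L, n_pos = 4L, n_neg_per_kind = 1L,
                   base_seed = 101L, n_val_normal = 4L,
                   n_val_abnormal_per_kind = 1L, scene = small_scene())
  })
}

# Small trained models on a shared normal set (32x32), reused by the
# anomaly-response and curation tests.
trained_ae_small <- function() {
  fixture("trained_ae_small", {
    train_ae(small_normals(8L),
             train_config(epochs = 80L, batch_size = 4L, latent_dim = 48L,
                          base_width = 12L, seed = 5L))
  })
}

trained_pddpm_small <- function() {
  fixture("trained_pddpm_small", {
    # t_test = T/4 keeps enough signal for the small model to anchor the
    # cells it cannot fully infer from context at this training scale
    train_pddpm(small_normals(12L),
                train_config(epochs = 300L, batch_size = 4L,
                             base_width = 12L, seed = 5L),
                diffusion_config(n_steps = 100L, t_test = 25L, seed = 5L))
  })
}

# Mean score inside vs outside an injected-anomaly mask, averaged over
# several test scenes (the anomaly-response protocol).
anomaly_response <- function(model, kind = "artifact", severity = 0.7,
                             n = 5L, seed_offset = 50L) {
  ratios <- vapply(seq_len(n), function(i) {
    img <- generate_normal(small_scene(seed_offset + i))
    res <- inject_anomaly(img, anomaly_spec(kind, severity = severity,
                                            seed = seed_offset + i))
    m <- anomaly_map(model, res$image)
    inside <- mean(m[res$mask == 1])
    outside <- mean(m[res$mask == 0])
    inside / outside
  }, 0)
  mean(ratios)
}

expect_all_equal <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) <= tol)
}

make_const_pddpm <- function(const, H = 64L, W = 64L, patch = 32L,
                             stride = 16L) {
  # a pDDPM whose denoiser ignores its input and always emits `const`
  # (internal frame): all weights zero, final bias = const
  ns <- asNamespace("autoqc")
  params <- ns$tree_map(function(x) x * 0, ns$unet_init(4L))
  params$c8$b <- const
  structure(list(kind = "pddpm", cfg = train_config(), H = H, W = W,
                 params = params,
                 diffusion = ns$resolve_patch(
                   diffusion_config(n_steps = 100L, patch_size = patch,
                                    patch_stride = stride, seed = 1L),
                   H, W)),
            class = c("autoqc_pddpm", "autoqc_model"))
}
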