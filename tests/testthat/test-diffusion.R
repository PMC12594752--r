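# Forward process, schedule algebra, and the patch machinery of pDDPM.

test_that("noise schedules satisfy their defining algebra for any length", {
  for (Tn in c(2L, 5L, 100L, 1000L)) {
    sc <- noise_schedule(Tn)
    expect_true(all(sc$beta > 0 & sc$beta < 1))
    expect_true(all(diff(sc$beta) >= 0))
    expect_true(all(diff(sc$alpha_bar) < 0))
    expect_true(all(sc$alpha_bar > 0 & sc$alpha_bar < 1))
    expect_equal(sc$alpha_bar[-1], sc$alpha_bar[-Tn] * sc$alpha[-1],
                 tolerance = 1e-15)
  }
  # the scaled short schedule reaches approximately the same cumulative
  # corruption as the reference at matching t/T (checked at mid-schedule;
  # the coarser beta discretization drifts a few percent)
  ref <- noise_schedule(1000L)
  short <- noise_schedule(100L)
  expect_equal(log(short$alpha_bar[50]), log(ref$alpha_bar[500]),
               tolerance = 0.05)
})

test_that("forward diffusion follows x_t = sqrt(ab) x0 + sqrt(1-ab) eps", {
  # schedule engineered so alpha_bar[1] = 0.25
  sc <- noise_schedule(2L, beta_start = 0.75, beta_end = 0.75,
                       reference_steps = 2L)
  x0 <- matrix(1, 4, 4)
  expect_all_equal(forward_diffuse(x0, 1L, sc, eps = matrix(0, 4, 4)), 0.5)

  sc2 <- noise_schedule(50L, reference_steps = 50L)
  x <- matrix(runif(16), 4, 4)
  for (t in c(1L, 7L, 50L))
    expect_all_equal(forward_diffuse(x, t, sc2, eps = matrix(0, 4, 4)),
                     sqrt(sc2$alpha_bar[t]) * x)
  expect_error(forward_diffuse(x, 0L, sc2), "range")
  expect_error(forward_diffuse(x, 51L, sc2), "range")
  expect_error(forward_diffuse(x, 1L, sc2, eps = matrix(0, 2, 2)), "shape")
})

test_that("forward diffusion has the Gaussian moments of its definition", {
  sc <- noise_schedule(100L)
  t <- 60L
  n <- 1e4
  x0 <- rep(0.3, n)
  withr::with_seed(31, {
    xt <- forward_diffuse(x0, t, sc)
  })
  ab <- sc$alpha_bar[t]
  se_mean <- sqrt((1 - ab) / n)
  expect_lt(abs(mean(xt) - sqrt(ab) * 0.3), 3 * se_mean)
  se_var <- (1 - ab) * sqrt(2 / (n - 1))
  expect_lt(abs(var(xt) - (1 - ab)), 3 * se_var)
})

test_that("a DDPM overfits constant images and reconstructs deterministically", {
  imgs <- lapply(c(0.35, 0.55, 0.75), function(b)
    generate_normal(scene_spec(32, 32, cell_count = 0, noise_sigma = 0,
                               background_level = b)))
  m <- train_ddpm(imgs, train_config(epochs = 600L, batch_size = 3L,
                                     base_width = 12L, learning_rate = 3e-3,
                                     seed = 13L),
                  diffusion_config(n_steps = 100L, seed = 13L))
  # mean per-pixel error at a signal-bearing timestep; isolated pixels
  # keep noise spikes, so the max is not the right summary here
  err <- max(vapply(imgs, function(x)
    mean(abs(reconstruct(m, x, t_test = 25L) - x)), 0))
  expect_lt(err, 0.05)
  r1 <- reconstruct(m, imgs[[1]], seed = 5L)
  r2 <- reconstruct(m, imgs[[1]], seed = 5L)
  expect_identical(r1, r2)
  expect_false(identical(r1, reconstruct(m, imgs[[1]], seed = 6L)))
  expect_error(reconstruct(m, imgs[[1]], t_test = 0L), "t_test")
})

test_that("a constant denoiser merges to a constant under any patch grid", {
  for (stride in c(32L, 16L, 24L)) {
    m <- make_const_pddpm(0.2, patch = 32L, stride = stride)
    r <- reconstruct(m, matrix(runif(64 * 64), 64, 64))
    expect_all_equal(r, (0.2 + 1) / 2, tol = 1e-12)
  }
})

test_that("patch grids cover every pixel with brute-force-verified counts", {
  # 64 with patch 32 / stride 32: an exact 2x2 tiling
  expect_identical(patch_positions(64L, 32L, 32L), c(1L, 33L))
  set.seed(41)
  for (k in 1:20) {
    n <- sample(16:80, 1)
    size <- sample(4:n, 1)
    stride <- sample(seq_len(size), 1)
    pos <- patch_positions(n, size, stride)
    expect_identical(anyDuplicated(pos), 0L)
    cover <- integer(n)
    for (p in pos) cover[p:(p + size - 1)] <- cover[p:(p + size - 1)] + 1L
    # independent oracle: per-pixel membership count over the window list
    brute <- vapply(seq_len(n), function(i)
      sum(pos <= i & i <= pos + size - 1L), 0L)
    expect_identical(cover, brute)
    expect_true(all(cover >= 1L))
    expect_identical(pos[length(pos)] + size - 1L, n)  # edge-aligned
  }
  expect_error(patch_positions(32L, 8L, 9L), "stride")
})

test_that("patch-conditioned training responds to localized anomalies", {
  expect_gt(anomaly_response(trained_pddpm_small(), "artifact", 0.7), 1)
})
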