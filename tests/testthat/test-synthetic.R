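test_that("normal scenes are deterministic and honour degenerate settings", {
  sp <- scene_spec(32, 32, cell_count = 0, noise_sigma = 0,
                   background_level = 0.7)
  img <- generate_normal(sp)
  expect_true(all(img == 0.7))
  sp2 <- small_scene(9)
  expect_identical(generate_normal(sp2), generate_normal(sp2))
  dark <- scene_spec(32, 32, cell_count = 0, noise_sigma = 0,
                     background_level = 0.7, polarity = "dark")
  expect_true(all(abs(generate_normal(dark) - 0.3) < 1e-12))
})

test_that("cell placement yields the requested number of separated components", {
  sp <- scene_spec(128, 128, cell_count = 10, noise_sigma = 0, seed = 21)
  img <- generate_normal(sp)
  bw <- img < sp$background_level - sp$cell_darkness / 2
  n_comp <- max(EBImage::bwlabel(EBImage::Image(bw * 1)))
  expect_identical(as.integer(n_comp), 10L)
})

test_that("localized anomalies modify only their masked pixels", {
  img <- generate_normal(small_scene(31))
  for (kind in c("air_bubble", "artifact", "contamination")) {
    res <- inject_anomaly(img, anomaly_spec(kind, severity = 0.8, seed = 3))
    expect_gt(sum(res$mask), 0)
    expect_identical(res$image[res$mask == 0], img[res$mask == 0])
    expect_gt(max(abs(res$image - img)), 0)
  }
})

test_that("whole-frame anomalies carry all-ones masks and behave as documented", {
  img <- generate_normal(small_scene(32))
  zs <- inject_anomaly(img, anomaly_spec("z_shift", severity = 0.6, seed = 1))
  expect_true(all(zs$mask == 1))
  il <- inject_anomaly(img, anomaly_spec("illumination", severity = 0.6,
                                         mode = "linear", seed = 1))
  expect_true(all(il$mask == 1))

  # blurring a constant image is the identity
  const <- matrix(0.6, 32, 32)
  zc <- inject_anomaly(const, anomaly_spec("z_shift", severity = 0.7, seed = 1))
  expect_all_equal(zc$image, const, tol = 1e-8)
})

test_that("global-gain illumination equals an independent recomputation", {
  img <- generate_normal(small_scene(33))
  s <- 0.65
  res <- inject_anomaly(img, anomaly_spec("illumination", severity = s,
                                          mode = "gain", seed = 2))
  oracle <- pmin(pmax((1 + 1.2 * s) * img, 0), 1)
  expect_all_equal(res$image, oracle)
})

test_that("an explicitly placed artifact blob produces one component containing its centre", {
  img <- matrix(0.75, 64, 64)
  res <- inject_anomaly(img, anomaly_spec(
    "artifact", severity = 0.9, n = 1L,
    centers = list(c(32, 32)), sizes = list(c(2.5, 2.5)),
    angles = list(0), seed = 4))
  lab <- EBImage::bwlabel(EBImage::Image(res$mask))
  expect_identical(as.integer(max(lab)), 1L)
  expect_identical(res$mask[32, 32], 1)
})

test_that("perturbation size grows monotonically with severity and vanishes at 0+", {
  img <- generate_normal(small_scene(34))
  sev <- c(0.05, 0.2, 0.4, 0.6, 0.8, 1)
  for (kind in c("air_bubble", "artifact", "z_shift", "illumination",
                 "contamination")) {
    delta <- vapply(sev, function(s) {
      res <- inject_anomaly(img, anomaly_spec(kind, severity = s, seed = 11))
      mean(abs(res$image - img)[res$mask == 1])
    }, 0)
    expect_true(all(diff(delta) >= -1e-12), info = kind)
    res_small <- inject_anomaly(img, anomaly_spec(kind, severity = 1e-3,
                                                  seed = 11))
    expect_lt(max(abs(res_small$image - img)), 0.02)
  }
})

test_that("invalid anomaly specifications are rejected", {
  img <- matrix(0.75, 32, 32)
  expect_error(anomaly_spec("artifact", severity = 0), "severity")
  expect_error(anomaly_spec("artifact", severity = 1.2), "severity")
  expect_error(inject_anomaly(img, anomaly_spec(
    "air_bubble", center = c(2, 2), radius = 10, seed = 1)), "frame")
  expect_error(inject_anomaly(img, anomaly_spec(
    "artifact", centers = list(c(1, 1)), sizes = list(c(4, 4)),
    angles = list(0), n = 1L, seed = 1)), "frame")
})

test_that("benchmark generation is counted, warned and byte-reproducible", {
  d1 <- file.path(withr::local_tempdir(), "b1")
  m <- make_benchmark(d1, n_train = 8, n_pos = 4, n_neg_per_kind = 1,
                      base_seed = 77, n_val_normal = 2,
                      n_val_abnormal_per_kind = 0, scene = small_scene())
  expect_length(m$train_normal, 8)
  expect_length(m$test_positive, 4)
  expect_identical(nrow(m$test_negative), 5L)
  expect_identical(length(list.files(file.path(d1, "test_negative/masks"))), 5L)

  d2 <- file.path(withr::local_tempdir(), "b2")
  make_benchmark(d2, n_train = 8, n_pos = 4, n_neg_per_kind = 1,
                 base_seed = 77, n_val_normal = 2,
                 n_val_abnormal_per_kind = 0, scene = small_scene())
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, setdiff(f1, "manifest.yaml")))
  h2 <- tools::md5sum(file.path(d2, setdiff(f2, "manifest.yaml")))
  expect_identical(unname(h1), unname(h2))

  expect_warning(make_benchmark(file.path(withr::local_tempdir(), "b3"),
                                n_train = 2, n_pos = 2, n_neg_per_kind = 0,
                                base_seed = 1, n_val_normal = 0,
                                n_val_abnormal_per_kind = 0,
                                scene = small_scene()),
                 "no abnormal")
})
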