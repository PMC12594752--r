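# Synthetic brightfield benchmark: sparse dark cell-like blobs on a bright
# background, plus five injectable anomaly classes with exact ground-truth
# masks. Everything is deterministic given the spec seeds.

#' Describe a synthetic normal scene
#'
#' Defaults emulate a brightfield field of view of sparse migrating
#' leukocyte-like cells: bright background, dark elliptical blobs with
#' smooth edges, mild additive Gaussian camera noise.
#'
#' @param height,width Frame size in pixels.
#' @param cell_count Number of non-overlapping cells to place.
#' @param cell_radius_range Min/max cell semi-axis length (pixels).
#' @param background_level Background intensity in (0, 1).
#' @param cell_darkness Intensity drop at a cell centre; must not exceed
#'   `background_level`.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise.
#' @param polarity `"bright"` for brightfield (bright background, dark
#'   cells); `"dark"` flips the scene for fluorescence-like imagery.
#' @param seed Integer seed; identical specs produce bit-identical images.
#' @export
scene_spec <- function(height = 64L, width = 64L, cell_count = 10L,
                       cell_radius_range = c(2, 5), background_level = 0.75,
                       cell_darkness = 0.35, noise_sigma = 0.02,
                       polarity = c("bright", "dark"), seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(height >= 32, width >= 32, cell_count >= 0,
            length(cell_radius_range) == 2,
            cell_radius_range[1] >= 1,
            cell_radius_range[2] >= cell_radius_range[1],
            background_level > 0, background_level < 1,
            cell_darkness > 0, cell_darkness < 1, noise_sigma >= 0)
  if (background_level - cell_darkness < 0)
    stop_autoqc("cell_darkness must not exceed background_level")
  structure(list(height = as.integer(height), width = as.integer(width),
                 cell_count = as.integer(cell_count),
                 cell_radius_range = cell_radius_range,
                 background_level = background_level,
                 cell_darkness = cell_darkness, noise_sigma = noise_sigma,
                 polarity = polarity, seed = as.integer(seed)),
            class = "autoqc_scene_spec")
}

# Normalised elliptical radial distance of every pixel to a cell.
ellipse_dist <- function(H, W, cx, cy, a, b, theta) {
  X <- matrix(seq_len(H), H, W) - cx
  Y <- matrix(seq_len(W), H, W, byrow = TRUE) - cy
  u <- (X * cos(theta) + Y * sin(theta)) / a
  v <- (-X * sin(theta) + Y * cos(theta)) / b
  sqrt(u * u + v * v)
}

#' Generate a synthetic normal image
#'
#' Places `cell_count` non-overlapping dark elliptical blobs (random radii,
#' orientation and position) on a bright background, smooths their edges
#' with a sigmoidal intensity profile, adds Gaussian noise and clips to
#' \[0, 1\]. Cells that do not fit are re-sampled up to a retry cap.
#'
#' @param spec A [scene_spec()].
#' @return H x W numeric matrix in \[0, 1\].
#' @export
generate_normal <- function(spec) {
  stopifnot(inherits(spec, "autoqc_scene_spec"))
  H <- spec$height; W <- spec$width
  withr::with_seed(spec$seed, {
    profile <- matrix(0, H, W)
    placed <- matrix(numeric(0), ncol = 3)  # cx, cy, rmax
    for (i in seq_len(spec$cell_count)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        b <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        theta <- runif(1, 0, pi)
        r <- max(a, b)
        if (2 * r + 6 > min(H, W))
          stop_autoqc("cell radius too large for the frame")
        cx <- runif(1, r + 3, H - r - 2)
        cy <- runif(1, r + 3, W - r - 2)
        clear <- nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + r + 2)
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) stop_autoqc("could not place cell ", i,
                           " without overlap (retry cap reached)")
      placed <- rbind(placed, c(cx, cy, r))
      d <- ellipse_dist(H, W, cx, cy, a, b, theta)
      profile <- pmax(profile, 1 / (1 + exp((d - 1) / 0.12)))
    }
    img <- spec$background_level - spec$cell_darkness * profile
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
    img <- clip01(img)
    if (spec$polarity == "dark") img <- 1 - img
    img
  })
}

#' Describe an anomaly to inject
#'
#' The five classes mirror the common failure modes of high-throughput
#' brightfield imaging: `air_bubble` (dark refraction ring with a bright
#' interior disc), `artifact` (small dark high-contrast dust blobs or
#' streaks), `z_shift` (global defocus blur), `illumination` (global gain or
#' uneven-exposure field) and `contamination` (soft-edged bright spots).
#' Geometry defaults are sampled deterministically from `seed`; any of them
#' can be pinned explicitly.
#'
#' @param kind One of `"air_bubble"`, `"artifact"`, `"z_shift"`,
#'   `"illumination"`, `"contamination"`.
#' @param severity Effect strength in (0, 1]. Perturbation magnitude grows
#'   monotonically with severity and vanishes as severity approaches 0.
#' @param center,radius,angle Optional geometry for `air_bubble` (centre
#'   `c(row, col)`, ring radius in pixels) and the `illumination` gradient
#'   direction (radians).
#' @param mode Illumination sub-mode: `"gain"`, `"linear"` or `"radial"`.
#' @param centers,sizes,angles Optional lists of per-blob geometry for
#'   `artifact` (semi-axes `c(a, b)`) and `contamination` (spot std, pixels).
#' @param n Number of blobs/spots for `artifact` / `contamination`.
#' @param seed Integer seed controlling sampled geometry.
#' @export
anomaly_spec <- function(kind = c("air_bubble", "artifact", "z_shift",
                                  "illumination", "contamination"),
                         severity = 0.7, center = NULL, radius = NULL,
                         angle = NULL, mode = NULL, centers = NULL,
                         sizes = NULL, angles = NULL, n = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(severity) || length(severity) != 1 ||
      severity <= 0 || severity > 1)
    stop_autoqc("severity must be a single value in (0, 1]")
  if (!is.null(mode)) mode <- match.arg(mode, c("gain", "linear", "radial"))
  structure(list(kind = kind, severity = severity, center = center,
                 radius = radius, angle = angle, mode = mode,
                 centers = centers, sizes = sizes, angles = angles, n = n,
                 seed = as.integer(seed)),
            class = "autoqc_anomaly_spec")
}

inject_air_bubble <- function(x, s) {
  H <- nrow(x); W <- ncol(x)
  R <- s$radius %||% runif(1, 0.12, 0.2) * min(H, W)
  ctr <- s$center %||% c(runif(1, 0.3 * H, 0.7 * H), runif(1, 0.3 * W, 0.7 * W))
  w <- 0.25 * R + 1
  if (ctr[1] - R - w < 1 || ctr[1] + R + w > H ||
      ctr[2] - R - w < 1 || ctr[2] + R + w > W)
    stop_autoqc("air bubble geometry extends outside the frame")
  r <- ellipse_dist(H, W, ctr[1], ctr[2], 1, 1, 0)  # pixel distance
  ring <- ifelse(abs(r - R) <= w, cos(pi * (r - R) / (2 * w)), 0)
  interior <- pmin(pmax((R - w - r) / w, 0), 1)
  out <- x - 0.55 * s$severity * ring + 0.45 * s$severity * (1 - x) * interior
  mask <- (r <= R + w) * 1
  list(image = clip01(out), mask = mask)
}

inject_artifact <- function(x, s) {
  H <- nrow(x); W <- ncol(x)
  n <- s$n %||% sample(1:3, 1)
  mask <- matrix(0, H, W)
  out <- x
  for (i in seq_len(n)) {
    sz <- if (!is.null(s$sizes)) s$sizes[[i]] else {
      if (runif(1) < 0.3) c(runif(1, 8, 14), runif(1, 1, 1.6))  # streak
      else runif(2, 1.5, 4)                                     # dust blob
    }
    th <- if (!is.null(s$angles)) s$angles[[i]] else runif(1, 0, pi)
    r <- max(sz)
    ctr <- if (!is.null(s$centers)) s$centers[[i]] else
      c(runif(1, r + 2, H - r - 1), runif(1, r + 2, W - r - 1))
    if (ctr[1] - r < 1 || ctr[1] + r > H || ctr[2] - r < 1 || ctr[2] + r > W)
      stop_autoqc("artifact geometry extends outside the frame")
    d <- ellipse_dist(H, W, ctr[1], ctr[2], sz[1], sz[2], th)
    prof <- ifelse(d <= 1.5, 1 / (1 + exp((d - 1) / 0.08)), 0)
    out <- out * (1 - 0.85 * s$severity * prof)
    mask[d <= 1.5] <- 1
  }
  list(image = clip01(out), mask = mask)
}

inject_z_shift <- function(x, s) {
  sigma <- 4 * s$severity  # severities 0.125..1 span a 0.5..4 px blur std
  out <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  list(image = clip01(matrix(out, nrow(x), ncol(x))),
       mask = matrix(1, nrow(x), ncol(x)))
}

inject_illumination <- function(x, s) {
  H <- nrow(x); W <- ncol(x)
  mode <- s$mode %||% sample(c("gain", "linear", "radial"), 1)
  out <- switch(mode,
    gain = (1 + 1.2 * s$severity) * x,
    linear = {
      phi <- s$angle %||% runif(1, 0, 2 * pi)
      X <- (matrix(seq_len(H), H, W) - (H + 1) / 2) / H
      Y <- (matrix(seq_len(W), H, W, byrow = TRUE) - (W + 1) / 2) / W
      x + 1.4 * s$severity * (X * cos(phi) + Y * sin(phi))
    },
    radial = {
      d <- ellipse_dist(H, W, (H + 1) / 2, (W + 1) / 2, H / 2, W / 2, 0)
      x - 0.8 * s$severity * pmin(d, 1.2)^2
    })
  list(image = clip01(out), mask = matrix(1, H, W))
}

inject_contamination <- function(x, s) {
  H <- nrow(x); W <- ncol(x)
  n <- s$n %||% sample(1:3, 1)
  mask <- matrix(0, H, W)
  out <- x
  cutoff <- exp(-4.5)  # profile truncated to exactly zero beyond 3 sd
  for (i in seq_len(n)) {
    sd_px <- if (!is.null(s$sizes)) s$sizes[[i]] else runif(1, 3, 6)
    ctr <- if (!is.null(s$centers)) s$centers[[i]] else
      c(runif(1, sd_px + 1, H - sd_px), runif(1, sd_px + 1, W - sd_px))
    if (ctr[1] < 1 || ctr[1] > H || ctr[2] < 1 || ctr[2] > W)
      stop_autoqc("contamination geometry extends outside the frame")
    d <- ellipse_dist(H, W, ctr[1], ctr[2], sd_px, sd_px, 0)
    prof <- pmax(exp(-d^2 / 2) - cutoff, 0) / (1 - cutoff)
    out <- out + 0.7 * s$severity * prof
    mask[prof > 0] <- 1
  }
  list(image = clip01(out), mask = mask)
}

#' Inject an anomaly into an image
#'
#' Applies the perturbation described by an [anomaly_spec()] and returns the
#' modified image with an exact ground-truth mask of the affected pixels.
#' For the whole-frame degradations (`z_shift` and `illumination`) the mask
#' is all-ones; for localized anomalies, pixels outside the mask are
#' bit-identical to the input.
#'
#' @param image H x W matrix in \[0, 1\].
#' @param spec An [anomaly_spec()].
#' @return `list(image =, mask =)`.
#' @export
inject_anomaly <- function(image, spec) {
  stopifnot(inherits(spec, "autoqc_anomaly_spec"))
  x <- unclass(as.matrix(image))
  attributes(x) <- list(dim = dim(x))
  withr::with_seed(spec$seed,
    switch(spec$kind,
           air_bubble = inject_air_bubble(x, spec),
           artifact = inject_artifact(x, spec),
           z_shift = inject_z_shift(x, spec),
           illumination = inject_illumination(x, spec),
           contamination = inject_contamination(x, spec)))
}

anomaly_kinds <- c("air_bubble", "artifact", "z_shift", "illumination",
                   "contamination")

#' Write a complete synthetic benchmark to disk
#'
#' Generates training normals, positive (normal) test images, negative
#' (anomalous) test images covering all five anomaly kinds with ground-truth
#' masks, and a validation split for threshold fitting, in the directory
#' layout understood by [read_manifest()]. Fully reproducible from
#' `base_seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_train,n_pos Numbers of training and positive test images.
#' @param n_neg_per_kind Negative test images per anomaly kind.
#' @param base_seed Integer master seed.
#' @param n_val_normal,n_val_abnormal_per_kind Validation split sizes
#'   (abnormal validation images carry masks, for threshold fitting).
#' @param scene Optional [scene_spec()] template (its seed is ignored).
#' @param severity_range Anomaly severities are drawn uniformly from this
#'   interval.
#' @param format `"tiff"` or `"png"` for the generated images.
#' @return The [read_manifest()] result for the written benchmark.
#' @export
make_benchmark <- function(out_dir, n_train = 32L, n_pos = 16L,
                           n_neg_per_kind = 2L, base_seed = 1L,
                           n_val_normal = 8L, n_val_abnormal_per_kind = 1L,
                           scene = NULL, severity_range = c(0.5, 1),
                           format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  scene <- scene %||% scene_spec()
  if (n_neg_per_kind == 0)
    warning("n_neg_per_kind = 0: benchmark has no abnormal test samples")
  dirs <- c("train_normal", "test_positive",
            file.path("test_negative", c("images", "masks")),
            file.path("validation", "normal"),
            file.path("validation", c("abnormal/images", "abnormal/masks")))
  for (d in dirs) dir.create(file.path(out_dir, d), recursive = TRUE,
                             showWarnings = FALSE)

  n_neg <- n_neg_per_kind * length(anomaly_kinds)
  n_val_abn <- n_val_abnormal_per_kind * length(anomaly_kinds)
  n_total <- n_train + n_pos + n_neg + n_val_normal + n_val_abn
  seeds <- withr::with_seed(base_seed,
                            sample.int(.Machine$integer.max - 8L, n_total))
  k <- 0L
  next_seed <- function() { k <<- k + 1L; seeds[k] }

  gen <- function(seed) {
    sp <- scene
    sp$seed <- seed
    generate_normal(sp)
  }
  write_normal <- function(dir, stem, seed) {
    save_image(gen(seed), file.path(out_dir, dir,
                                    sprintf("%s.%s", stem, ext)))
  }
  write_abnormal <- function(img_dir, mask_dir, stem, kind, seed) {
    img <- gen(seed)
    sev <- withr::with_seed(seed + 1L,
                            runif(1, severity_range[1], severity_range[2]))
    res <- inject_anomaly(img, anomaly_spec(kind, severity = sev,
                                            seed = seed + 2L))
    save_image(res$image, file.path(out_dir, img_dir,
                                    sprintf("%s.%s", stem, ext)))
    save_mask(res$mask, file.path(out_dir, mask_dir,
                                  sprintf("%s.%s", stem, ext)))
  }

  for (i in seq_len(n_train))
    write_normal("train_normal", sprintf("train_%03d", i), next_seed())
  for (i in seq_len(n_pos))
    write_normal("test_positive", sprintf("pos_%03d", i), next_seed())
  for (kind in anomaly_kinds)
    for (i in seq_len(n_neg_per_kind))
      write_abnormal("test_negative/images", "test_negative/masks",
                     sprintf("neg_%s_%02d", kind, i), kind, next_seed())
  for (i in seq_len(n_val_normal))
    write_normal("validation/normal", sprintf("val_norm_%03d", i),
                 next_seed())
  for (kind in anomaly_kinds)
    for (i in seq_len(n_val_abnormal_per_kind))
      write_abnormal("validation/abnormal/images", "validation/abnormal/masks",
                     sprintf("val_%s_%02d", kind, i), kind, next_seed())

  m <- read_manifest(out_dir, check_shapes = FALSE)
  write_manifest_yaml(m, file.path(out_dir, "manifest.yaml"))
  m
}
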