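# From reconstructions to decisions: pixel-wise anomaly score maps,
# image-level anomaly scores (three aggregators), learned thresholds for
# the image-level alarm (AS*) and the pixel-level mask (lambda*), and the
# two-stage classify step (alarm first, localization mask only for alarmed
# frames).

#' Pixel-wise anomaly score map
#'
#' The per-pixel reconstruction error between an image and its
#' reconstruction: `|x - xhat|` (default) or `(x - xhat)^2`. Higher values
#' indicate higher probability of being abnormal.
#'
#' @param x,x_hat Same-shape matrices in \[0, 1\].
#' @param loss `"absolute"` or `"squared"`.
#' @param smooth_sigma Optional Gaussian smoothing (pixels) applied to the
#'   map; 0 (default) disables it.
#' @export
score_map <- function(x, x_hat, loss = c("absolute", "squared"),
                      smooth_sigma = 0) {
  loss <- match.arg(loss)
  x <- unclass(as.matrix(x)); x_hat <- unclass(as.matrix(x_hat))
  if (!identical(dim(x), dim(x_hat)))
    stop_autoqc("image and reconstruction shapes differ")
  m <- if (loss == "absolute") abs(x - x_hat) else (x - x_hat)^2
  if (smooth_sigma > 0)
    m <- matrix(EBImage::gblur(m, sigma = smooth_sigma,
                               boundary = "replicate"),
                nrow(m), ncol(m))
  unname(m)
}

win_sums <- function(map, pr, pc, pos_r, pos_c) {
  H <- nrow(map); W <- ncol(map)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- t(apply(apply(map, 2, cumsum), 1, cumsum))
  outer(pos_r, pos_c, function(i, j)
    S[cbind(i + pr, j + pc)] - S[cbind(i, j + pc)] -
      S[cbind(i + pr, j)] + S[cbind(i, j)])
}

#' Image-level anomaly score
#'
#' Aggregates a score map to a scalar: its maximum, its mean, or the
#' maximum over sliding-window patch means (`patch_max`; windows slide with
#' the given stride and the final row/column of windows is edge-aligned so
#' every pixel is covered).
#'
#' @param map Score map matrix.
#' @param method `"max"`, `"mean"` or `"patch_max"`.
#' @param patch_size Window size for `patch_max`: one value or
#'   `c(rows, cols)`. Default: a quarter of the shorter image side.
#' @param patch_stride Window stride (one value or two); default half the
#'   window.
#' @export
aggregate_score <- function(map, method = c("max", "mean", "patch_max"),
                            patch_size = NULL, patch_stride = NULL) {
  method <- match.arg(method)
  map <- unclass(as.matrix(map))
  if (method == "max") return(max(map))
  if (method == "mean") return(mean(map))
  H <- nrow(map); W <- ncol(map)
  ps <- patch_size %||% max(1L, round(min(H, W) / 4))
  ps <- rep(as.integer(ps), length.out = 2L)
  st <- patch_stride %||% pmax(1L, ps %/% 2L)
  st <- rep(as.integer(st), length.out = 2L)
  if (any(ps > c(H, W))) stop_autoqc("patch_size exceeds the map")
  sums <- win_sums(map, ps[1], ps[2],
                   patch_positions(H, ps[1], st[1]),
                   patch_positions(W, ps[2], st[2]))
  max(sums) / prod(ps)
}

#' Fit the image-level alarm threshold AS*
#'
#' Greedy search over candidate thresholds (midpoints between consecutive
#' sorted unique scores plus the extremes) maximizing classification
#' accuracy under the rule "abnormal iff score > AS*". Ties are broken
#' toward the smallest threshold (favoring sensitivity).
#'
#' @param scores Numeric anomaly scores of validation images.
#' @param labels Parallel labels: `"normal"`/`"abnormal"`, or 0/1 with 1 =
#'   abnormal, or logical.
#' @return `list(as_star, accuracy)`.
#' @export
fit_as_threshold <- function(scores, labels) {
  lab <- normalize_labels(labels)
  if (length(scores) != length(lab))
    stop_autoqc("scores and labels lengths differ")
  if (length(unique(lab)) < 2)
    stop_autoqc("need both normal and abnormal validation scores")
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, if (length(su) > 1)
    (su[-1] + su[-length(su)]) / 2, su[length(su)])
  acc <- vapply(cand, function(th) mean((scores > th) == lab), 0)
  best <- which.max(acc)  # first index = smallest threshold on ties
  list(as_star = cand[best], accuracy = acc[best])
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("normal", "abnormal")))
      stop_autoqc("character labels must be 'normal' or 'abnormal'")
    return(as.integer(labels == "abnormal"))
  }
  lab <- as.integer(as.logical(labels) | labels > 0)
  if (!all(labels %in% c(0, 1, TRUE, FALSE)))
    stop_autoqc("numeric labels must be 0/1 (1 = abnormal)")
  lab
}

dice_pair <- function(pred, gt) {
  s <- sum(pred) + sum(gt)
  if (s == 0) return(1)  # empty prediction vs empty ground truth
  2 * sum(pred * gt) / s
}

#' Fit the pixel-level binarization threshold lambda*
#'
#' Evaluates the mean Dice coefficient of `map > lambda` against the
#' ground-truth masks over a grid of candidate thresholds (evenly spaced
#' quantiles of the pooled score values, plus zero as the predict-all
#' anchor) and returns the Dice-maximizing lambda. Ties are broken toward the largest lambda (favoring
#' specificity).
#'
#' @param maps List of score maps of abnormal validation images.
#' @param gt_masks Parallel list of binary ground-truth masks.
#' @param n_grid Number of quantile grid points.
#' @return `list(lambda_star, dice)`.
#' @export
fit_lambda_threshold <- function(maps, gt_masks, n_grid = 200L) {
  if (length(maps) == 0 || length(maps) != length(gt_masks))
    stop_autoqc("need a non-empty, aligned set of maps and masks")
  maps <- lapply(maps, function(m) unclass(as.matrix(m)))
  gt_masks <- lapply(gt_masks, function(m) (unclass(as.matrix(m)) > 0.5) * 1)
  for (i in seq_along(maps))
    if (!identical(dim(maps[[i]]), dim(gt_masks[[i]])))
      stop_autoqc("map/mask shape mismatch at pair ", i)
  if (sum(vapply(gt_masks, sum, 0)) == 0)
    stop_autoqc("ground-truth masks contain no positive pixel")
  pooled <- unlist(maps)
  # zero anchors the grid so the predict-all extreme is always considered
  # (score maps are non-negative; thresholding is strict)
  cand <- sort(unique(c(0, quantile(pooled, seq(0, 1, length.out = n_grid),
                                    names = FALSE))))
  mean_dice <- vapply(cand, function(lam)
    mean(mapply(function(m, g) dice_pair((m > lam) * 1, g),
                maps, gt_masks)), 0)
  best <- max(which(mean_dice == max(mean_dice)))  # largest lambda on ties
  list(lambda_star = cand[best], dice = mean_dice[best])
}

#' Bundle fitted decision thresholds
#'
#' @param as_star Image-level alarm threshold.
#' @param lambda_star Pixel-level binarization threshold (>= 0).
#' @param provenance Free-text description of the validation set used.
#' @export
thresholds <- function(as_star, lambda_star = NA_real_, provenance = "") {
  stopifnot(is.finite(as_star), is.na(lambda_star) ||
              (is.finite(lambda_star) && lambda_star >= 0))
  structure(list(as_star = as_star, lambda_star = lambda_star,
                 provenance = provenance), class = "autoqc_thresholds")
}

#' @export
print.autoqc_thresholds <- function(x, ...) {
  cat("autoqc thresholds: AS* =", signif(x$as_star, 5),
      " lambda* =", signif(x$lambda_star, 5), "\n")
  if (nzchar(x$provenance)) cat("  fitted on:", x$provenance, "\n")
  invisible(x)
}

#' Binarize a score map into an anomaly mask
#'
#' Strict-inequality thresholding: a pixel is anomalous iff its score
#' exceeds `lambda`.
#'
#' @param map Score map matrix.
#' @param lambda Finite threshold.
#' @export
binarize <- function(map, lambda) {
  stopifnot(is.finite(lambda))
  unname((unclass(as.matrix(map)) > lambda) * 1)
}

#' Two-stage alarm-and-localize decision for one frame
#'
#' Raises an alarm iff the aggregate anomaly score strictly exceeds AS*;
#' only for alarmed frames is the pixel-level mask produced (by
#' [binarize()] at lambda*), mirroring the flag-then-localize workflow.
#'
#' @param map Score map of the frame.
#' @param th A [thresholds()] object.
#' @inheritParams aggregate_score
#' @return `list(is_abnormal, score, mask)` with `mask = NULL` for
#'   non-alarmed frames.
#' @export
classify <- function(map, th, method = "patch_max", patch_size = NULL,
                     patch_stride = NULL) {
  stopifnot(inherits(th, "autoqc_thresholds"))
  s <- aggregate_score(map, method, patch_size, patch_stride)
  alarmed <- s > th$as_star
  list(is_abnormal = alarmed, score = s,
       mask = if (alarmed) binarize(map, th$lambda_star) else NULL)
}

#' Fit alarm and binarization thresholds on a validation split
#'
#' Scores every validation image of a benchmark manifest with the model,
#' fits AS* on the normal/abnormal scores and lambda* on the score maps of
#' the masked abnormal images.
#'
#' @param model A trained `autoqc_model`.
#' @param manifest An `autoqc_manifest` with a non-empty validation split.
#' @inheritParams classify
#' @param loss Score-map loss, `"absolute"` or `"squared"`.
#' @export
fit_thresholds <- function(model, manifest, method = "patch_max",
                           patch_size = NULL, patch_stride = NULL,
                           loss = "absolute") {
  val <- manifest$validation
  if (nrow(val) == 0 || length(unique(val$label)) < 2)
    stop_autoqc("manifest validation split must contain both classes")
  maps <- lapply(val$image, function(p)
    anomaly_map(model, load_image(p), loss = loss))
  scores <- vapply(maps, aggregate_score, 0, method = method,
                   patch_size = patch_size, patch_stride = patch_stride)
  as_fit <- fit_as_threshold(scores, val$label)
  masked <- which(val$label == "abnormal" & !is.na(val$mask))
  lam_fit <- if (length(masked))
    fit_lambda_threshold(maps[masked], lapply(val$mask[masked], load_mask))
  else list(lambda_star = NA_real_, dice = NA_real_)
  thresholds(as_fit$as_star, lam_fit$lambda_star,
             provenance = sprintf(
               "%d validation images (%d abnormal, %d masked); val acc %.3f, val dice %.3f",
               nrow(val), sum(val$label == "abnormal"), length(masked),
               as_fit$accuracy, lam_fit$dice))
}
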