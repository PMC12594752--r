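# Benchmark metrics (accuracy, AUROC, Dice, AUPRC) and the per-method
# evaluation report over a benchmark manifest.

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, not all zero.
#' @export
accuracy <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  tot <- tp + tn + fp + fn
  if (tot == 0) stop_autoqc("all confusion counts are zero")
  (tp + tn) / tot
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic (ties counted 1/2), which
#' equals trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric anomaly scores.
#' @param labels Parallel labels (1/"abnormal" = positive class).
#' @export
auroc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  if (length(scores) != length(lab))
    stop_autoqc("scores and labels lengths differ")
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) stop_autoqc("need both classes for AUROC")
  r <- rank(scores)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |P ∩ G| / (|P| + |G|)`, with the convention that two empty masks
#' have Dice 1.
#'
#' @param pred,gt Same-shape binary masks.
#' @export
dice <- function(pred, gt) {
  pred <- unclass(as.matrix(pred)); gt <- unclass(as.matrix(gt))
  if (!identical(dim(pred), dim(gt)))
    stop_autoqc("mask shapes differ")
  dice_pair((pred > 0.5) * 1, (gt > 0.5) * 1)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over distinct score thresholds in descending order
#' (no linear interpolation between points): `sum over k of
#' (R_k - R_{k-1}) * P_k`.
#'
#' @param scores Pixel (or sample) scores.
#' @param labels Parallel 0/1 labels with at least one positive.
#' @export
auprc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  if (length(scores) != length(lab))
    stop_autoqc("scores and labels lengths differ")
  P <- sum(lab == 1)
  if (P == 0) stop_autoqc("no positive labels for AUPRC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- lab[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each threshold
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  rec <- tp / P
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a trained model over a benchmark manifest
#'
#' Classification metrics (ACC at the fitted AS*, AUROC on the raw scores)
#' are computed over all test images, with "abnormal" as the positive
#' class. Segmentation metrics use the negative (abnormal) test samples
#' only, where ground-truth masks exist: Dice of `binarize(map, lambda*)`
#' averaged per image, and AUPRC of the pixel scores (pooled across images
#' by default, or averaged per image).
#'
#' @param manifest An `autoqc_manifest` with both test classes.
#' @param model A trained `autoqc_model`.
#' @param th A [thresholds()] object (e.g. from [fit_thresholds()]).
#' @inheritParams fit_thresholds
#' @param auprc_mode `"pooled"` or `"per_image"`.
#' @return An `autoqc_report` with fields `acc`, `auc`, `dice`, `auprc`,
#'   `counts` and a `per_image` table.
#' @export
evaluate_method <- function(manifest, model, th, method = "patch_max",
                            patch_size = NULL, patch_stride = NULL,
                            loss = "absolute",
                            auprc_mode = c("pooled", "per_image")) {
  auprc_mode <- match.arg(auprc_mode)
  stopifnot(inherits(th, "autoqc_thresholds"))
  if (length(manifest$test_positive) == 0 || nrow(manifest$test_negative) == 0)
    stop_autoqc("manifest must contain both positive and negative test samples")
  paths <- c(manifest$test_positive, manifest$test_negative$image)
  lab <- rep(c(0L, 1L), c(length(manifest$test_positive),
                          nrow(manifest$test_negative)))
  maps <- lapply(paths, function(p)
    anomaly_map(model, load_image(p), loss = loss))
  scores <- vapply(maps, aggregate_score, 0, method = method,
                   patch_size = patch_size, patch_stride = patch_stride)
  alarm <- scores > th$as_star
  tp <- sum(alarm & lab == 1); fn <- sum(!alarm & lab == 1)
  fp <- sum(alarm & lab == 0); tn <- sum(!alarm & lab == 0)

  neg_idx <- which(lab == 1)
  gt <- lapply(manifest$test_negative$mask, load_mask)
  dice_i <- mapply(function(m, g) dice(binarize(m, th$lambda_star), g),
                   maps[neg_idx], gt)
  pix_auprc <- if (auprc_mode == "pooled") {
    auprc(unlist(maps[neg_idx]), unlist(lapply(gt, as.numeric)))
  } else {
    mean(mapply(function(m, g) auprc(as.numeric(m), as.numeric(g)),
                maps[neg_idx], gt))
  }
  per_image <- data.frame(
    image = basename(paths), score = scores, alarm = alarm,
    label = ifelse(lab == 1, "abnormal", "normal"),
    dice = NA_real_, stringsAsFactors = FALSE)
  per_image$dice[neg_idx] <- dice_i
  structure(list(method = model$kind,
                 acc = accuracy(tp, tn, fp, fn),
                 auc = auroc(scores, lab),
                 dice = mean(dice_i),
                 auprc = pix_auprc,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 n_images = length(paths),
                 n_masked_images = length(neg_idx),
                 per_image = per_image),
            class = "autoqc_report")
}

#' @export
print.autoqc_report <- function(x, ...) {
  cat(sprintf("autoqc evaluation report — method: %s (%d images, %d masked)\n",
              x$method, x$n_images, x$n_masked_images))
  cat(sprintf("  ACC  %.4f   AUC  %.4f   DICE  %.4f   AUPRC  %.4f\n",
              x$acc, x$auc, x$dice, x$auprc))
  cat(sprintf("  counts: TP %d  TN %d  FP %d  FN %d\n",
              x$counts["tp"], x$counts["tn"], x$counts["fp"],
              x$counts["fn"]))
  invisible(x)
}

#' Ground-truth oracle model for pipeline validation
#'
#' A pseudo-model whose anomaly map for a benchmark image is its
#' ground-truth mask (zero for unmasked images). Useful to verify that the
#' evaluation machinery yields perfect metrics when given perfect scores.
#'
#' @param manifest An `autoqc_manifest`.
#' @export
oracle_model <- function(manifest) {
  masked <- rbind(
    manifest$test_negative[, c("image", "mask")],
    manifest$validation[manifest$validation$label == "abnormal" &
                          !is.na(manifest$validation$mask),
                        c("image", "mask")])
  masks <- stats::setNames(as.list(masked$mask), normalizePath(masked$image))
  structure(list(kind = "oracle", masks = masks, H = NA, W = NA,
                 params = list(), cfg = NULL),
            class = c("autoqc_oracle", "autoqc_model"))
}

#' @export
reconstruct.autoqc_oracle <- function(model, image, ...) {
  clip01(unclass(as.matrix(image)))
}

#' @export
anomaly_map.autoqc_oracle <- function(model, image, loss = "absolute", ...) {
  key <- attr(image, "source_path")
  x <- unclass(as.matrix(image))
  if (!is.null(key) && file.exists(key)) {
    key <- normalizePath(key)
    if (!is.null(model$masks[[key]]))
      return(unclass(load_mask(model$masks[[key]])) + 0)
  }
  matrix(0, nrow(x), ncol(x))
}
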