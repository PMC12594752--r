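# Curation workflow: train on a small curated normal set, score a large
# unlabeled pool, and rank images by confidence of being abnormal. No
# threshold is needed — the output is a pure ranking.

#' Rank an unlabeled image pool by anomaly confidence
#'
#' Scores every image of the pool with the model and the chosen aggregator
#' and returns a table ordered most-abnormal-first. Ties are broken by
#' lexicographic path for reproducibility; unreadable images are skipped
#' with a warning and recorded in the `skipped` attribute.
#'
#' @param model A trained `autoqc_model`.
#' @param pool Directory of images, or a character vector of image paths.
#' @inheritParams fit_thresholds
#' @param seed Seed forwarded to the model's reconstruction (diffusion
#'   models); defaults to the model's own.
#' @return A `data.frame` with columns `path`, `score`, `rank` (descending
#'   score) of class `autoqc_ranked_pool`.
#' @export
rank_pool <- function(model, pool, method = "patch_max", patch_size = NULL,
                      patch_stride = NULL, loss = "absolute", seed = NULL) {
  paths <- if (length(pool) == 1 && dir.exists(pool)) list_images(pool)
           else as.character(pool)
  if (length(paths) == 0) stop_autoqc("image pool is empty")
  paths <- paths[order(paths)]
  scores <- rep(NA_real_, length(paths))
  for (i in seq_along(paths)) {
    m <- tryCatch(
      anomaly_map(model, load_image(paths[i]), loss = loss, seed = seed),
      error = function(e) {
        warning("skipping unreadable pool image '", paths[i], "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(m))
      scores[i] <- aggregate_score(m, method, patch_size, patch_stride)
  }
  skipped <- paths[is.na(scores)]
  keep <- !is.na(scores)
  paths <- paths[keep]; scores <- scores[keep]
  o <- order(-scores, paths)  # ties: lexicographic path
  out <- data.frame(path = paths[o], score = scores[o],
                    rank = seq_along(o), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("autoqc_ranked_pool", "data.frame")
  out
}
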