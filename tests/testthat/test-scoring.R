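# Brute-force oracles used to validate the scoring module.

brute_patch_max <- function(map, pr, pc, sr, sc) {
  best <- -Inf
  H <- nrow(map); W <- ncol(map)
  for (i in patch_positions(H, pr, sr))
    for (j in patch_positions(W, pc, sc))
      best <- max(best, mean(map[i:(i + pr - 1), j:(j + pc - 1)]))
  best
}

brute_as_threshold <- function(scores, labels) {
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
            su[length(su)])
  accs <- sapply(cand, function(th) mean((scores > th) == labels))
  list(th = cand[which.max(accs)], acc = max(accs))
}

brute_dice <- function(pred, gt) {
  s <- sum(pred) + sum(gt)
  if (s == 0) 1 else 2 * sum(pred == 1 & gt == 1) / s
}

test_that("score maps implement absolute and squared reconstruction error", {
  x <- matrix(runif(64), 8, 8)
  expect_true(all(score_map(x, x) == 0))
  one <- matrix(1, 4, 4); q <- matrix(0.25, 4, 4)
  expect_true(all(score_map(one, q) == 0.75))
  expect_true(all(score_map(one, q, loss = "squared") == 0.5625))
  y <- matrix(runif(64), 8, 8)
  expect_equal(score_map(x, y, loss = "squared"), score_map(x, y)^2)
  expect_error(score_map(x, matrix(0, 4, 4)), "shape")
})

test_that("the three aggregators reproduce their defining formulas", {
  m <- rbind(c(0, 1), c(2, 3))
  expect_identical(aggregate_score(m, "max"), 3)
  expect_identical(aggregate_score(m, "mean"), 1.5)
  # 1x2 row windows, stride 1: patch means 0.5 and 2.5
  expect_identical(aggregate_score(m, "patch_max", patch_size = c(1, 2),
                                   patch_stride = 1), 2.5)
})

test_that("patch_max equals a brute-force window scan on random maps", {
  set.seed(11)
  for (k in 1:10) {
    map <- matrix(runif(16 * 16), 16, 16)
    expect_equal(aggregate_score(map, "patch_max", patch_size = 4,
                                 patch_stride = 2),
                 brute_patch_max(map, 4, 4, 2, 2))
  }
})

test_that("aggregator ordering holds: mean <= patch_max <= max", {
  set.seed(12)
  for (k in 1:10) {
    map <- matrix(rexp(16 * 16), 16, 16)
    pm <- aggregate_score(map, "patch_max", patch_size = 4, patch_stride = 4)
    expect_lte(aggregate_score(map, "mean"), pm + 1e-12)
    expect_lte(pm, aggregate_score(map, "max") + 1e-12)
  }
})

test_that("AS* search separates classes and matches the exhaustive scan", {
  fit <- fit_as_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_identical(fit$as_star, 0.5)
  expect_identical(fit$accuracy, 1)

  tie <- fit_as_threshold(c(0.5, 0.5), c(0, 1))
  expect_identical(tie$accuracy, 0.5)
  expect_identical(tie$as_star, -0.5)  # smallest candidate on ties

  set.seed(13)
  for (k in 1:30) {
    n <- sample(4:20, 1)
    sc <- round(runif(n), 2)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))
    fit <- fit_as_threshold(sc, lab)
    oracle <- brute_as_threshold(sc, lab)
    expect_equal(fit$accuracy, oracle$acc)
    expect_equal(mean((sc > fit$as_star) == lab), fit$accuracy)
  }
  expect_error(fit_as_threshold(c(1, 2), c(1, 1)), "both")
})

test_that("lambda* search maximizes mean Dice on its grid", {
  gt <- matrix(0, 8, 8); gt[3:5, 3:5] <- 1
  perfect <- gt
  fit <- fit_lambda_threshold(list(perfect), list(gt))
  expect_identical(fit$dice, 1)
  expect_true(fit$lambda_star >= 0 && fit$lambda_star < 1)

  # constant map: predict-all iff its Dice beats the empty prediction
  const <- matrix(0.4, 8, 8)
  fit2 <- fit_lambda_threshold(list(const), list(gt), n_grid = 10)
  d_all <- 2 * sum(gt) / (64 + sum(gt))
  expect_equal(fit2$dice, max(d_all, 0))

  set.seed(14)
  for (k in 1:5) {
    maps <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
    gts <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.3), 8, 8))
    fit <- fit_lambda_threshold(maps, gts, n_grid = 10)
    cand <- sort(unique(c(0, quantile(unlist(maps),
                                      seq(0, 1, length.out = 10),
                                      names = FALSE))))
    md <- sapply(cand, function(lam)
      mean(mapply(function(m, g) brute_dice((m > lam) * 1, g), maps, gts)))
    expect_equal(fit$dice, max(md))
    expect_identical(fit$lambda_star, max(cand[md == max(md)]))
  }
  expect_error(fit_lambda_threshold(list(matrix(1, 4, 4)),
                                    list(matrix(0, 4, 4))), "positive")
})

test_that("binarization uses a strict inequality and is monotone", {
  m <- matrix(c(0.1, 0.9), 1, 2)
  expect_identical(binarize(m, 0.5), matrix(c(0, 1), 1, 2))
  expect_true(all(binarize(m, max(m)) == 0))
  expect_true(all(binarize(m, -1) == 1))
  set.seed(15)
  map <- matrix(runif(100), 10, 10)
  l1 <- sort(runif(2))
  m2 <- binarize(map, l1[2]); m1 <- binarize(map, l1[1])
  expect_true(all(m2 <= m1))
})

test_that("classify alarms strictly above AS* and masks only alarmed frames", {
  map <- matrix(0.2, 8, 8); map[1, 1] <- 0.9
  th <- thresholds(as_star = aggregate_score(map, "max"), lambda_star = 0.5)
  res <- classify(map, th, method = "max")
  expect_false(res$is_abnormal)   # score == AS* raises no alarm
  expect_null(res$mask)

  th2 <- thresholds(as_star = 0.5, lambda_star = 0.5)
  res2 <- classify(map, th2, method = "max")
  expect_true(res2$is_abnormal)
  expect_identical(res2$mask, binarize(map, 0.5))
})
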