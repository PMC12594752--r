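# Minimal neural-network core: stride-1 "same" convolutions (via im2col in
# C++), 2x average pooling / nearest upsampling, dense layers, ReLU family,
# and Adam. All tensors are plain R arrays, images stored H x W x C.
# Forward functions return list(y, cache); backward functions take the cache
# and upstream gradient and return parameter gradients plus dx.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

he_init <- function(fan_in, n, gain = sqrt(2)) {
  stats::rnorm(n, sd = gain / sqrt(fan_in))
}

## ---- convolution ------------------------------------------------------

# All convolutions are 3x3, stride 1, zero-padded "same".
conv_init <- function(cin, cout, k = 3L) {
  list(W = matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout),
       b = numeric(cout))
}

conv_k <- function(p, cin) as.integer(round(sqrt(nrow(p$W) / cin)))

conv_fwd <- function(p, x) {
  x <- as_cube(x)
  d <- dim(x)
  k <- conv_k(p, d[3])
  pad <- (k - 1L) %/% 2L
  cols <- im2col_cpp(x, d[1], d[2], d[3], k, pad)
  y <- crossprod(cols, p$W)                       # (H*W) x cout
  y <- sweep(y, 2L, p$b, "+")
  list(y = array(y, c(d[1], d[2], ncol(p$W))), cache = list(cols = cols, d = d))
}

conv_bwd <- function(p, cache, dy) {
  d <- cache$d
  k <- conv_k(p, d[3])
  pad <- (k - 1L) %/% 2L
  cout <- ncol(p$W)
  dy_mat <- matrix(dy, d[1] * d[2], cout)         # (H*W) x cout
  dW <- cache$cols %*% dy_mat
  db <- colSums(dy_mat)
  dx <- col2im_cpp(p$W %*% t(dy_mat), d[1], d[2], d[3], k, pad)
  list(dW = dW, db = db, dx = array(dx, d))
}

## ---- pooling / upsampling --------------------------------------------

avgpool2_fwd <- function(x) {
  x <- as_cube(x)
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  y <- (x[o1, o2, , drop = FALSE] + x[o1 + 1L, o2, , drop = FALSE] +
        x[o1, o2 + 1L, , drop = FALSE] + x[o1 + 1L, o2 + 1L, , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_bwd <- function(cache, dy) {
  d <- cache
  idx1 <- rep(seq_len(d[1] %/% 2L), each = 2L)
  idx2 <- rep(seq_len(d[2] %/% 2L), each = 2L)
  dy[idx1, idx2, , drop = FALSE] / 4
}

upsample2_fwd <- function(x) {
  x <- as_cube(x)
  d <- dim(x)
  idx1 <- rep(seq_len(d[1]), each = 2L)
  idx2 <- rep(seq_len(d[2]), each = 2L)
  list(y = x[idx1, idx2, , drop = FALSE], cache = d)
}

upsample2_bwd <- function(cache, dy) {
  d <- cache
  o1 <- seq(1L, 2L * d[1], 2L); o2 <- seq(1L, 2L * d[2], 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1L, o2, , drop = FALSE] +
    dy[o1, o2 + 1L, , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , drop = FALSE]
}

## ---- dense ------------------------------------------------------------

dense_init <- function(nin, nout, gain = sqrt(2)) {
  list(W = matrix(he_init(nin, nin * nout, gain), nin, nout), b = numeric(nout))
}

dense_fwd <- function(p, x) {
  y <- drop(crossprod(p$W, as.numeric(x))) + p$b
  list(y = y, cache = as.numeric(x))
}

dense_bwd <- function(p, cache, dy) {
  dy <- as.numeric(dy)
  list(dW = outer(cache, dy), db = dy, dx = drop(p$W %*% dy))
}

## ---- activations ------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  x[!m] <- 0
  list(y = x, cache = m)
}

relu_bwd <- function(cache, dy) {
  dy[!cache] <- 0
  dy
}

lrelu_fwd <- function(x, slope = 0.2) {
  g <- ifelse(x > 0, 1, slope)
  list(y = x * g, cache = g)
}

lrelu_bwd <- function(cache, dy) dy * cache

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bwd <- function(cache, dy) dy * cache * (1 - cache)

## ---- parameter trees and Adam ----------------------------------------

# Parameters are nested lists whose leaves are numeric arrays; the layer
# metadata field "k" (kernel size) is carried along but never updated.
is_param_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tr) {
  if (is.list(tr)) lapply(tr, function(el) tree_map(f, el)) else f(tr)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(f, x, y), a, b)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}

zeros_like <- function(tr) tree_map(function(x) x * 0, tr)

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, st$m, grads)
  st$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, st$v, grads)
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  upd <- tree_map2(function(m, v) lr * (m / c1) / (sqrt(v / c2) + eps),
                   st$m, st$v)
  params <- tree_map2(function(p, u) p - u, params, upd)
  list(params = params, state = st)
}

# Sum two gradient trees (for gradient accumulation over a batch).
tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(tr, s) tree_map(function(x) x * s, tr)

## ---- timestep embedding ----------------------------------------------

# Standard sinusoidal embedding of a (scaled) diffusion timestep.
time_embedding <- function(t, dim = 16L, max_period = 1e4) {
  half <- dim %/% 2L
  freqs <- exp(-log(max_period) * (seq_len(half) - 1L) / half)
  c(sin(t * freqs), cos(t * freqs))
}
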