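# Numerical core of the AA-gapped convolutional network.
#
# A gapped convolution with dilation set M computes, at output bin i,
#   y_i = W0 x_i + sum_{m in M} ( Wm_minus x_{i-m} + Wm_plus x_{i+m} )
# with zero padding at the ends, so the length dimension is preserved.
#
# Activations are (channels x N*B) matrices in sample-fastest column
# order (column = n + N*(bin-1)): a 1-bin shift is then a global column
# offset of N, evaluated in C++ on submatrix views (see
# src/gapped_conv.cpp) without materializing shifted copies.

# (C, B, N) array -> (C, N*B) matrix, columns sample-fastest
.to_sample_fastest <- function(x) {
  d <- dim(x)
  y <- aperm(x, c(1, 3, 2))
  dim(y) <- c(d[1], d[2] * d[3])
  y
}

# He-style initialization for one gapped-conv layer
.gconv_init <- function(c_in, c_out, dil) {
  fan_in <- c_in * (1L + 2L * length(dil))
  sd0 <- sqrt(2 / fan_in)
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sd0), nr, nc)
  list(W0 = rnd(c_out, c_in),
       Wd = lapply(dil, function(m) rnd(c_out, 2L * c_in)),
       b = numeric(c_out),
       bn_gamma = rep(1, c_out), bn_beta = numeric(c_out))
}

.gconv_forward <- function(X2, par, dil, shift_unit) {
  cpp_gconv_forward(X2, par$W0, par$Wd, par$b, as.integer(dil),
                    as.integer(shift_unit))
}

# returns list(dX2, grad); X2 is the cached layer input
.gconv_backward <- function(dY, X2, par, dil, shift_unit) {
  res <- cpp_gconv_backward(dY, X2, par$W0, par$Wd, as.integer(dil),
                            as.integer(shift_unit))
  list(dX2 = res$dX,
       grad = list(W0 = res$W0, Wd = res$Wd, b = as.numeric(res$b)))
}

.bn_forward <- function(Y, par, training, run, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(Y)
    v <- rowMeans(Y * Y) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Y - mu) * invstd
  list(out = par$bn_gamma * xhat + par$bn_beta,
       xhat = xhat, invstd = invstd, run = run)
}

.bn_backward <- function(dY, cache, par) {
  M <- ncol(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * par$bn_gamma
  dX <- cache$invstd / M *
    (M * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dX = dX, bn_gamma = dgamma, bn_beta = dbeta)
}

#' Binary focal loss
#'
#' `FL = -mean( a_t * (1 - p_t)^gamma * log(p_t) )` with
#' `p_t = p` at positive labels and `1 - p` at negatives. With
#' `gamma = 0` and `alpha = NULL` this is exactly binary cross-entropy.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param target 0/1 labels, same shape.
#' @param gamma Focusing parameter (default 2).
#' @param alpha Optional class-balance weight in `(0, 1)` applied to
#'   positives (`1 - alpha` to negatives); `NULL` disables it.
#' @return Scalar mean loss.
#' @export
focal_loss <- function(p, target, gamma = 2, alpha = NULL) {
  eps <- 1e-12
  pt <- pmin(pmax(target * p + (1 - target) * (1 - p), eps), 1 - eps)
  w <- if (is.null(alpha)) 1 else target * alpha + (1 - target) * (1 - alpha)
  mean(-w * (1 - pt)^gamma * log(pt))
}

# gradient of mean focal loss w.r.t. logits z (p = sigmoid(z))
.focal_grad_logits <- function(p, target, gamma, alpha) {
  eps <- 1e-12
  pt <- pmin(pmax(target * p + (1 - target) * (1 - p), eps), 1 - eps)
  w <- if (is.null(alpha)) 1 else target * alpha + (1 - target) * (1 - alpha)
  dl_dpt <- w * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  dpt_dz <- (2 * target - 1) * p * (1 - p)
  dl_dpt * dpt_dz / length(p)
}

# elementwise helpers over a nested parameter tree (lists of numerics)
.tree_map2 <- function(f, a, b) {
  if (is.list(a)) return(mapply(.tree_map2, a = a, b = b,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

.tree_map3 <- function(f, a, b, d) {
  if (is.list(a)) return(mapply(.tree_map3, a = a, b = b, d = d,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b, d)
}

.tree_zero <- function(a) {
  if (is.list(a)) return(lapply(a, .tree_zero))
  a * 0
}

# one Adam step over a parameter tree; state holds m, v, t
.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map3(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}
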