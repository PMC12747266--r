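# Neural-network primitives: initialization, batch normalization, dropout,
# smooth-L1 loss and Adam. All dense math is base-R matrix algebra; segment
# (per-node / per-graph) reductions go through rowsum-based helpers.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -s, s), dim = dims)
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

# Batch normalization over rows (samples or nodes). Training mode uses batch
# statistics (biased variance) and updates the running estimates; eval mode
# uses the running estimates only, which keeps eval outputs independent of
# batch composition.
bn_forward <- function(x, gamma, beta, rmean, rvar, training,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x * x) - mu^2
    v <- pmax(v, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv, training = training),
       rmean = rmean, rvar = rvar)
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  inv <- cache$inv
  n <- nrow(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  if (cache$training) {
    t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
    t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / n, "*")
    dx <- sweep(t1 - t2, 2, inv, "*")
  } else {
    dx <- sweep(dxhat, 2, inv, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  # inverted dropout: scale kept units by 1/(1-p) so eval needs no rescaling
  matrix(stats::rbinom(n[1] * n[2], 1, 1 - p) / (1 - p), n[1], n[2])
}

#' Smooth-L1 (Huber) loss
#'
#' Quadratic for residuals smaller than `beta`, linear beyond:
#' `0.5 d^2 / beta` for `|d| < beta`, else `|d| - beta / 2`, with
#' `d = pred - truth`. Continuous and once-differentiable at `|d| = beta`;
#' robust to outlying activity measurements.
#'
#' @param pred,truth numeric vectors (recycled).
#' @param beta transition point, > 0.
#' @return numeric vector of per-element losses.
#' @examples
#' smooth_l1(0.5, 0)  # 0.125
#' smooth_l1(2, 0)    # 1.5
#' @export
smooth_l1 <- function(pred, truth, beta = 1) {
  if (beta <= 0) stopf("beta must be > 0")
  d <- pred - truth
  ifelse(abs(d) < beta, 0.5 * d^2 / beta, abs(d) - 0.5 * beta)
}

smooth_l1_grad <- function(pred, truth, beta = 1) {
  d <- pred - truth
  ifelse(abs(d) < beta, d / beta, sign(d))
}

adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

adam_step <- function(params, grads, opt, lr = 1e-3, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
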