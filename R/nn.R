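# Shared building blocks for the two small networks (the U-Net landmark
# localizer and the LeNet-type O2Sat regressor): parameter initialization,
# inverted dropout, and an Adam optimizer over named parameter lists.
# Convolution / pooling / upsampling kernels live in src/ops.cpp; each
# parameter is a list(W, b) with W of shape Cout x (k*k*Cin).

conv_param <- function(c_in, c_out, k = 3) {
  fan_in <- k * k * c_in
  list(W = matrix(rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)), c_out, fan_in),
       b = numeric(c_out))
}

dense_param <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

# Leaky rectifier (slope 0.01): negative units keep a trickle of gradient,
# preventing whole-network activation death under MSE heatmap targets.
relu <- function(x) { neg <- x < 0; x[neg] <- 0.01 * x[neg]; x }
relu_bwd <- function(dy, y) { dy[y <= 0] <- 0.01 * dy[y <= 0]; dy }

# Inverted dropout mask: zeros with probability p, survivors scaled by
# 1/(1-p) so expected activations are unchanged. p = 0 gives all ones.
dropout_mask <- function(dims, p) {
  if (p <= 0) return(array(1, dim = dims))
  array((runif(prod(dims)) >= p) / (1 - p), dim = dims)
}

dense_fwd <- function(x, par) as.numeric(par$W %*% x + par$b)
dense_bwd <- function(x, par, dy) {
  list(dx = as.numeric(crossprod(par$W, dy)),
       dW = outer(as.numeric(dy), as.numeric(x)),
       db = as.numeric(dy))
}

# Adam over a flat named list of parameter tensors (recursively: every
# leaf is a numeric array). State carries first/second moments and step.
adam_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# Clip a gradient list to a maximum global L2 norm (training stabilizer
# for the higher step sizes used by shortened schedules).
grad_clip <- function(g, max_norm) {
  total <- sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
  if (!is.finite(total) || total <= max_norm) return(g)
  grad_scale(g, max_norm / total)
}

# Elementwise sum of two parameter/gradient lists with the same shape.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  Map(function(x, y) if (is.list(x)) grad_add(x, y) else x + y, a, b)
}

grad_scale <- function(a, s) {
  rapply(a, function(x) x * s, how = "replace")
}
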