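#' @useDynLib tagloc3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal neural-network core: dense stacks with manual backprop and
# Adam/AdamW. Everything operates on base matrices (rows = samples) so all
# heavy lifting is BLAS. Parameters and gradients are (possibly nested)
# named lists of arrays with identical structure; the optimizer recurses
# over that structure. Correctness is guarded by finite-difference
# gradient-check tests.

# ---- activations -----------------------------------------------------------

.act_fun <- function(name) {
  switch(name,
    identity = list(f = function(x) x,
                    df = function(x, y) 1),
    relu = list(f = function(x) pmax(x, 0),
                df = function(x, y) (x > 0) * 1),
    sigmoid = list(f = function(x) 1 / (1 + exp(-x)),
                   df = function(x, y) y * (1 - y)),
    tanh = list(f = tanh,
                df = function(x, y) 1 - y^2),
    gelu = list(
      f = function(x) {
        0.5 * x * (1 + tanh(0.7978845608028654 * (x + 0.044715 * x^3)))
      },
      df = function(x, y) {
        u <- 0.7978845608028654 * (x + 0.044715 * x^3)
        t <- tanh(u)
        0.5 * (1 + t) + 0.5 * x * (1 - t^2) *
          0.7978845608028654 * (1 + 3 * 0.044715 * x^2)
      }),
    stop("unknown activation: ", name))
}

.init_mat <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

# ---- dense stack (MLP) -----------------------------------------------------

# sizes: c(input, hidden..., output); acts: one name per non-input layer
mlp_new <- function(sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1L)
  params <- list()
  for (l in seq_along(acts)) {
    params[[paste0("W", l)]] <- .init_mat(sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  list(sizes = sizes, acts = acts, params = params)
}

mlp_forward <- function(net, X, keep_cache = FALSE) {
  A <- X
  cache <- if (keep_cache) list(A0 = X) else NULL
  for (l in seq_along(net$acts)) {
    Z <- sweep(A %*% net$params[[paste0("W", l)]], 2L,
               net$params[[paste0("b", l)]], "+")
    A <- .act_fun(net$acts[l])$f(Z)
    if (keep_cache) {
      cache[[paste0("Z", l)]] <- Z
      cache[[paste0("A", l)]] <- A
    }
  }
  list(out = A, cache = cache)
}

# dOut: gradient of the loss wrt the network output (same shape as out)
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$acts)
  grads <- vector("list", 2L * L)
  names(grads) <- names(net$params)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    act <- .act_fun(net$acts[l])
    dZ <- dA * act$df(cache[[paste0("Z", l)]], cache[[paste0("A", l)]])
    A_prev <- if (l == 1L) cache$A0 else cache[[paste0("A", l - 1L)]]
    grads[[paste0("W", l)]] <- crossprod(A_prev, dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    dA <- tcrossprod(dZ, net$params[[paste0("W", l)]])
  }
  list(grads = grads, dX = dA)
}

# ---- Adam / AdamW over nested parameter lists ------------------------------

opt_init <- function(params) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

# decoupled weight decay (AdamW); wd = 0 gives plain Adam
opt_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"),
           m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# elementwise sum of two gradient structures
.grad_add <- function(a, b) {
  if (is.list(a)) Map(.grad_add, a, b) else a + b
}

.grad_scale <- function(a, s) {
  if (is.list(a)) lapply(a, .grad_scale, s = s) else a * s
}

# global L2 norm of a gradient structure (for clipping / diagnostics)
.grad_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
}
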