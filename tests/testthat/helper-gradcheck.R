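# finite-difference gradient checking utilities shared by the NN tests

all_param_paths <- function(p) {
  out <- list()
  rec <- function(p, prefix) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else as.list(names(p))
      for (k in keys) rec(p[[k]], c(prefix, list(k)))
    } else out[[length(out) + 1L]] <<- prefix
  }
  rec(p, list())
  out
}

param_get <- function(p, path) { for (k in path) p <- p[[k]]; p }

param_set <- function(p, path, v) {
  if (length(path) == 1L) { p[[path[[1]]]] <- v; return(p) }
  p[[path[[1]]]] <- param_set(p[[path[[1]]]], path[-1], v)
  p
}

# worst relative error between analytic and central-difference gradients
# over randomly picked parameter entries
gradcheck_worst <- function(loss_and_grad, params, n_checks = 12,
                            eps = 1e-5, seed = 99) {
  g <- loss_and_grad(params)$grads
  paths <- all_param_paths(params)
  set.seed(seed)
  worst <- 0
  for (rep in seq_len(n_checks)) {
    path <- paths[[sample(length(paths), 1L)]]
    arr <- param_get(params, path)
    i <- sample(length(arr), 1L)
    a2 <- arr; a2[i] <- arr[i] + eps
    lp <- loss_and_grad(param_set(params, path, a2))$loss
    a2[i] <- arr[i] - eps
    lm <- loss_and_grad(param_set(params, path, a2))$loss
    num <- (lp - lm) / (2 * eps)
    ana <- param_get(g, path)[i]
    worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
  }
  worst
}
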