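## Minimal dense-network toolkit: forward/backward passes are written
## out by hand (no autodiff stack exists here) and verified against
## finite differences in the tests. Parameters live in named nested
## lists of numeric arrays; AdamW walks the tree.

`%||%` <- function(a, b) if (is.null(a)) b else a

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
delu <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
dsoftplus <- function(x) 1 / (1 + exp(-x))

dense_init <- function(n_in, n_out) {
  ## He-style scaling, sensible for ELU
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

## widths: hidden layer sizes; returns list of dense layers in -> hidden*
mlp_init <- function(n_in, widths) {
  sizes <- c(n_in, widths)
  lapply(seq_len(length(sizes) - 1),
         function(i) dense_init(sizes[i], sizes[i + 1]))
}

## forward through hidden stack with ELU; returns activations cache
mlp_forward <- function(layers, X) {
  pre <- list(); act <- list(X)
  H <- X
  for (i in seq_along(layers)) {
    Z <- H %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(H), length(layers[[i]]$b), byrow = TRUE)
    H <- elu(Z)
    pre[[i]] <- Z
    act[[i + 1]] <- H
  }
  list(out = H, pre = pre, act = act)
}

## backprop through the hidden stack; gout = dL/d(out)
## returns list(gin = dL/dX, grads = per-layer list(W, b))
mlp_backward <- function(layers, cache, gout) {
  grads <- vector("list", length(layers))
  g <- gout
  for (i in rev(seq_along(layers))) {
    gz <- g * delu(cache$pre[[i]])
    grads[[i]] <- list(W = t(cache$act[[i]]) %*% gz, b = colSums(gz))
    g <- gz %*% t(layers[[i]]$W)
  }
  list(gin = g, grads = grads)
}

## ---- parameter-tree utilities ----

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0)
}

## decoupled weight decay (AdamW); returns list(params, state)
adamw_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-6,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * (u + weight_decay * p), params, upd)
  list(params = params, state = state)
}
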