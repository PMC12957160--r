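# Minimal dense feedforward network with tanh hidden units, hand-rolled
# backprop and Adam. Kept internal: the PINN module is the public surface.
# Weights use Glorot-uniform initialization from a local, restorable RNG.

nn_init <- function(sizes, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -r, r),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

# forward pass; returns output and the per-layer activations needed by
# nn_backward. Hidden layers tanh, output layer linear.
nn_forward <- function(net, x) {
  L <- length(net$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- x
  a <- x
  for (l in seq_len(L)) {
    z <- a %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    a <- if (l < L) tanh(z) else z
    acts[[l + 1]] <- a
  }
  list(out = a, acts = acts)
}

# gradient of a scalar loss w.r.t. all weights, given dL/d(output)
nn_backward <- function(net, cache, dout) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    a_prev <- cache$acts[[l]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a_here <- cache$acts[[l]]           # tanh activation of layer l-1 output
      delta <- (delta %*% t(net$W[[l]])) * (1 - a_here^2)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(net = net, state = state)
}
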