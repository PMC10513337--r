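# Shared neural-network primitives used by the segmentation U-Net and the
# VAE: parameter initialization, activations, Adam, and thin wrappers over
# the compiled conv/pool/upsample kernels. Parameters are plain R arrays so
# models serialize with saveRDS and remain fully deterministic under R's RNG.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(g, y) {
  g[y <= 0] <- 0
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

# He-normal initialization for a k x k convolution, cin -> cout channels.
# Weight layout: row index = cin_channel * k^2 + dy * k + dx (0-based),
# matching the compiled im2col column ordering.
nn_conv_init <- function(k, cin, cout) {
  list(
    w = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               nrow = k * k * cin, ncol = cout),
    b = numeric(cout),
    k = k
  )
}

nn_dense_init <- function(nin, nout) {
  list(w = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

conv_fwd <- function(x, p) .cm_conv2d_fwd(as_cube(x), p$w, p$b, p$k)
conv_bwd <- function(x, p, gout) .cm_conv2d_bwd(as_cube(x), p$w, as_cube(gout), p$k)

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$w) + length(p$b), numeric(1)))
}

# Adam over a nested parameter list (each element has $w and $b).
adam_init <- function(params) {
  zero <- function(p) list(w = p$w * 0, b = p$b * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    for (slot in c("w", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / (1 - beta1^t)
      vhat <- state$v[[nm]][[slot]] / (1 - beta2^t)
      params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Numerically stable mean binary cross-entropy from logits, with gradient.
bce_with_logits <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  grad <- (sigmoid(z) - y) / length(z)
  list(loss = loss, grad = grad)
}
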