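# Minimal dense-network machinery shared by the image translator and the
# TL-embedding network: He-initialized weight lists, ReLU forward/backward,
# and an Adam optimizer over flat parameter lists. All matmuls go through
# BLAS; batches are row-major (one sample per row).

nn_init_dense <- function(sizes, seed, scale = NULL) {
  with_seed(seed, {
    params <- list()
    for (i in seq_len(length(sizes) - 1)) {
      fan_in <- sizes[i]
      sd <- if (is.null(scale)) sqrt(2 / fan_in) else scale
      params[[paste0("W", i)]] <-
        matrix(stats::rnorm(fan_in * sizes[i + 1], 0, sd), fan_in, sizes[i + 1])
      params[[paste0("b", i)]] <- numeric(sizes[i + 1])
    }
    params
  })
}

# forward through dense layers with ReLU on all but the last; returns the
# output and the cache needed for backprop
nn_forward <- function(params, X, nlayers) {
  h <- X
  cache <- vector("list", nlayers)
  for (i in seq_len(nlayers)) {
    cache[[i]] <- h
    z <- h %*% params[[paste0("W", i)]] +
      matrix(params[[paste0("b", i)]], nrow(h), length(params[[paste0("b", i)]]),
             byrow = TRUE)
    h <- if (i < nlayers) pmax(z, 0) else z
    if (i < nlayers) cache[[i]] <- list(inp = cache[[i]], act = h)
  }
  list(out = h, cache = cache)
}

# backward pass: dout is the gradient at the (linear) output; returns
# gradients for every parameter plus (optionally) the gradient at the input
nn_backward <- function(params, fwd, dout, nlayers, need_input = TRUE) {
  grads <- list()
  g <- dout
  for (i in rev(seq_len(nlayers))) {
    inp <- if (i < nlayers) fwd$cache[[i]]$inp else fwd$cache[[i]]
    if (i < nlayers) g <- g * (fwd$cache[[i]]$act > 0)
    grads[[paste0("W", i)]] <- crossprod(inp, g)
    grads[[paste0("b", i)]] <- colSums(g)
    if (i > 1 || need_input)
      g <- tcrossprod(g, params[[paste0("W", i)]])
  }
  if (need_input) grads$input <- g
  grads
}

adam_init <- function(params) {
  # `+ 0` forces fresh arrays: the fused update mutates params/state in
  # place, so they must not share memory with anything else
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       params = lapply(params, function(p) p + 0),
       t = 0)
}

# fused in-place Adam over a parameter list; returns the updated list (the
# same arrays, mutated) plus state
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- state$params
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    .adam_update_cpp(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                     lr, beta1, beta2, eps, bc1, bc2)
  }
  list(params = params, state = state)
}

check_finite_params <- function(params, where) {
  ok <- all(vapply(params, function(p) all(is.finite(p)), logical(1)))
  if (!ok) stop(sprintf("non-finite parameters after %s", where))
  invisible(TRUE)
}
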