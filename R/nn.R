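# Parameter containers, initialization, the Adam optimizer and global-norm
# gradient clipping shared by the denoiser and the bond refiner.

# Kaiming-style initialization for a dense layer.
fd_init_dense <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

# Register a dense layer's parameters under `prefix` into a parameter list.
fd_add_dense <- function(params, prefix, n_in, n_out) {
  params[[paste0(prefix, ".W")]] <- fd_init_dense(n_in, n_out)
  params[[paste0(prefix, ".b")]] <- matrix(0, 1, n_out)
  params
}

# Apply a registered dense layer on the tape.
fd_dense <- function(tp, params, prefix, x) {
  W <- tp$param(paste0(prefix, ".W"), params[[paste0(prefix, ".W")]])
  b <- tp$param(paste0(prefix, ".b"), params[[paste0(prefix, ".b")]])
  tp$add(tp$matmul(x, W), b)
}

# Register batch-normalization parameters (scale/shift + running stats kept
# in a separate state list updated by the caller).
fd_add_bn <- function(params, prefix, k) {
  params[[paste0(prefix, ".gamma")]] <- matrix(1, 1, k)
  params[[paste0(prefix, ".beta")]] <- matrix(0, 1, k)
  params
}

# Batch normalization on the tape, always on the current graph's node
# statistics. The activations' scale is strongly diffusion-time dependent,
# so frozen running statistics (accumulated across all t) systematically
# mis-normalize the small-t regime; node-batch statistics are well defined
# at sampling time (each graph is a batch) and keep training and inference
# consistent. Running statistics are still accumulated in training mode so
# checkpoints carry them.
fd_bn <- function(tp, params, state, prefix, x, training = TRUE,
                  momentum = 0.1) {
  g <- tp$param(paste0(prefix, ".gamma"), params[[paste0(prefix, ".gamma")]])
  b <- tp$param(paste0(prefix, ".beta"), params[[paste0(prefix, ".beta")]])
  key_m <- paste0(prefix, ".run_mean"); key_v <- paste0(prefix, ".run_var")
  if (training) {
    A <- tp$value(x)
    mu <- colMeans(A); va <- colMeans(A^2) - mu^2
    if (is.null(state[[key_m]])) {
      state[[key_m]] <- mu; state[[key_v]] <- va
    } else {
      state[[key_m]] <- (1 - momentum) * state[[key_m]] + momentum * mu
      state[[key_v]] <- (1 - momentum) * state[[key_v]] + momentum * va
    }
  }
  tp$batchnorm(x, g, b)
}

# Two- or three-layer MLP with SiLU activations (final layer linear unless
# `final_act`).
fd_add_mlp <- function(params, prefix, dims) {
  for (k in seq_len(length(dims) - 1)) {
    params <- fd_add_dense(params, paste0(prefix, ".l", k),
                           dims[k], dims[k + 1])
  }
  params
}

fd_mlp <- function(tp, params, prefix, x, n_layers, final_act = FALSE) {
  h <- x
  for (k in seq_len(n_layers)) {
    h <- fd_dense(tp, params, paste0(prefix, ".l", k), h)
    if (k < n_layers || final_act) h <- tp$silu(h)
  }
  h
}

#' Global-norm gradient clipping
#'
#' Rescales a gradient list so its global L2 norm does not exceed
#' `max_norm`.
#'
#' @param grads Named list of gradient matrices.
#' @param max_norm Clipping threshold.
#' @return List with `grads` (clipped) and `norm` (pre-clip global norm).
#' @export
fd_clip_grads <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  list(grads = grads, norm = total)
}

# Adam optimizer state and update (standard bias-corrected moments).
fd_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

fd_adam_step <- function(params, grads, opt, lr = 2e-4, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
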