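# The E(3)-equivariant denoising network.
#
# A stack of equivariant graph convolution layers (EGCL) over the fully
# connected graph of context atoms (pocket + fragment or scaffold, frozen)
# and generated atoms (noisy). Messages and feature updates consume only
# rotation/translation-invariant quantities (scalar features, squared
# distances and their Gaussian radial-basis expansion), while coordinate
# updates are linear in relative positions, so coordinate outputs rotate
# with the input frame and feature outputs do not. Context atoms receive a
# zero coordinate update at every layer. The predicted noise is the final
# minus the initial coordinates (and a linear head on final features),
# restricted to the generated atoms.

#' Denoiser configuration
#'
#' @param n_layers Number of EGCL layers.
#' @param hidden_dim Feature width.
#' @param K Number of radial-basis centers.
#' @param d_max Span (Angstrom) of the uniformly spaced centers.
#' @param sigma Shared kernel bandwidth (Angstrom); default `d_max / K`.
#' @param centers Optional explicit centers (overrides the uniform grid).
#' @return An object of class `fd_denoiser_config`.
#' @export
fd_denoiser_config <- function(n_layers = 6L, hidden_dim = 128L, K = 16L,
                               d_max = 10, sigma = d_max / K,
                               centers = NULL) {
  if (is.null(centers)) centers <- seq(0, d_max, length.out = K)
  stopifnot(length(centers) == K, sigma > 0, n_layers >= 1, hidden_dim >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 K = as.integer(K), d_max = d_max, sigma = sigma,
                 centers = as.numeric(centers)),
            class = "fd_denoiser_config")
}

#' Gaussian radial-basis expansion of a distance
#'
#' `e_k = exp(-(d - mu_k)^2 / (2 sigma^2))`, a rigid-motion-invariant
#' soft binning of the distance axis.
#'
#' @param d Nonnegative distance(s), Angstrom.
#' @param config An [fd_denoiser_config()].
#' @return Matrix `length(d) x K` with values in `(0, 1]`.
#' @export
fd_rbf_expand <- function(d, config) {
  if (any(d < 0)) stop("distances must be nonnegative")
  outer(as.numeric(d), config$centers,
        function(x, mu) exp(-(x - mu)^2 / (2 * config$sigma^2)))
}

# Feature layout of a graph node: element channels (vocabulary + virtual),
# 4 role flags (pocket / fragment / scaffold / generated), anchor bit,
# time conditioning (t/T plus sinusoidal features, which let the network
# resolve the strongly time-dependent noise scale).
#' @rdname fd_assemble_graph
#' @export
fd_n_feature_channels <- function() length(fd_element_vocab()) + 1L

# Scale at which one-hot type channels are diffused. Unit one-hots drown
# in unit Gaussian noise over most of the schedule; a larger channel
# magnitude raises the type signal-to-noise ratio mid-trajectory so slot
# types commit reliably during reverse sampling. Decoding (arg-max) is
# scale free.
fd_type_scale <- function() 4
.fd_time_freqs <- c(1, 2, 4, 8)
fd_time_features <- function(t_frac) {
  c(t_frac, sin(2 * pi * .fd_time_freqs * t_frac),
    cos(2 * pi * .fd_time_freqs * t_frac))
}
#' @rdname fd_assemble_graph
#' @export
fd_node_input_dim <- function() {
  fd_n_feature_channels() + 4L + 1L + 1L + 2L * length(.fd_time_freqs)
}

#' Initialize denoiser parameters
#'
#' @param config An [fd_denoiser_config()].
#' @param seed Integer seed for the initialization draw.
#' @return Model list: `params`, `config`, `state` (running batch-norm
#'   statistics, an environment), `version`.
#' @export
fd_denoiser_init <- function(config = fd_denoiser_config(), seed = 1L) {
  h <- config$hidden_dim
  ein <- 2 * h + 1 + config$K
  fd_with_seed(seed, {
    params <- list()
    params <- fd_add_dense(params, "embed", fd_node_input_dim(), h)
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("egcl", l)
      params <- fd_add_mlp(params, paste0(pre, ".phi_e"), c(ein, h, h))
      params <- fd_add_dense(params, paste0(pre, ".phi_h1"), 2 * h, h)
      params <- fd_add_bn(params, paste0(pre, ".bn1"), h)
      params <- fd_add_dense(params, paste0(pre, ".phi_h2"), h, h)
      params <- fd_add_bn(params, paste0(pre, ".bn2"), h)
      params <- fd_add_mlp(params, paste0(pre, ".phi_r"), c(ein, h, h, 1))
      # small initial coordinate head keeps early updates stable
      params[[paste0(pre, ".phi_r.l3.W")]] <-
        params[[paste0(pre, ".phi_r.l3.W")]] * 0.1
    }
    params <- fd_add_dense(params, "out_feat", h, fd_n_feature_channels())
    list(params = params, config = config, state = new.env(),
         version = "fragdiff-denoiser-1")
  })
}

#' Equivariant network forward pass on a tape
#'
#' Low-level entry used by training, sampling and the symmetry tests.
#' @param tp A tape from [fd_tape()].
#' @param model From [fd_denoiser_init()].
#' @param h0 Node feature matrix (n x input dim).
#' @param r0 Node coordinates (n x 3).
#' @param gen_mask Logical; TRUE marks generated (noisy) atoms.
#' @param training Batch-statistics mode for normalization layers.
#' @param gain Output preconditioning factor (see [fd_predict_noise()]).
#' @return Tape node ids `eps_coords`, `eps_features`.
#' @export
fd_egnn_forward <- function(tp, model, h0, r0, gen_mask, training = FALSE,
                            gain = 1) {
  cfg <- model$config
  n <- nrow(h0)
  idx <- which(outer(seq_len(n), seq_len(n), `!=`), arr.ind = TRUE)
  ei <- idx[, 1]; ej <- idx[, 2]
  centers <- tp$leaf(matrix(cfg$centers, 1))
  ones_k <- tp$leaf(matrix(1, 1, cfg$K))
  mask <- tp$leaf(matrix(as.numeric(gen_mask), ncol = 1))
  r_in <- tp$leaf(r0)
  h <- fd_dense(tp, model$params, "embed", tp$leaf(h0))
  r <- r_in
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("egcl", l)
    ri <- tp$gather(r, ei); rj <- tp$gather(r, ej)
    diff <- tp$sub(ri, rj)
    d2 <- tp$rowsums(tp$square(diff))
    d <- tp$sqrt_(d2)
    dmat <- tp$matmul(d, ones_k)
    rbf <- tp$exp_(tp$scale(tp$square(tp$sub(dmat, centers)),
                            -1 / (2 * cfg$sigma^2)))
    hi <- tp$gather(h, ei); hj <- tp$gather(h, ej)
    ein <- tp$concat(c(hi, hj, d2, rbf))
    msg <- fd_mlp(tp, model$params, paste0(pre, ".phi_e"), ein, 2,
                  final_act = TRUE)
    magg <- tp$segsum(msg, ei, n)
    u <- fd_dense(tp, model$params, paste0(pre, ".phi_h1"),
                  tp$concat(c(h, magg)))
    u <- fd_bn(tp, model$params, model$state, paste0(pre, ".bn1"), u,
               training = training)
    u <- tp$silu(u)
    u <- fd_dense(tp, model$params, paste0(pre, ".phi_h2"), u)
    u <- fd_bn(tp, model$params, model$state, paste0(pre, ".bn2"), u,
               training = training)
    h <- tp$add(h, u)
    s <- fd_mlp(tp, model$params, paste0(pre, ".phi_r"), ein, 3)
    coef <- tp$mul(diff, tp$recip(tp$addc(d, 1)))
    disp <- tp$segsum(tp$mul(coef, s), ei, n)
    r <- tp$add(r, tp$mul(disp, mask))
  }
  eps_r_all <- if (gain == 1) tp$sub(r, r_in) else
    tp$scale(tp$sub(r, r_in), gain)
  feat <- fd_dense(tp, model$params, "out_feat", h)
  if (gain != 1) feat <- tp$scale(feat, gain)
  gen_idx <- which(gen_mask)
  if (!any(is.finite(tp$value(eps_r_all)))) {
    stop("non-finite coordinates in the denoiser forward pass")
  }
  list(eps_coords = tp$gather(eps_r_all, gen_idx),
       eps_features = tp$gather(feat, gen_idx))
}

#' Context centroid (translation gauge)
#'
#' The mean of the conditioning context's coordinates; the diffusion chain
#' operates on coordinates relative to it, shared by training, prediction
#' and sampling.
#' @param context An [fd_context()].
#' @return Length-3 numeric vector.
#' @export
fd_context_centroid <- function(context) {
  ctx_coords <- context$pocket$atoms$coords
  other <- if (identical(context$stage, "scaffold")) {
    context$fragment$atoms$coords
  } else context$scaffold$coords
  colMeans(rbind(ctx_coords, other))
}

#' Assemble the denoiser input graph
#'
#' Builds node features (element channels, role flags, anchor bit, time
#' features), centered coordinates and the generated-atom mask for a
#' conditioning context plus noisy atoms.
#' @param noisy_coords,noisy_feats Noisy-atom state.
#' @param context An [fd_context()].
#' @param t_frac Time fraction t/T.
#' @return List `h0`, `r0`, `gen_mask`, `centroid`.
#' @export
fd_assemble_graph <- function(noisy_coords, noisy_feats, context, t_frac) {
  nf <- fd_n_feature_channels()
  onehot_pad <- function(atoms) {
    oh <- atoms$element_onehot
    cbind(oh, matrix(0, nrow(oh), nf - ncol(oh)))
  }
  role <- function(n, k) {
    m <- matrix(0, n, 4); if (n > 0) m[, k] <- 1; m
  }
  pk <- context$pocket$atoms
  ctx_feats <- onehot_pad(pk)
  ctx_roles <- role(fd_n_atoms(pk), 1)
  ctx_anchor <- numeric(fd_n_atoms(pk))
  ctx_coords <- pk$coords
  if (identical(context$stage, "scaffold")) {
    fr <- context$fragment
    anc <- numeric(fd_n_atoms(fr$atoms)); anc[fr$anchors] <- 1
    ctx_feats <- rbind(ctx_feats, onehot_pad(fr$atoms))
    ctx_roles <- rbind(ctx_roles, role(fd_n_atoms(fr$atoms), 2))
    ctx_anchor <- c(ctx_anchor, anc)
    ctx_coords <- rbind(ctx_coords, fr$atoms$coords)
  } else {
    sc <- context$scaffold
    ctx_feats <- rbind(ctx_feats, onehot_pad(sc))
    ctx_roles <- rbind(ctx_roles, role(fd_n_atoms(sc), 3))
    ctx_anchor <- c(ctx_anchor, numeric(fd_n_atoms(sc)))
    ctx_coords <- rbind(ctx_coords, sc$coords)
  }
  n_ctx <- nrow(ctx_coords); n_gen <- nrow(noisy_coords)
  centroid <- colMeans(ctx_coords)
  tf <- fd_time_features(t_frac)
  h0 <- rbind(
    cbind(ctx_feats, ctx_roles, ctx_anchor,
          matrix(tf, n_ctx, length(tf), byrow = TRUE)),
    cbind(noisy_feats, role(n_gen, 4), numeric(n_gen),
          matrix(tf, n_gen, length(tf), byrow = TRUE)))
  r0 <- sweep(rbind(ctx_coords, noisy_coords), 2, centroid)
  list(h0 = h0, r0 = r0,
       gen_mask = c(rep(FALSE, n_ctx), rep(TRUE, n_gen)),
       centroid = centroid)
}

#' Predict diffusion noise for generated atoms
#'
#' Builds the fully connected graph over context and noisy atoms (the
#' system is first translated so the context centroid sits at the origin,
#' fixing the translation gauge), runs the EGCL stack and returns the
#' coordinate output minus the input coordinates together with the feature
#' head, restricted to the noisy atoms.
#'
#' @param noisy_coords `n_gen x 3` coordinates of the noisy atoms.
#' @param noisy_feats `n_gen x (vocab + 1)` continuous type channels.
#' @param context An [fd_context()].
#' @param t Diffusion step.
#' @param model From [fd_denoiser_init()] (or a trained checkpoint).
#' @param T_total Total steps (for the `t/T` time feature).
#' @param training Use batch statistics (training) or accumulated running
#'   statistics (sampling).
#' @param schedule Optional [fd_make_schedule()]; when given, the network
#'   output is read as the predicted clean state (its final coordinates as
#'   the denoised positions, the feature head as the denoised type
#'   channels) and converted analytically to predicted noise,
#'   `eps = (x_t - sqrt(abar_t) x0hat) / sqrt(1 - abar_t)`. Without a
#'   schedule the raw output-minus-input form is returned.
#' @return List `eps_coords` (`n_gen x 3`), `eps_features`
#'   (`n_gen x (vocab + 1)`).
#' @export
fd_predict_noise <- function(noisy_coords, noisy_feats, context, t, model,
                             T_total, training = FALSE, schedule = NULL) {
  if (nrow(noisy_coords) == 0) stop("no noisy atoms to denoise")
  if (fd_n_atoms(context$pocket$atoms) == 0) stop("empty pocket context")
  g <- fd_assemble_graph(noisy_coords, noisy_feats, context, t / T_total)
  tp <- fd_tape()
  out <- fd_egnn_forward(tp, model, g$h0, g$r0, g$gen_mask,
                         training = training)
  disp <- tp$value(out$eps_coords)
  feat <- tp$value(out$eps_features)
  if (is.null(schedule)) {
    return(list(eps_coords = disp, eps_features = feat))
  }
  ab <- schedule$alpha_bar[t]
  # clean-state conversion in the centered frame: the diffusion chain is
  # defined on coordinates relative to the context centroid, which keeps
  # the predicted noise exactly translation invariant
  xt_c <- sweep(noisy_coords, 2, g$centroid)
  x0hat_c <- xt_c + disp             # the network's final coordinates
  list(eps_coords = (xt_c - sqrt(ab) * x0hat_c) / sqrt(1 - ab),
       eps_features = (noisy_feats - sqrt(ab) * feat) / sqrt(1 - ab))
}
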