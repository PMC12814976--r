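# The two conditional diffusion stages.
#
# Stage 1 (scaffold): conditioned on (pocket, seed fragment, anchors); new
# atoms are initialized from Gaussian noise centered on the anchors'
# centroid and denoised over T reverse steps while the context stays
# frozen. Stage 2 (R-group): conditioned on (pocket, scaffold); exactly 10
# padded slots are denoised under the polynomial schedule, slots decoding
# to the virtual category are dropped. The two stages train separately,
# each with its own parameters (decoupled training).

#' Stage conditioning context
#'
#' @param stage `"scaffold"` or `"rgroup"`.
#' @param pocket An [fd_pocket()].
#' @param fragment Seed [fd_fragment()] with nonempty anchors (scaffold
#'   stage).
#' @param scaffold An `fd_atomset` (R-group stage).
#' @param attach_idx Optional scaffold atom index marking the attachment
#'   region (R-group stage initialization; defaults to the scaffold
#'   centroid).
#' @return An object of class `fd_context`.
#' @export
fd_context <- function(stage = c("scaffold", "rgroup"), pocket,
                       fragment = NULL, scaffold = NULL, attach_idx = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(pocket, "fd_pocket"))
  if (fd_n_atoms(pocket$atoms) == 0) stop("pocket context is empty")
  if (stage == "scaffold") {
    if (is.null(fragment) || !inherits(fragment, "fd_fragment")) {
      stop("scaffold stage requires a seed fragment")
    }
    if (!length(fragment$anchors)) stop("seed fragment has no anchors")
  } else {
    if (is.null(scaffold) || !inherits(scaffold, "fd_atomset") ||
        fd_n_atoms(scaffold) == 0) {
      stop("rgroup stage requires a nonempty scaffold")
    }
  }
  structure(list(stage = stage, pocket = pocket, fragment = fragment,
                 scaffold = scaffold, attach_idx = attach_idx),
            class = "fd_context")
}

# ---- Size model -----------------------------------------------------------

#' Empirical size model
#'
#' Histogram over new-atom counts, sampled when the caller does not fix the
#' number of atoms to generate (the sizes of generated molecules follow the
#' training-set size distribution).
#'
#' @param counts Integer vector of observed new-atom counts (or a named
#'   probability vector via `probs`).
#' @param probs Optional named probabilities (names = counts).
#' @return An object of class `fd_size_model`.
#' @export
fd_size_model <- function(counts = NULL, probs = NULL) {
  if (is.null(probs)) {
    if (!length(counts)) stop("empty size histogram")
    tab <- table(counts)
    probs <- as.numeric(tab) / sum(tab)
    names(probs) <- names(tab)
  }
  if (!length(probs) || abs(sum(probs) - 1) > 1e-8) {
    stop("size histogram probabilities must sum to 1")
  }
  structure(list(support = as.integer(names(probs)),
                 probs = as.numeric(probs)),
            class = "fd_size_model")
}

#' Draw a size from the model
#' @param model An [fd_size_model()].
#' @param seed Integer seed (deterministic draw).
#' @return Integer count.
#' @export
fd_sample_size <- function(model, seed) {
  stopifnot(inherits(model, "fd_size_model"))
  fd_with_seed(seed, {
    if (length(model$support) == 1) model$support else
      sample(model$support, 1, prob = model$probs)
  })
}

# ---- Stage examples -------------------------------------------------------

#' Convert a toy complex into a training tuple
#'
#' Canonical tuple shape shared with [fd_build_dataset()]: pocket, seed
#' fragment, scaffold (an `fd_fragment` whose anchor is the attachment
#' atom), R-group, and the seed's indices inside the scaffold.
#' @param cx Output of [fd_make_toy_complex()].
#' @return A training tuple list.
#' @export
fd_toy_tuple <- function(cx) {
  sc_idx <- cx$scaffold_idx
  sc_bonds <- cx$ligand$bonds[cx$ligand$bonds$i %in% sc_idx &
                                cx$ligand$bonds$j %in% sc_idx, , drop = FALSE]
  if (nrow(sc_bonds)) {
    sc_bonds$i <- match(sc_bonds$i, sc_idx)
    sc_bonds$j <- match(sc_bonds$j, sc_idx)
  }
  anchors_sc <- if (!is.null(cx$attachment)) {
    match(cx$attachment[1], sc_idx)
  } else 1L
  list(pocket = cx$pocket,
       seed = cx$fragment,
       scaffold = fd_fragment(cx$scaffold, anchors = anchors_sc,
                              bonds = sc_bonds),
       rgroup = cx$rgroup,
       seed_in_scaffold = match(cx$fragment_idx, sc_idx),
       complex_id = cx$pocket$source_id, template_id = "toy")
}

#' Clean training targets for one tuple and stage
#'
#' Returns the conditioning context plus the x0 coordinates and type
#' channels of the atoms the stage must generate (scaffold stage: scaffold
#' minus seed; R-group stage: the R-group padded with virtual slots), or
#' NULL when the tuple offers nothing for the stage.
#' @param tuple A training tuple.
#' @param stage `"scaffold"` or `"rgroup"`.
#' @param max_rgroup Padded slot count for the R-group stage.
#' @return List (`context`, `x0_coords`, `x0_feats`) or NULL.
#' @export
fd_stage_example <- function(tuple, stage, max_rgroup = 10L) {
  nf <- fd_n_feature_channels()
  pad_onehot <- function(atoms) {
    oh <- atoms$element_onehot
    fd_type_scale() * cbind(oh, matrix(0, nrow(oh), nf - ncol(oh)))
  }
  if (stage == "scaffold") {
    sc <- tuple$scaffold$atoms
    new_idx <- setdiff(seq_len(fd_n_atoms(sc)), tuple$seed_in_scaffold)
    if (!length(new_idx)) return(NULL)
    ctx <- fd_context("scaffold", tuple$pocket, fragment = tuple$seed)
    x0c <- sc$coords[new_idx, , drop = FALSE]
    x0f <- pad_onehot(fd_atomset_subset(sc, new_idx))
    list(context = ctx, x0_coords = x0c, x0_feats = x0f)
  } else {
    rg <- if (inherits(tuple$rgroup, "fd_fragment")) tuple$rgroup$atoms else
      tuple$rgroup
    n_real <- fd_n_atoms(rg)
    if (n_real > max_rgroup) return(NULL)
    sc_frag <- tuple$scaffold
    attach <- if (inherits(sc_frag, "fd_fragment") &&
                  length(sc_frag$anchors)) sc_frag$anchors[1] else NULL
    sc_atoms <- if (inherits(sc_frag, "fd_fragment")) sc_frag$atoms else
      sc_frag
    ctx <- fd_context("rgroup", tuple$pocket, scaffold = sc_atoms,
                      attach_idx = attach)
    anchor_pos <- if (!is.null(attach)) sc_atoms$coords[attach, ] else
      colMeans(sc_atoms$coords)
    n_pad <- max_rgroup - n_real
    x0c <- rbind(rg$coords,
                 matrix(anchor_pos, n_pad, 3, byrow = TRUE))
    virt <- matrix(0, n_pad, nf)
    if (n_pad > 0) virt[, nf] <- fd_type_scale()
    x0f <- rbind(pad_onehot(rg), virt)
    list(context = ctx, x0_coords = x0c, x0_feats = x0f)
  }
}

# ---- Sampling -------------------------------------------------------------

#' Pre-drawn sampling noise
#'
#' All Gaussian draws a reverse trajectory consumes, as one structure; used
#' both for seeded sampling and for the rigid-motion covariance tests
#' (which must rotate the coordinate noise together with the context).
#'
#' @param n_new Number of generated atoms.
#' @param T_steps Schedule length.
#' @param seed Integer seed.
#' @return List `init_coords`, `init_feats`, `steps` (per-t coordinate and
#'   feature noise).
#' @export
fd_sampling_noise <- function(n_new, T_steps, seed) {
  nf <- fd_n_feature_channels()
  fd_with_seed(seed, {
    list(init_coords = matrix(stats::rnorm(n_new * 3), n_new, 3),
         init_feats = matrix(stats::rnorm(n_new * nf), n_new, nf),
         steps = lapply(seq_len(T_steps), function(t) {
           list(coords = matrix(stats::rnorm(n_new * 3), n_new, 3),
                feats = matrix(stats::rnorm(n_new * nf), n_new, nf))
         }))
  })
}

# Shared reverse-diffusion loop. The state is clamped after every step:
# late polynomial-schedule steps divide by sqrt(1 - beta_t) with beta_t
# near 1, and an imperfect noise prediction there would otherwise send the
# trajectory to infinity. The coordinate clamp is radial (per-atom norm
# around the initialization center), which commutes with rotations and so
# preserves the sampler's rigid-motion covariance.
.fd_reverse_loop <- function(context, model, schedule, n_new, center,
                             noise, coord_extent = 15, feat_extent = 5) {
  nf <- fd_n_feature_channels()
  mu <- fd_context_centroid(context)
  # the coordinate chain lives in the context-centered frame; `center`
  # (anchor centroid / attachment atom) seeds the initialization in it
  clamp_ref <- center - mu
  coords_c <- sweep(noise$init_coords, 2, clamp_ref, `+`)
  feats <- noise$init_feats
  for (t in seq(schedule$T, 1)) {
    eps <- fd_predict_noise(sweep(coords_c, 2, mu, `+`), feats, context,
                            t, model, T_total = schedule$T,
                            training = FALSE, schedule = schedule)
    zc <- if (t > 1) noise$steps[[t]]$coords else NULL
    zf <- if (t > 1) noise$steps[[t]]$feats else NULL
    coords_c <- fd_posterior_step(coords_c, eps$eps_coords, t, schedule, zc)
    feats <- fd_posterior_step(feats, eps$eps_features, t, schedule, zf)
    rel <- sweep(coords_c, 2, clamp_ref)
    rad <- sqrt(rowSums(rel^2))
    shrink <- ifelse(rad > coord_extent, coord_extent / rad, 1)
    coords_c <- sweep(rel * shrink, 2, clamp_ref, `+`)
    feats <- pmin(pmax(feats, -feat_extent), feat_extent)
  }
  list(coords = sweep(coords_c, 2, mu, `+`), feats = feats)
}

#' Generate a scaffold conditioned on (pocket, fragment, anchors)
#'
#' Initializes `n_new` atoms from Gaussian noise centered on the anchors'
#' centroid and runs the full reverse chain with the fragment and pocket
#' frozen. The output contains the untouched fragment atoms followed by the
#' denoised new atoms with arg-max decoded element types.
#'
#' @param context Scaffold-stage [fd_context()].
#' @param model Trained denoiser (scaffold stage).
#' @param schedule An [fd_make_schedule()].
#' @param n_new Number of atoms to generate (0 returns the fragment).
#' @param seed Integer seed (ignored when `noise` is given).
#' @param noise Optional [fd_sampling_noise()] structure.
#' @return List `atoms` (fragment + new, an `fd_atomset`), `new_coords`,
#'   `new_elements`, `fragment_atoms`.
#' @export
fd_generate_scaffold <- function(context, model, schedule, n_new, seed = 1L,
                                 noise = NULL) {
  stopifnot(inherits(context, "fd_context"), context$stage == "scaffold")
  frag <- context$fragment
  if (n_new == 0) {
    return(list(atoms = frag$atoms,
                new_coords = matrix(0, 0, 3), new_elements = character(),
                fragment_atoms = frag$atoms))
  }
  if (is.null(noise)) noise <- fd_sampling_noise(n_new, schedule$T, seed)
  center <- colMeans(frag$atoms$coords[frag$anchors, , drop = FALSE])
  out <- .fd_reverse_loop(context, model, schedule, n_new, center, noise)
  vocab <- fd_element_vocab()
  el <- vocab[apply(out$feats[, seq_along(vocab), drop = FALSE], 1,
                    which.max)]
  new_atoms <- fd_atomset(el, out$coords)
  list(atoms = fd_atomset_bind(frag$atoms, new_atoms),
       new_coords = out$coords, new_elements = el,
       fragment_atoms = frag$atoms)
}

#' Generate an R-group conditioned on (pocket, scaffold)
#'
#' Denoises exactly `max_atoms` padded slots; slots decoding to the virtual
#' category are dropped, so the returned R-group has at most `max_atoms`
#' real atoms (possibly none).
#'
#' @param context R-group-stage [fd_context()].
#' @param model Trained denoiser (R-group stage).
#' @param schedule Typically a polynomial [fd_make_schedule()].
#' @param seed Integer seed (ignored when `noise` is given).
#' @param noise Optional [fd_sampling_noise()] structure (for
#'   `n_new = max_atoms`).
#' @param max_atoms Padded slot count.
#' @return List `atoms` (the real decoded R-group, an `fd_atomset`),
#'   `n_virtual`, `slot_coords`, `slot_elements`.
#' @export
fd_generate_rgroup <- function(context, model, schedule, seed = 1L,
                               noise = NULL, max_atoms = 10L) {
  stopifnot(inherits(context, "fd_context"), context$stage == "rgroup")
  if (is.null(noise)) noise <- fd_sampling_noise(max_atoms, schedule$T, seed)
  center <- if (!is.null(context$attach_idx)) {
    context$scaffold$coords[context$attach_idx, ]
  } else colMeans(context$scaffold$coords)
  out <- .fd_reverse_loop(context, model, schedule, max_atoms, center, noise)
  nf <- fd_n_feature_channels()
  lab <- c(fd_element_vocab(), fd_virtual_label())[apply(out$feats, 1,
                                                         which.max)]
  real <- lab != fd_virtual_label()
  atoms <- fd_atomset(lab[real], out$coords[real, , drop = FALSE])
  list(atoms = atoms, n_virtual = sum(!real),
       slot_coords = out$coords, slot_elements = lab)
}

# ---- Training -------------------------------------------------------------

#' Training configuration for one stage
#'
#' @param stage `"scaffold"` or `"rgroup"`.
#' @param learning_rate Adam step size.
#' @param batch_size Samples per optimizer step.
#' @param iterations Optimizer steps.
#' @param grad_clip_norm Global-norm clipping threshold.
#' @param lr_decay Cosine-decay the learning rate to 1% of its initial
#'   value over the run (standard practice; lets the optimizer settle).
#' @param seed Integer seed (initialization + sampling).
#' @return An object of class `fd_train_config`.
#' @export
fd_train_config <- function(stage = c("scaffold", "rgroup"),
                            learning_rate = 2e-4, batch_size = 32L,
                            iterations = 2000L, grad_clip_norm = 1,
                            lr_decay = TRUE, seed = 1L) {
  stage <- match.arg(stage)
  stopifnot(learning_rate > 0, batch_size >= 1, iterations >= 1,
            grad_clip_norm > 0)
  structure(list(stage = stage, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 grad_clip_norm = grad_clip_norm,
                 lr_decay = isTRUE(lr_decay), seed = as.integer(seed)),
            class = "fd_train_config")
}

#' Train one diffusion stage
#'
#' Per optimizer step: draw `batch_size` (tuple, t) pairs with t uniform on
#' 1..T, noise the stage's target atoms with the closed-form forward
#' marginal, predict the noise, and take one Adam step on the mean squared
#' error with global-norm gradient clipping. The two stages never share
#' parameters; training one stage cannot touch the other's checkpoint.
#'
#' @param tuples List of training tuples (from [fd_build_dataset()]'s
#'   `tuples`, or [fd_toy_tuple()]).
#' @param config An [fd_train_config()].
#' @param schedule An [fd_make_schedule()].
#' @param model Optional warm-start model; defaults to a fresh
#'   [fd_denoiser_init()].
#' @param denoiser_config Used when `model` is NULL.
#' @param verbose Print progress every 200 steps.
#' @return List `model` (with `stage` tag), `losses` (per-step), `grad_norms`
#'   (post-clip global norms).
#' @export
fd_train_stage <- function(tuples, config, schedule,
                           model = NULL,
                           denoiser_config = fd_denoiser_config(),
                           verbose = FALSE) {
  stopifnot(inherits(config, "fd_train_config"))
  examples <- Filter(Negate(is.null),
                     lapply(tuples, fd_stage_example, stage = config$stage))
  if (!length(examples)) stop("no usable tuples for stage ", config$stage)
  if (is.null(model)) {
    model <- fd_denoiser_init(denoiser_config, seed = config$seed)
  }
  model$stage <- config$stage
  opt <- fd_adam_init(model$params)
  ema <- model$params  # exponential moving average of the weights
  ema_decay <- 0.995
  losses <- numeric(config$iterations)
  norms <- numeric(config$iterations)
  fd_with_seed(config$seed + 1L, {
    for (step in seq_len(config$iterations)) {
      acc <- NULL; loss_acc <- 0
      for (b in seq_len(config$batch_size)) {
        ex <- examples[[sample.int(length(examples), 1)]]
        if (config$stage == "rgroup") {
          # padded slots are exchangeable; symmetrize over their order so
          # the model learns the joint (exactly-one-real) structure rather
          # than a privileged slot index
          perm <- sample.int(nrow(ex$x0_coords))
          ex$x0_coords <- ex$x0_coords[perm, , drop = FALSE]
          ex$x0_feats <- ex$x0_feats[perm, , drop = FALSE]
        }
        t <- sample.int(schedule$T, 1)
        n_gen <- nrow(ex$x0_coords)
        nf <- ncol(ex$x0_feats)
        mu <- fd_context_centroid(ex$context)
        eps_c <- matrix(stats::rnorm(n_gen * 3), n_gen, 3)
        eps_f <- matrix(stats::rnorm(n_gen * nf), n_gen, nf)
        # the coordinate chain lives in the context-centered frame
        x0_cent <- sweep(ex$x0_coords, 2, mu)
        xt_cent <- fd_forward_marginal(x0_cent, t, schedule, eps_c)
        xt_orig <- sweep(xt_cent, 2, mu, `+`)
        xt_f <- fd_forward_marginal(ex$x0_feats, t, schedule, eps_f)
        g <- fd_assemble_graph(xt_orig, xt_f, ex$context, t / schedule$T)
        tp <- fd_tape()
        out <- fd_egnn_forward(tp, model, g$h0, g$r0, g$gen_mask,
                               training = TRUE)
        # clean-state parameterization: the network's final (centered)
        # coordinates and the feature head are x0hat; predicted noise
        # follows analytically from the forward marginal
        ab <- schedule$alpha_bar[t]
        x0hat_c <- tp$add(out$eps_coords, tp$leaf(xt_cent))
        x0hat_f <- out$eps_features
        eps_hat_c <- tp$scale(tp$sub(tp$leaf(xt_cent),
                                     tp$scale(x0hat_c, sqrt(ab))),
                              1 / sqrt(1 - ab))
        eps_hat_f <- tp$scale(tp$sub(tp$leaf(xt_f),
                                     tp$scale(x0hat_f, sqrt(ab))),
                              1 / sqrt(1 - ab))
        target <- tp$leaf(cbind(eps_c, eps_f))
        pred <- tp$concat(c(eps_hat_c, eps_hat_f))
        diffn <- tp$sub(pred, target)
        loss_node <- tp$scale(tp$sum_(tp$square(diffn)),
                              1 / (n_gen * (3 + nf)))
        loss <- as.numeric(tp$value(loss_node))
        if (!is.finite(loss)) {
          stop("non-finite loss at training step ", step)
        }
        tp$backward(loss_node)
        gr <- tp$pgrads
        acc <- if (is.null(acc)) gr else
          Map(`+`, acc, gr[names(acc)])
        loss_acc <- loss_acc + loss
      }
      acc <- lapply(acc, function(g) g / config$batch_size)
      cl <- fd_clip_grads(acc, config$grad_clip_norm)
      lr_t <- if (config$lr_decay) {
        frac <- (step - 1) / max(1, config$iterations - 1)
        config$learning_rate * (0.01 + 0.99 * 0.5 *
                                  (1 + cos(pi * frac)))
      } else config$learning_rate
      upd <- fd_adam_step(model$params, cl$grads, opt, lr = lr_t)
      model$params <- upd$params; opt <- upd$opt
      ema <- Map(function(e, p) ema_decay * e + (1 - ema_decay) * p,
                 ema, model$params[names(ema)])
      losses[step] <- loss_acc / config$batch_size
      norms[step] <- min(cl$norm, config$grad_clip_norm)
      if (verbose && step %% 200 == 0) {
        message("step ", step, " loss ",
                format(mean(losses[max(1, step - 99):step]), digits = 4))
      }
    }
  })
  model$params <- ema  # sampling uses the averaged weights
  list(model = model, losses = losses, grad_norms = norms)
}

# ---- Checkpoints ----------------------------------------------------------

#' Save / load a stage checkpoint
#'
#' Versioned container holding the stage tag, parameters, denoiser
#' configuration and batch-norm running statistics.
#'
#' @param model Trained model from [fd_train_stage()].
#' @param path Checkpoint path (RDS container, a runtime artifact).
#' @return Invisibly `path`; the loader returns the model.
#' @export
fd_save_checkpoint <- function(model, path) {
  obj <- list(version = model$version, stage = model$stage,
              config = model$config, params = model$params,
              bn_state = as.list(model$state))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname fd_save_checkpoint
#' @export
fd_load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "fragdiff-denoiser-1")) {
    stop("unrecognized checkpoint version: ", obj$version)
  }
  state <- new.env()
  for (nm in names(obj$bn_state)) state[[nm]] <- obj$bn_state[[nm]]
  list(params = obj$params, config = obj$config, state = state,
       version = obj$version, stage = obj$stage)
}
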