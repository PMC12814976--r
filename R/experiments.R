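# Bundled desk-scale experiments: the single-complex overfit-recovery
# studies for both diffusion stages and the bond-refiner accuracy study.
# These back both the test suite and scripts/acceptance.R.

#' Monte-Carlo estimate of a trained stage's diffusion loss
#'
#' Uniform t, fresh forward-marginal noise, mean squared error between the
#' injected and the predicted noise over coordinate and type channels.
#'
#' @param model Trained denoiser.
#' @param tuples Training tuples.
#' @param stage `"scaffold"` or `"rgroup"`.
#' @param schedule An [fd_make_schedule()].
#' @param n_draw Monte-Carlo draws.
#' @param seed Evaluation seed.
#' @return Mean loss.
#' @export
fd_mc_stage_loss <- function(model, tuples, stage, schedule,
                             n_draw = 300, seed = 12345) {
  exs <- Filter(Negate(is.null),
                lapply(tuples, fd_stage_example, stage = stage))
  fd_with_seed(seed, {
    vals <- vapply(seq_len(n_draw), function(i) {
      ex <- exs[[sample.int(length(exs), 1)]]
      t <- sample.int(schedule$T, 1)
      n <- nrow(ex$x0_coords); nf <- ncol(ex$x0_feats)
      mu <- fd_context_centroid(ex$context)
      ec <- matrix(stats::rnorm(n * 3), n)
      ef <- matrix(stats::rnorm(n * nf), n)
      # the coordinate chain is defined in the context-centered frame
      xc <- sweep(fd_forward_marginal(sweep(ex$x0_coords, 2, mu), t,
                                      schedule, ec), 2, mu, `+`)
      xf <- fd_forward_marginal(ex$x0_feats, t, schedule, ef)
      p <- fd_predict_noise(xc, xf, ex$context, t, model, schedule$T,
                            training = FALSE, schedule = schedule)
      fd_diffusion_loss(cbind(ec, ef),
                        cbind(p$eps_coords, p$eps_features))
    }, numeric(1))
    mean(vals)
  })
}

#' Single-complex overfit-recovery experiment
#'
#' Trains one stage on one toy complex and measures (a) the Monte-Carlo
#' diffusion loss of the trained model and (b) how often seeded samples
#' regenerate the held-out target (scaffold stage: aligned heavy-atom RMSD
#' of the new atoms; R-group stage: atom count and element multiset).
#'
#' @param stage `"scaffold"` or `"rgroup"`.
#' @param template Catalog ligand for the toy complex.
#' @param iterations Optimizer steps.
#' @param T_steps Schedule length.
#' @param seed Training seed.
#' @param n_samples Seeded samples drawn for the recovery rate.
#' @return List with `model`, `schedule`, `loss` and per-seed outcomes.
#' @export
fd_overfit_experiment <- function(stage, template = "methyl-phenyl-ether",
                                  iterations = 3000L, T_steps = 100L,
                                  seed = 7L, n_samples = 10L) {
  cx <- fd_make_toy_complex(fd_toy_spec(template, 8, 11))
  tup <- fd_toy_tuple(cx)
  cfg <- fd_denoiser_config(n_layers = 3, hidden_dim = 40, K = 12,
                            d_max = 10)
  sch <- if (stage == "scaffold") {
    fd_make_schedule("linear", T_steps)
  } else fd_make_schedule("polynomial", T_steps)
  tr <- fd_train_stage(list(tup),
                       fd_train_config(stage, learning_rate = 1e-3,
                                       batch_size = 1,
                                       iterations = iterations,
                                       seed = seed),
                       sch, denoiser_config = cfg)
  loss <- fd_mc_stage_loss(tr$model, list(tup), stage, sch)
  ex <- fd_stage_example(tup, stage)
  if (stage == "scaffold") {
    rmsd <- vapply(seq_len(n_samples), function(s) {
      out <- fd_generate_scaffold(ex$context, tr$model, sch,
                                  n_new = nrow(ex$x0_coords),
                                  seed = 100 + s)
      sqrt(mean(rowSums((out$new_coords - ex$x0_coords)^2)))
    }, numeric(1))
    list(model = tr$model, schedule = sch, loss = loss, rmsd = rmsd,
         complex = cx, tuple = tup)
  } else {
    want_n <- fd_n_atoms(cx$rgroup)
    want_el <- sort(fd_elements(cx$rgroup))
    res <- lapply(seq_len(n_samples), function(s) {
      rg <- fd_generate_rgroup(ex$context, tr$model, sch, seed = 200 + s)
      list(n = fd_n_atoms(rg$atoms),
           hit = fd_n_atoms(rg$atoms) == want_n &&
             identical(sort(fd_elements(rg$atoms)), want_el))
    })
    list(model = tr$model, schedule = sch, loss = loss,
         n_atoms = vapply(res, `[[`, numeric(1), "n"),
         hits = vapply(res, `[[`, logical(1), "hit"),
         complex = cx, tuple = tup)
  }
}

#' Bond-refiner accuracy experiment
#'
#' Trains the edge refiner on the fixture catalog with jitter augmentation
#' and evaluates edge-classification accuracy on held-out jittered copies
#' (fresh draws) and on clean geometries.
#'
#' @param epochs Training epochs over the catalog.
#' @param hidden Hidden width.
#' @param jitter_sd Jitter (Angstrom).
#' @param seed Training seed.
#' @param eval_reps Held-out evaluation repetitions.
#' @return List `model`, `jittered`, `clean` (accuracy, edge counts).
#' @export
fd_bond_accuracy_experiment <- function(epochs = 150L, hidden = 48L,
                                        jitter_sd = 0.1, seed = 3L,
                                        eval_reps = 4L) {
  mols <- lapply(fd_catalog_names(), fd_catalog_molecule)
  tr <- fd_train_bond_model(mols, fd_bondnet_init(hidden_dim = hidden,
                                                  seed = 2),
                            epochs = epochs, lr = 2e-3,
                            jitter_sd = jitter_sd, seed = seed)
  acc_at <- function(sd) {
    labs <- character(); preds <- character()
    probs_ok <- TRUE
    for (rep in seq_len(eval_reps)) {
      for (m in mols) {
        if (fd_n_atoms(m$atoms) < 2) next
        a <- m$atoms
        if (sd > 0) {
          a$coords <- a$coords +
            matrix(stats::rnorm(length(a$coords), sd = sd),
                   nrow(a$coords))
        }
        g <- fd_refine_bonds(fd_build_candidate_graph(a), tr$model)
        if (nrow(g$edges)) {
          probs_ok <- probs_ok &&
            all(abs(rowSums(g$class_probs) - 1) < 1e-6)
        }
        labs <- c(labs, fd_bond_labels(g, m$bonds))
        preds <- c(preds, g$classes)
      }
    }
    list(acc = mean(labs == preds), probs_ok = probs_ok,
         n_edges = length(labs))
  }
  jit <- fd_with_seed(99, acc_at(jitter_sd))
  clean <- acc_at(0)
  list(model = tr$model, jittered = jit, clean = clean)
}
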