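# Radial-basis expansion, EGCL behavior and the symmetry properties of the
# noise predictor.

test_that("RBF expansion evaluates the Gaussian kernels exactly", {
  cfg <- fd_denoiser_config(K = 4L, d_max = 3, sigma = 1,
                            centers = c(0, 1, 2, 3))
  out <- fd_rbf_expand(1, cfg)
  expect_equal(as.numeric(out),
               c(exp(-1 / 2), 1, exp(-1 / 2), exp(-2)))
  # d equal to a center gives a unit response there
  expect_equal(fd_rbf_expand(2, cfg)[3], 1)
  expect_true(all(fd_rbf_expand(c(0, 0.5, 2.7), cfg) > 0))
  expect_true(all(fd_rbf_expand(c(0, 0.5, 2.7), cfg) <= 1))
  expect_error(fd_rbf_expand(-0.1, cfg), "nonnegative")
})

test_that("context atoms never move through stacked layers", {
  cx <- tiny_complex()
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "scaffold")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 4, hidden_dim = 16,
                                               K = 6), seed = 1)
  g <- fd_assemble_graph(ex$x0_coords, ex$x0_feats, ex$context, 0.3)
  tp <- fd_tape()
  fd_egnn_forward(tp, model, g$h0, g$r0, g$gen_mask)
  # recompute: run and inspect that only generated rows of r changed
  tp2 <- fd_tape()
  out <- fd_egnn_forward(tp2, model, g$h0, g$r0, g$gen_mask)
  # eps_coords rows equal in count to generated atoms, independent of
  # context size
  expect_equal(nrow(tp2$value(out$eps_coords)), sum(g$gen_mask))
  # with an all-context mask there is nothing to denoise upstream; the
  # coordinate trajectory of context atoms is pinned to zero displacement
  # by construction: verify via a forward pass on a graph where the
  # displacement of context rows must be exactly zero
  tp3 <- fd_tape()
  out3 <- fd_egnn_forward(tp3, model, g$h0, g$r0,
                          rep(FALSE, nrow(g$r0)))
  expect_equal(tp3$value(out3$eps_coords),
               matrix(0, 0, 3), ignore_attr = TRUE)
})

test_that("a lone node gets a feature update from the empty message sum", {
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 1,
                                               hidden_dim = 8, K = 4),
                            seed = 2)
  h0 <- matrix(rnorm(fd_node_input_dim()), 1)
  r0 <- matrix(c(1, 2, 3), 1)
  tp <- fd_tape()
  out <- fd_egnn_forward(tp, model, h0, r0, gen_mask = TRUE)
  expect_equal(tp$value(out$eps_coords), matrix(0, 1, 3),
               ignore_attr = TRUE)          # no neighbors, no displacement
  expect_true(all(is.finite(tp$value(out$eps_features))))
})

test_that("a two-node layer reproduces a manual evaluation", {
  # one EGCL, hidden width 1, all dense weights = 1, biases = 0, batch
  # normalization neutralized by feeding identical rows is not possible
  # with n = 2, so the manual computation replays the exact same algebra
  # with plain arithmetic, including batch statistics
  cfg <- fd_denoiser_config(n_layers = 1, hidden_dim = 1, K = 1, d_max = 2,
                            sigma = 1, centers = 1)
  model <- fd_denoiser_init(cfg, seed = 1)
  model$params <- lapply(model$params, function(p) {
    p[] <- 1; p
  })
  for (nm in grep("\\.b$|\\.beta$", names(model$params), value = TRUE)) {
    model$params[[nm]][] <- 0
  }
  h0 <- matrix(rnorm(2 * fd_node_input_dim()), 2)
  r0 <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  tp <- fd_tape()
  out <- fd_egnn_forward(tp, model, h0, r0, gen_mask = c(TRUE, TRUE),
                         training = TRUE)
  got_r <- tp$value(out$eps_coords)

  silu <- function(x) x / (1 + exp(-x))
  bn <- function(v) (v - mean(v)) / sqrt(mean(v^2) - mean(v)^2 + 1e-5)
  emb <- rowSums(h0)                     # embedding dense: all-ones, b = 0
  d <- 1.2; d2 <- d^2; rbf <- exp(-(d - 1)^2 / 2)
  # message (symmetric in the endpoints): two dense + SiLU stages
  m <- silu(silu(emb[1] + emb[2] + d2 + rbf))
  # feature update: dense -> BN(batch stats) -> SiLU -> dense -> BN -> add
  u <- emb + m
  u <- bn(u); u <- silu(u); u <- bn(u)
  h1 <- emb + u
  # coordinate head: three dense layers, SiLU after the first two
  s <- silu(silu(emb[1] + emb[2] + d2 + rbf))
  disp1 <- (r0[1, ] - r0[2, ]) / (d + 1) * s
  disp2 <- (r0[2, ] - r0[1, ]) / (d + 1) * s
  expect_equal(got_r[1, ], disp1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(got_r[2, ], disp2, tolerance = 1e-10, ignore_attr = TRUE)
  # output feature head (all-ones): each row is h1_i across channels
  got_h <- tp$value(out$eps_features)
  expect_equal(got_h,
               matrix(h1, 2, fd_n_feature_channels()),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the noise predictor is translation invariant and rotation equivariant", {
  set.seed(11)
  cx <- tiny_complex("ethanol", seed = 5)
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "scaffold")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 2,
                                               hidden_dim = 16, K = 8),
                            seed = 4)
  n_gen <- nrow(ex$x0_coords)
  xc <- ex$x0_coords + 0.3 * matrix(rnorm(n_gen * 3), n_gen)
  xf <- ex$x0_feats + 0.3 * matrix(rnorm(length(ex$x0_feats)),
                                   nrow(ex$x0_feats))
  base <- fd_predict_noise(xc, xf, ex$context, 5, model, 10)
  for (i in seq_len(20)) {
    R <- rand_rotation(); tvec <- rnorm(3, sd = 5)
    pk <- ex$context$pocket; pk$atoms <- rotate_atomset(pk$atoms, R, tvec)
    fr <- ex$context$fragment
    fr$atoms <- rotate_atomset(fr$atoms, R, tvec)
    ctx2 <- fd_context("scaffold", pk, fragment = fr)
    out2 <- fd_predict_noise(sweep(xc %*% t(R), 2, tvec, `+`), xf, ctx2,
                             5, model, 10)
    expect_lt(max(abs(out2$eps_coords - base$eps_coords %*% t(R))) /
                max(abs(base$eps_coords)), 1e-8)
    expect_lt(max(abs(out2$eps_features - base$eps_features)) /
                max(abs(base$eps_features)), 1e-8)
  }
  # pure translation: outputs unchanged entirely
  tvec <- c(3, -7, 2)
  pk <- ex$context$pocket
  pk$atoms$coords <- sweep(pk$atoms$coords, 2, tvec, `+`)
  fr <- ex$context$fragment
  fr$atoms$coords <- sweep(fr$atoms$coords, 2, tvec, `+`)
  ctx3 <- fd_context("scaffold", pk, fragment = fr)
  out3 <- fd_predict_noise(sweep(xc, 2, tvec, `+`), xf, ctx3, 5, model, 10)
  expect_equal(out3$eps_coords, base$eps_coords, tolerance = 1e-9)
  expect_equal(out3$eps_features, base$eps_features, tolerance = 1e-9)
})

test_that("permuting generated atoms permutes the prediction identically", {
  set.seed(12)
  cx <- tiny_complex("methyl-phenyl-ether", seed = 6)
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "rgroup")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 2,
                                               hidden_dim = 16, K = 8),
                            seed = 4)
  n <- nrow(ex$x0_coords)
  xc <- ex$x0_coords + 0.2 * matrix(rnorm(n * 3), n)
  xf <- ex$x0_feats + 0.2 * matrix(rnorm(length(ex$x0_feats)), n)
  base <- fd_predict_noise(xc, xf, ex$context, 3, model, 10)
  perm <- sample(n)
  out <- fd_predict_noise(xc[perm, ], xf[perm, ], ex$context, 3, model, 10)
  expect_equal(out$eps_coords, base$eps_coords[perm, ], tolerance = 1e-9)
  expect_equal(out$eps_features, base$eps_features[perm, ],
               tolerance = 1e-9)
})

test_that("empty pocket or empty noisy set are refused", {
  cx <- tiny_complex()
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "scaffold")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 1,
                                               hidden_dim = 8, K = 4))
  expect_error(fd_predict_noise(matrix(0, 0, 3),
                                matrix(0, 0, fd_n_feature_channels()),
                                ex$context, 1, model, 10),
               "no noisy atoms")
})
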