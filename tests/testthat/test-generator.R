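# Conditioning contexts, size model, sampling contracts and decoupled
# training.

test_that("contexts validate their stage-appropriate fields", {
  cx <- tiny_complex()
  expect_error(fd_context("scaffold", cx$pocket), "seed fragment")
  nofrag <- fd_fragment(cx$fragment$atoms, anchors = integer())
  expect_error(fd_context("scaffold", cx$pocket, fragment = nofrag),
               "no anchors")
  expect_error(fd_context("rgroup", cx$pocket), "nonempty scaffold")
  ok <- fd_context("rgroup", cx$pocket, scaffold = cx$scaffold)
  expect_s3_class(ok, "fd_context")
})

test_that("the size model draws from its histogram", {
  m1 <- fd_size_model(probs = c(`5` = 1))
  expect_equal(fd_sample_size(m1, 1), 5)
  expect_equal(fd_sample_size(m1, 99), 5)
  m <- fd_size_model(counts = c(1, 1, 2, 2, 2, 3))
  expect_equal(fd_sample_size(m, 4), fd_sample_size(m, 4))
  draws <- vapply(1:10000, function(s) fd_sample_size(m, s), numeric(1))
  freq <- table(draws) / length(draws)
  expect_equal(as.numeric(freq), c(2, 3, 1) / 6,
               tolerance = 3 * sqrt(0.25 / 10000) / min(c(2, 3, 1) / 6))
  expect_error(fd_size_model(counts = integer()), "empty")
})

test_that("sampling freezes the context and honors n_new = 0", {
  cx <- tiny_complex("ethanol", seed = 3)
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "scaffold")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 2,
                                               hidden_dim = 12, K = 6),
                            seed = 2)
  sch <- fd_make_schedule("linear", 8)
  none <- fd_generate_scaffold(ex$context, model, sch, n_new = 0)
  expect_identical(none$atoms, ex$context$fragment$atoms)
  out <- fd_generate_scaffold(ex$context, model, sch, n_new = 2, seed = 5)
  nf <- fd_n_atoms(ex$context$fragment$atoms)
  expect_identical(out$atoms$coords[seq_len(nf), , drop = FALSE],
                   ex$context$fragment$atoms$coords)   # bit-identical
  expect_equal(fd_n_atoms(out$atoms), nf + 2)
  # determinism
  out2 <- fd_generate_scaffold(ex$context, model, sch, n_new = 2, seed = 5)
  expect_identical(out$atoms, out2$atoms)
})

test_that("R-group sampling pads to 10 slots and drops virtual decodes", {
  cx <- tiny_complex("methyl-phenyl-ether", seed = 4)
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "rgroup")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 2,
                                               hidden_dim = 12, K = 6),
                            seed = 2)
  sch <- fd_make_schedule("polynomial", 8)
  for (s in 1:6) {
    rg <- fd_generate_rgroup(ex$context, model, sch, seed = s)
    expect_equal(nrow(rg$slot_coords), 10)
    expect_lte(fd_n_atoms(rg$atoms), 10)
    expect_equal(fd_n_atoms(rg$atoms) + rg$n_virtual, 10)
    expect_false(fd_virtual_label() %in% fd_elements(rg$atoms))
  }
})

test_that("rotating the whole context rotates sampled coordinates", {
  cx <- tiny_complex("ethanol", seed = 6)
  tup <- fd_toy_tuple(cx)
  ex <- fd_stage_example(tup, "scaffold")
  model <- fd_denoiser_init(fd_denoiser_config(n_layers = 2,
                                               hidden_dim = 12, K = 6),
                            seed = 3)
  sch <- fd_make_schedule("linear", 6)
  noise <- fd_sampling_noise(2, sch$T, seed = 11)
  base <- fd_generate_scaffold(ex$context, model, sch, n_new = 2,
                               noise = noise)
  set.seed(21)
  R <- rand_rotation(); tvec <- rnorm(3, sd = 4)
  rot_noise <- noise
  rot_noise$init_coords <- noise$init_coords %*% t(R)
  rot_noise$steps <- lapply(noise$steps, function(s) {
    list(coords = s$coords %*% t(R), feats = s$feats)
  })
  pk <- ex$context$pocket; pk$atoms <- rotate_atomset(pk$atoms, R, tvec)
  fr <- ex$context$fragment; fr$atoms <- rotate_atomset(fr$atoms, R, tvec)
  ctx2 <- fd_context("scaffold", pk, fragment = fr)
  out2 <- fd_generate_scaffold(ctx2, model, sch, n_new = 2,
                               noise = rot_noise)
  expect_lt(max(abs(out2$new_coords -
                      sweep(base$new_coords %*% t(R), 2, tvec, `+`))),
            1e-4)
  expect_identical(out2$new_elements, base$new_elements)
})

test_that("training clips gradients and keeps the stages decoupled", {
  cx <- tiny_complex("ethanol", seed = 8)
  tup <- fd_toy_tuple(cx)
  dcfg <- fd_denoiser_config(n_layers = 1, hidden_dim = 8, K = 4)
  sch <- fd_make_schedule("linear", 10)
  tr1 <- fd_train_stage(list(tup),
                        fd_train_config("scaffold", learning_rate = 1e-3,
                                        batch_size = 1, iterations = 15,
                                        grad_clip_norm = 0.5, seed = 2),
                        sch, denoiser_config = dcfg)
  expect_true(all(tr1$grad_norms <= 0.5 + 1e-9))
  expect_true(all(is.finite(tr1$losses)))
  expect_equal(tr1$model$stage, "scaffold")
  ck1 <- tempfile(fileext = ".rds")
  fd_save_checkpoint(tr1$model, ck1)
  hash_before <- tools::md5sum(ck1)
  # an R-group run builds its own parameters and cannot touch stage 1
  tr2 <- fd_train_stage(list(tup),
                        fd_train_config("rgroup", learning_rate = 1e-3,
                                        batch_size = 1, iterations = 5,
                                        seed = 3),
                        fd_make_schedule("polynomial", 10),
                        denoiser_config = dcfg)
  expect_equal(tr2$model$stage, "rgroup")
  expect_identical(tools::md5sum(ck1), hash_before)
  expect_false(identical(tr1$model$params, tr2$model$params))
  # checkpoints round trip
  back <- fd_load_checkpoint(ck1)
  expect_identical(back$params, tr1$model$params)
  expect_equal(back$stage, "scaffold")
})
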