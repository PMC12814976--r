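# Candidate graph, deterministic bond perception, and molecule assembly.
# (The trained refiner's accuracy target lives in the acceptance suite.)

test_that("the candidate graph contains exactly the pairs within 3 A", {
  two_far <- fd_atomset(c("C", "C"), rbind(c(0, 0, 0), c(3.5, 0, 0)))
  expect_equal(nrow(fd_build_candidate_graph(two_far)$edges), 0)
  two_near <- fd_atomset(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(nrow(fd_build_candidate_graph(two_near)$edges), 1)
  tri <- fd_atomset(rep("C", 3),
                    1.5 * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  g <- fd_build_candidate_graph(tri)
  expect_equal(nrow(g$edges), 3)
  expect_error(fd_build_candidate_graph(fd_atomset("C", matrix(0, 1, 3))),
               "at least 2")
  # exhaustive agreement with brute force on spread-out clouds
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    a <- fd_atomset(sample(c("C", "N", "O"), n, replace = TRUE),
                    matrix(runif(n * 3, 0, 6), n))
    g <- fd_build_candidate_graph(a)
    D <- as.matrix(dist(a$coords))
    brute <- which(upper.tri(D) & D <= 3, arr.ind = TRUE)
    expect_equal(nrow(g$edges), nrow(brute))
    if (nrow(g$edges)) expect_lte(max(g$edges$dist), 3)
  }
})

test_that("deterministic perception reproduces every fixture bond list", {
  for (m in fixture_panel()) {
    got <- fd_perceive_bonds_reference(m$atoms)
    expect_equal(sort_bonds(got), sort_bonds(m$bonds), info = m$name)
  }
  # far atoms bond to nothing
  far <- fd_atomset(c("C", "O"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(fd_perceive_bonds_reference(far)), 0)
  expect_error(fd_perceive_bonds_reference(
    fd_atomset(character(), matrix(0, 0, 3))), "no atoms")
})

test_that("perceived bonds never exceed valence caps", {
  set.seed(6)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    a <- fd_atomset(sample(c("C", "N", "O", "F"), n, replace = TRUE),
                    matrix(runif(n * 3, 0, 4), n))
    b <- fd_perceive_bonds_reference(a)
    mol <- fd_molecule(a, b)
    el <- fd_elements(a)
    used <- rep(0, n)
    if (nrow(b)) {
      ord <- c(single = 1, double = 2, aromatic = 1.5, triple = 3)[b$class]
      for (k in seq_len(nrow(b))) {
        used[b$i[k]] <- used[b$i[k]] + ord[k]
        used[b$j[k]] <- used[b$j[k]] + ord[k]
      }
    }
    expect_true(all(used <= fd_max_valence(el) + 1e-9))
  }
})

test_that("an untrained refiner is refused and assembly flags failures", {
  g <- fd_build_candidate_graph(fd_catalog_molecule("ethanol")$atoms)
  expect_error(fd_refine_bonds(g, fd_bondnet_init(hidden_dim = 8)),
               "not been trained")
  # fixture atoms + fixture bonds assemble valid and round-trip
  m <- fd_catalog_molecule("methyl-phenyl-ether")
  asm <- fd_assemble_molecule(m$atoms, m$bonds, name = "anisole")
  expect_true(asm$valid)
  tf <- tempfile(fileext = ".sdf")
  fd_write_molecules(list(asm), tf)
  back <- fd_read_ligands(tf)[[1]]
  expect_equal(sort_bonds(back$bonds), sort_bonds(m$bonds))
  # a carbon with five single bonds fails sanitization with a reason
  a <- fd_atomset(rep("C", 6), cbind(c(0, 1.5, -1.5, 0, 0, 0),
                                     c(0, 0, 0, 1.5, -1.5, 0),
                                     c(0, 0, 0, 0, 0, 1.5)))
  bad <- fd_assemble_molecule(a, fd_bonds(rep(1, 5), 2:6,
                                          rep("single", 5)))
  expect_false(bad$valid)
  expect_match(bad$properties$invalid_reason, "valence")
  # empty bond list on 2 atoms: largest component, flagged disconnected
  two <- fd_atomset(c("C", "C"), rbind(c(0, 0, 0), c(4, 0, 0)))
  lone <- fd_assemble_molecule(two, fd_empty_bonds())
  expect_equal(fd_n_atoms(lone$atoms), 1)
  expect_true(isTRUE(lone$properties$disconnected))
})

test_that("a briefly trained refiner is normalized and symmetric", {
  mols <- lapply(c("ethane", "ethanol", "benzene", "acetone"),
                 fd_catalog_molecule)
  tr <- fd_train_bond_model(mols, fd_bondnet_init(hidden_dim = 16,
                                                  seed = 3),
                            epochs = 3, lr = 2e-3, seed = 4)
  g <- fd_refine_bonds(fd_build_candidate_graph(
    fd_catalog_molecule("phenol")$atoms), tr$model)
  expect_equal(rowSums(g$class_probs), rep(1, nrow(g$edges)),
               tolerance = 1e-6)
  # permuting atom indices permutes the per-edge predictions consistently
  m <- fd_catalog_molecule("ethanol")
  set.seed(9)
  perm <- sample(fd_n_atoms(m$atoms))
  pm <- fd_atomset_subset(m$atoms, perm)
  g1 <- fd_refine_bonds(fd_build_candidate_graph(m$atoms), tr$model)
  g2 <- fd_refine_bonds(fd_build_candidate_graph(pm), tr$model)
  key1 <- apply(cbind(g1$edges$i, g1$edges$j), 1, function(ij) {
    paste(sort(match(ij, perm)), collapse = "-")
  })
  key2 <- paste(pmin(g2$edges$i, g2$edges$j),
                pmax(g2$edges$i, g2$edges$j), sep = "-")
  expect_setequal(key1, key2)
  expect_equal(g1$class_probs[order(key1), , drop = FALSE],
               g2$class_probs[order(key2), , drop = FALSE],
               tolerance = 1e-9)
})
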