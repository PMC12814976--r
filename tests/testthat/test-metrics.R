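# Evaluation battery: panels, heteroatom ratio, similarity, geometric
# distributions and threshold counting.

test_that("panels stay inside their documented ranges on the fixtures", {
  panel <- fixture_panel()
  pans <- fd_property_panels(panel)
  expect_true(all(pans$qed > 0 & pans$qed < 1))
  expect_true(all(pans$sa_norm >= 0 & pans$sa_norm <= 1))
  expect_true(all(pans$lipinski %in% 0:5))
  expect_true(all(pans$r_value >= 0 & pans$r_value <= 1))
  expect_true(all(pans$tpsa >= 0))
  expect_true(all(pans$mw > 0))
  # ring counts agree with a minimum-cycle enumeration on the fixtures
  expect_equal(pans$n_rings,
               vapply(panel, fd_n_rings, integer(1)))
})

test_that("the heteroatom ratio counts non-carbon heavy atoms", {
  expect_equal(fd_r_value(fd_catalog_molecule("methane")), 0)
  expect_equal(fd_r_value(fd_catalog_molecule("ethanol")), 1 / 3)
  expect_equal(fd_r_value(fd_catalog_molecule("pyridine")), 1 / 6)
  # explicit hydrogens never enter the ratio
  expect_equal(fd_r_value(fd_catalog_molecule("methane",
                                              explicit_h = TRUE)), 0)
  for (m in fixture_panel()) {
    r <- fd_r_value(m)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("diversity and reference similarity behave as set metrics", {
  b <- fd_catalog_molecule("benzene")
  expect_warning(d0 <- fd_diversity(list(b)), "fewer than 2")
  expect_equal(d0, 0)
  expect_equal(fd_diversity(list(b, b, b)), 0)
  mixed <- lapply(c("benzene", "ethanol", "acetone"), fd_catalog_molecule)
  dv <- fd_diversity(mixed)
  expect_gt(dv, 0); expect_lte(dv, 1)
  # generated set contained in the reference: similarity 1
  expect_equal(fd_similarity_to_ref(mixed, mixed), 1)
  expect_error(fd_similarity_to_ref(mixed, list()), "empty reference")
  # hand-built three-fingerprint Tanimoto arithmetic
  fp1 <- c(TRUE, TRUE, FALSE, FALSE)
  fp2 <- c(TRUE, FALSE, TRUE, FALSE)
  fp3 <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(fd_tanimoto(fp1, fp2), 1 / 3)
  expect_equal(fd_tanimoto(fp1, fp3), 2 / 3)
  expect_equal(fd_tanimoto(fp2, fp3), 2 / 3)
  expect_equal(fd_tanimoto(fp1, fp1), 1)
})

test_that("geometry histograms are normalized and deduplicated", {
  panel <- fixture_panel()
  hists <- fd_geometry_distributions(panel, c("C-O", "C-O-C", "C-C-C-C"))
  for (h in hists) {
    expect_equal(sum(h$density), 1)
    expect_gt(h$n_obs, 0)
  }
  # one ethanol C-O bond: a path and its reversal count once
  h <- fd_geometry_distributions(list(fd_catalog_molecule("ethanol")),
                                 "C-O")[[1]]
  expect_equal(h$n_obs, 1)
  # ideal methane H-C-H angles all fall in the tetrahedral bin
  mh <- fd_catalog_molecule("methane", explicit_h = TRUE)
  gh <- fd_geometry_distributions(list(mh), "H-C-H")[[1]]
  bin <- findInterval(acos(-1 / 3), gh$breaks)
  expect_equal(gh$density[bin], 1)
  expect_equal(gh$n_obs, 6)
  expect_warning(fd_geometry_distributions(panel, "Br-Br"), "matched no")
  expect_error(fd_geometry_distributions(panel, "C"), "must have")
})

test_that("KL divergence has its defining properties", {
  mk <- function(dens) {
    structure(list(key = "x", kind = "bond",
                   breaks = seq(0, 1, length.out = length(dens) + 1),
                   density = dens, n_obs = 10),
              class = "fd_geom_hist")
  }
  p <- mk(c(0.5, 0.5)); q <- mk(c(0.25, 0.75))
  expect_equal(fd_kl_divergence(p, p), 0)
  expect_equal(fd_kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_gte(fd_kl_divergence(q, p), 0)
  # asymmetry
  expect_false(isTRUE(all.equal(fd_kl_divergence(p, q),
                                fd_kl_divergence(q, p))))
  # p mass where q has none stays finite through the floor
  expect_true(is.finite(fd_kl_divergence(mk(c(1, 0)), mk(c(0, 1)))))
  expect_error(fd_kl_divergence(p, mk(c(0.2, 0.3, 0.5))), "bin edges")
  # nonnegative over random floored histogram pairs
  set.seed(8)
  for (i in 1:20) {
    a <- runif(16); a <- a / sum(a)
    b <- runif(16); b <- b / sum(b)
    expect_gte(fd_kl_divergence(mk(a), mk(b)), 0)
  }
})

test_that("joint threshold counting is exact and monotone", {
  panels <- data.frame(sa_norm = c(0.9, 0.6, 0.3, 0.8),
                       qed = c(0.7, 0.8, 0.9, 0.2))
  expect_equal(fd_threshold_joint_count(panels, 0, 0), 4)
  expect_equal(fd_threshold_joint_count(panels, 0.5, 0.5), 2)
  expect_equal(fd_threshold_joint_count(panels, 0.85, 0.5), 1)
  grid <- seq(0, 1, by = 0.25)
  for (qm in grid) {
    counts <- vapply(grid, function(sm) {
      fd_threshold_joint_count(panels, sm, qm)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  expect_error(fd_threshold_joint_count(panels[0, ], 0, 0), "empty")
})
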