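# Domain types, fixture catalog and standard-format I/O.

test_that("atom sets enforce their invariants", {
  a <- fd_atomset(c("C", "O"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_equal(fd_n_atoms(a), 2)
  expect_equal(fd_elements(a), c("C", "O"))
  expect_true(all(rowSums(a$element_onehot) == 1))
  expect_error(fd_atomset("C", matrix(c(1, NA, 0), 1)), "finite")
  expect_error(fd_atomset("Xx", matrix(0, 1, 3)), "vocabulary")
  expect_error(fd_bonds(1, 1, "single"), "self-bonds")
  expect_error(fd_bonds(c(1, 2), c(2, 1), c("single", "single")),
               "duplicate")
  expect_error(fd_bonds(1, 2, "quadruple"), "unknown bond class")
})

test_that("catalog geometries match their reference bond lists", {
  for (m in fixture_panel()) {
    n <- fd_n_atoms(m$atoms)
    if (n < 2) next
    D <- as.matrix(dist(m$atoms$coords))
    bonded <- matrix(FALSE, n, n)
    bonded[cbind(m$bonds$i, m$bonds$j)] <- TRUE
    bonded[cbind(m$bonds$j, m$bonds$i)] <- TRUE
    bd <- D[upper.tri(D)][bonded[upper.tri(bonded)]]
    nbd <- D[upper.tri(D)][!bonded[upper.tri(bonded)]]
    expect_lt(max(bd), 1.9)
    if (length(nbd)) expect_gt(min(nbd), 2.2)
  }
})

test_that("tabulated ideal geometry reproduces standard covalent values", {
  eth <- fd_catalog_molecule("ethane")
  expect_equal(sqrt(sum((eth$atoms$coords[1, ] - eth$atoms$coords[2, ])^2)),
               1.54, tolerance = 1e-12)
  mh <- fd_catalog_molecule("methane", explicit_h = TRUE)
  ang <- fd_angle(mh$atoms$coords[2, ], mh$atoms$coords[1, ],
                  mh$atoms$coords[3, ])
  expect_equal(ang, acos(-1 / 3), tolerance = 1e-10)
  benz <- fd_catalog_molecule("benzene")
  ring_d <- sqrt(sum((benz$atoms$coords[1, ] - benz$atoms$coords[2, ])^2))
  expect_equal(ring_d, 1.39, tolerance = 1e-12)
})

test_that("toy complexes are pure functions of their spec", {
  s <- fd_toy_spec("methyl-phenyl-ether", 8, seed = 7)
  a <- fd_make_toy_complex(s)
  b <- fd_make_toy_complex(s)
  expect_identical(a, b)
  # partition consistency
  expect_setequal(c(a$scaffold_idx, a$rgroup_idx),
                  seq_len(fd_n_atoms(a$ligand$atoms)))
  expect_true(all(a$fragment_idx %in% a$scaffold_idx))
  expect_equal(fd_n_atoms(a$scaffold) + fd_n_atoms(a$rgroup),
               fd_n_atoms(a$ligand$atoms))
  # pocket shell sits at the requested radius
  cen <- colMeans(a$ligand$atoms$coords)
  rad <- sqrt(rowSums(sweep(a$pocket$atoms$coords, 2, cen)^2))
  expect_equal(rad, rep(8, length(rad)), tolerance = 1e-9)
  expect_error(fd_toy_spec("nonexistent"), "unknown template")
  expect_error(fd_toy_spec("benzene", pocket_shell_radius = 0.5),
               "exceed")
})

test_that("SDF round trip preserves atoms, bonds and properties", {
  mols <- list(fd_catalog_molecule("ethanol"),
               fd_catalog_molecule("methyl-phenyl-ether"))
  mols[[1]]$properties <- list(QED = 0.5)
  tf <- tempfile(fileext = ".sdf")
  fd_write_molecules(mols, tf)
  back <- fd_read_ligands(tf)
  expect_length(back, 2)
  expect_equal(fd_n_atoms(back[[1]]$atoms), 3)
  expect_equal(nrow(back[[1]]$bonds), 2)
  expect_equal(sort_bonds(back[[2]]$bonds), sort_bonds(mols[[2]]$bonds))
  expect_equal(back[[2]]$atoms$coords, mols[[2]]$atoms$coords,
               tolerance = 1e-4)
  expect_equal(as.numeric(back[[1]]$properties$QED), 0.5)
  expect_true(all(vapply(back, `[[`, logical(1), "valid")))
})

test_that("corrupt bond blocks yield valid = FALSE, not a crash", {
  tf <- tempfile(fileext = ".sdf")
  writeLines(c("broken", "  fragdiff", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0",
               "    1.5000    0.0000    0.0000 C   0  0",
               "  1  9  1  0",  # bond to a nonexistent atom
               "M  END", "$$$$"), tf)
  recs <- fd_read_ligands(tf)
  expect_length(recs, 1)
  expect_false(recs[[1]]$valid)
  expect_error(suppressWarnings(fd_read_ligands(tempfile())),
               "cannot open|no SDF records|error")
})

test_that("virtual atoms are never serialized and empty input errors", {
  a <- fd_atomset(c("C", "C", "O"),
                  rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                  real_mask = c(TRUE, TRUE, FALSE))
  mol <- fd_molecule(a, fd_bonds(1, 2, "single"))
  tf <- tempfile(fileext = ".sdf")
  fd_write_molecules(list(mol), tf)
  back <- fd_read_ligands(tf)
  expect_equal(fd_n_atoms(back[[1]]$atoms), 2)
  expect_error(fd_write_molecules(list(), tf), "no molecule records")
})

test_that("pocket PDB round trip preserves coordinates to format precision", {
  cx <- tiny_complex("benzene", seed = 4)
  tf <- tempfile(fileext = ".pdb")
  fd_write_pocket(cx$pocket, tf)
  back <- fd_read_pocket(tf)
  expect_equal(fd_n_atoms(back$atoms), fd_n_atoms(cx$pocket$atoms))
  expect_equal(back$atoms$coords, cx$pocket$atoms$coords, tolerance = 1e-3)
  expect_equal(fd_elements(back$atoms), fd_elements(cx$pocket$atoms))
})

test_that("pocket selection is residue-level within the radius", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  %-3s %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1, "CA", "ALA", 1, 2.0, 0.0, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            2, "CB", "ALA", 1, 3.0, 0.0, 0.0, "C"),
    sprintf("ATOM  %5d  %-3s %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            3, "CA", "GLY", 2, 20.0, 0.0, 0.0, "C"),
    "END"), tf)
  lig <- fd_molecule(fd_atomset("C", matrix(0, 1, 3)))
  pk <- fd_read_pocket(tf, ligand = lig, radius = 10)
  # the residue 20 A away is excluded; the near residue enters whole
  expect_equal(fd_n_atoms(pk$atoms), 2)
  pk_all <- fd_read_pocket(tf)
  expect_equal(fd_n_atoms(pk_all$atoms), 3)
  expect_error(fd_read_pocket(tf, ligand = lig, radius = 1), "empty pocket")
  expect_error(fd_read_pocket(tempfile()), "failed to parse|cannot be opened")
})

test_that("sanitization flags valence violations without crashing", {
  a <- fd_atomset(rep("C", 6), cbind(seq(0, 7.5, by = 1.5), 0, 0))
  # central carbon with 5 single bonds
  b <- fd_bonds(rep(1, 5), 2:6, rep("single", 5))
  mol <- fd_molecule(a, b)
  san <- fd_sanitize(mol)
  expect_false(san$valid)
  expect_match(san$reason, "valence")
})
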