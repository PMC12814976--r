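# BRICS fragmentation, descriptors, Rule-of-Three filter, template slicing
# and dataset assembly.

test_that("BRICS cleavage agrees with the reference implementation", {
  ref <- jsonlite::read_json(test_path("fixtures-brics-reference.json"),
                             simplifyVector = TRUE)
  mols <- c(fixture_panel(), random_pool(40))
  names(mols) <- vapply(mols, `[[`, character(1), "name")
  for (nm in names(ref)) {
    b <- fd_brics_bonds(mols[[nm]])
    got <- if (nrow(b)) sort(paste(b$i, b$j, sep = "-")) else character()
    want <- sort(as.character(unlist(ref[[nm]], use.names = FALSE)))
    expect_equal(got, want, info = nm, ignore_attr = TRUE)
  }
})

test_that("BRICS fragments partition the molecule with boundary anchors", {
  for (m in c(fixture_panel(), random_pool(15, seed_offset = 300))) {
    frs <- fd_brics_decompose(m)
    idx <- lapply(frs, attr, "atom_idx")
    expect_setequal(unlist(idx), seq_len(fd_n_atoms(m$atoms)))
    expect_equal(sum(lengths(idx)), fd_n_atoms(m$atoms))  # disjoint
    cut <- fd_brics_bonds(m)
    cut_atoms <- unique(c(cut$i, cut$j))
    anch <- unlist(lapply(frs, function(f) attr(f, "atom_idx")[f$anchors]))
    expect_setequal(anch, cut_atoms)
    # fragment coordinates inherited from the parent
    for (f in frs) {
      expect_equal(f$atoms$coords,
                   m$atoms$coords[attr(f, "atom_idx"), , drop = FALSE])
    }
  }
})

test_that("single-heavy-atom molecules are a single anchor-free fragment", {
  frs <- fd_brics_decompose(fd_catalog_molecule("methane"))
  expect_length(frs, 1)
  expect_length(frs[[1]]$anchors, 0)
  expect_equal(fd_n_atoms(frs[[1]]$atoms), 1)
})

test_that("descriptors match independent reference computations", {
  # reference values computed with an independent cheminformatics toolkit
  d <- fd_compute_descriptors(fd_catalog_molecule("ethanol"))
  expect_equal(d$mw, 46.069, tolerance = 1e-3)
  expect_equal(d$logp, -0.0014, tolerance = 1e-3)
  expect_equal(d$tpsa, 20.23, tolerance = 1e-3)
  expect_equal(d$hbd, 1)
  expect_equal(d$hba, 1)
  expect_equal(d$rot_bonds, 0)

  b <- fd_compute_descriptors(fd_catalog_molecule("benzene"))
  expect_equal(b$hbd, 0); expect_equal(b$hba, 0)
  expect_equal(b$tpsa, 0); expect_equal(b$rot_bonds, 0)
  expect_equal(b$logp, 1.6866, tolerance = 1e-3)

  # amide N-H and carbonyl O count as donor and acceptor
  am <- fd_compute_descriptors(fd_catalog_molecule("n-methylacetamide"))
  expect_gte(am$hbd, 1)
  expect_gte(am$hba, 1)
})

test_that("the Rule-of-Three filter is the exact six-way conjunction", {
  base <- data.frame(mw = 150, logp = 1, hbd = 1, hba = 1, tpsa = 20,
                     rot_bonds = 0)
  frag <- fd_catalog_molecule("benzene")
  expect_true(fd_ro3_filter(frag, descriptors = base))
  for (mod in list(list(mw = 302), list(mw = 300), list(logp = 3.1),
                   list(hbd = 4), list(hba = 4), list(tpsa = 61),
                   list(rot_bonds = 1))) {
    d <- base
    d[[names(mod)]] <- mod[[1]]
    expect_false(fd_ro3_filter(frag, descriptors = d),
                 info = names(mod))
  }
  expect_true(fd_ro3_filter(fd_catalog_molecule("benzene")))
})

test_that("accepted fragments from a generated pool satisfy every bound", {
  pool <- random_pool(40, seed_offset = 600)
  frags <- unlist(lapply(pool, fd_brics_decompose), recursive = FALSE)
  descs <- fd_descriptor_table(frags)
  keep <- vapply(seq_along(frags), function(k) {
    fd_ro3_filter(frags[[k]], descriptors = descs[k, , drop = FALSE])
  }, logical(1))
  expect_gt(sum(keep), 0)
  acc <- descs[keep, ]
  expect_true(all(acc$mw < 300))
  expect_true(all(acc$logp <= 3))
  expect_true(all(acc$hbd <= 3))
  expect_true(all(acc$hba <= 3))
  expect_true(all(acc$tpsa <= 60))
  expect_true(all(acc$rot_bonds == 0))
})

test_that("reaction templates load and unknown matchers are refused", {
  tpl <- fd_read_templates()
  expect_gte(nrow(tpl), 10)
  expect_true(all(grepl(">>", tpl$smirks)))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsmirks\tdescription",
               "mystery\t[C:1]>>[C:1]\tunmatched"), bad)
  expect_error(fd_read_templates(bad), "no matcher")
})

test_that("slicing produces reassemblable scaffold/R-group pairs", {
  tpl <- fd_read_templates()
  m <- fd_catalog_molecule("n-methylacetamide")
  pairs <- fd_slice_scaffold_rgroups(m, tpl)
  ids <- vapply(pairs, `[[`, character(1), "template_id")
  expect_true("amide" %in% ids)
  am <- pairs[[which(ids == "amide")[1]]]
  # the R-group of the amide cut is the N-methyl side
  expect_setequal(am$rgroup_idx, c(4, 5))
  expect_setequal(am$scaffold_idx, c(1, 2, 3))
  for (mol in list(m, fd_catalog_molecule("methyl-phenyl-ether"),
                   fd_catalog_molecule("toluene"))) {
    for (p in fd_slice_scaffold_rgroups(mol, tpl)) {
      re <- fd_reassemble_pair(p)
      expect_equal(sort_bonds(re$bonds), sort_bonds(mol$bonds))
      expect_equal(re$atoms$coords, mol$atoms$coords)
      expect_equal(fd_elements(re$atoms), fd_elements(mol$atoms))
    }
  }
  # molecule matching no template
  expect_length(fd_slice_scaffold_rgroups(fd_catalog_molecule("propane"),
                                          tpl), 0)
})

test_that("dataset assembly slices, filters and splits deterministically", {
  cx <- fd_make_toy_complex(fd_toy_spec("methyl-phenyl-ether", 8, 3))
  complexes <- list(list(pocket = cx$pocket, ligand = cx$ligand,
                         id = "anisole"))
  ds1 <- fd_build_dataset(complexes, seed = 5)
  ds2 <- fd_build_dataset(complexes, seed = 5)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_gte(nrow(ds1$manifest), 1)
  expect_true(all(ds1$manifest$split %in% c("train", "validation", "test")))
  expect_true("train" %in% ds1$manifest$split)
  tf <- tempfile(fileext = ".csv")
  fd_write_manifest(ds1, tf)
  expect_equal(fd_read_manifest(tf)$template_id, ds1$manifest$template_id)

  # a complex whose only candidate seed keeps a rotatable bond yields
  # nothing: butyramide sliced at the amide bond leaves a flexible acyl
  # seed that the filter rejects
  chain <- fd_molecule(
    fd_atomset(c("C", "C", "C", "C", "O", "N", "C"),
               cbind(seq(0, 9, by = 1.5), 0, 0)),
    fd_bonds(c(1, 2, 3, 4, 4, 6), c(2, 3, 4, 5, 6, 7),
             c("single", "single", "single", "double", "single", "single")))
  amide_only <- fd_read_templates()[fd_read_templates()$id == "amide", ]
  expect_error(
    fd_build_dataset(list(list(pocket = cx$pocket, ligand = chain)),
                     templates = amide_only, seed = 1),
    "empty dataset")
})
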