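# Synthetic protein-ligand fixtures: a pocket shell around an
# ideal-geometry catalog ligand, with a consistent
# fragment / scaffold / R-group partition, plus a seeded random-molecule
# generator used to build fragment pools at test scale.

#' Toy complex specification
#'
#' @param template_name Catalog template for the ligand (see
#'   [fd_catalog_names()]).
#' @param pocket_shell_radius Radius (Angstrom) of the pseudo-atom shell
#'   around the ligand centroid; must exceed the ligand extent.
#' @param seed Integer seed; the resulting complex is a pure function of the
#'   spec.
#' @param n_pocket_atoms Number of shell pseudo-atoms.
#' @return An object of class `fd_toy_spec`.
#' @export
fd_toy_spec <- function(template_name, pocket_shell_radius = 6, seed = 1L,
                        n_pocket_atoms = 16L) {
  tpl <- fd_catalog_get(template_name)
  extent <- if (nrow(tpl$coords) > 1) {
    cen <- colMeans(tpl$coords)
    max(sqrt(rowSums(sweep(tpl$coords, 2, cen)^2)))
  } else 0
  if (pocket_shell_radius <= extent) {
    stop("pocket_shell_radius (", pocket_shell_radius,
         ") must exceed the ligand extent (", round(extent, 2), ")")
  }
  structure(list(template_name = template_name,
                 pocket_shell_radius = pocket_shell_radius,
                 seed = as.integer(seed),
                 n_pocket_atoms = as.integer(n_pocket_atoms)),
            class = "fd_toy_spec")
}

#' Build a synthetic protein-ligand training fixture
#'
#' Constructs, deterministically from the spec, a pocket shell of
#' pseudo-atoms at the requested radius, the catalog ligand, and the
#' partition used by the two generation stages: a seed fragment (with growth
#' anchors at the partition boundary), the scaffold atom set and the R-group
#' atom set. The fragment is a subset of the scaffold, and scaffold plus
#' R-group exactly cover the ligand's heavy atoms.
#'
#' @param spec An [fd_toy_spec()].
#' @return A list with fields `pocket` (`fd_pocket`), `ligand`
#'   (`fd_molecule`), `fragment` (`fd_fragment`), `scaffold` (`fd_atomset`),
#'   `rgroup` (`fd_atomset`), plus index bookkeeping (`scaffold_idx`,
#'   `rgroup_idx`, `fragment_idx`, `attachment`).
#' @export
fd_make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "fd_toy_spec"))
  tpl <- fd_catalog_get(spec$template_name)
  ligand <- fd_catalog_molecule(spec$template_name)
  cen <- colMeans(ligand$atoms$coords)

  pocket <- fd_with_seed(spec$seed, {
    z <- matrix(stats::rnorm(spec$n_pocket_atoms * 3), ncol = 3)
    dirs <- z / sqrt(rowSums(z^2))
    xyz <- sweep(dirs * spec$pocket_shell_radius, 2, cen, `+`)
    els <- sample(c("C", "C", "N", "O", "S"), spec$n_pocket_atoms,
                  replace = TRUE)
    fd_pocket(fd_atomset(els, xyz),
              residue_labels = paste0("SHL", seq_len(spec$n_pocket_atoms)),
              source_id = paste0("toy:", spec$template_name, ":", spec$seed))
  })

  frag_idx <- tpl$fragment
  sub_bonds <- function(idx) {
    keep <- ligand$bonds$i %in% idx & ligand$bonds$j %in% idx
    b <- ligand$bonds[keep, , drop = FALSE]
    b$i <- match(b$i, idx); b$j <- match(b$j, idx)
    b
  }
  fragment <- fd_fragment(fd_atomset_subset(ligand$atoms, frag_idx),
                          anchors = match(tpl$anchors, frag_idx),
                          bonds = sub_bonds(frag_idx))
  list(pocket = pocket,
       ligand = ligand,
       fragment = fragment,
       scaffold = fd_atomset_subset(ligand$atoms, tpl$scaffold),
       rgroup = fd_atomset_subset(ligand$atoms, tpl$rgroup),
       fragment_idx = frag_idx,
       scaffold_idx = tpl$scaffold,
       rgroup_idx = tpl$rgroup,
       attachment = tpl$attachment,
       spec = spec)
}

# ---- Random drug-like molecule generator ----------------------------------

# Building blocks for the pool generator: small graph motifs with open
# valences. Coordinates are a crude breadth-first embedding (fixed 1.5 A
# steps, randomized directions); pools feed graph-level operations
# (fragmentation, descriptors), not geometric ones.
.fd_blocks <- function() {
  ring6 <- function(cls, els) {
    list(elements = els,
         bonds = fd_bonds(1:6, c(2:6, 1), rep(cls, 6)))
  }
  list(
    benzene = ring6("aromatic", rep("C", 6)),
    pyridine = ring6("aromatic", c("N", rep("C", 5))),
    cyclohexane = ring6("single", rep("C", 6)),
    amide = list(elements = c("C", "O", "N"),
                 bonds = fd_bonds(c(1, 1), c(2, 3), c("double", "single"))),
    ester = list(elements = c("C", "O", "O"),
                 bonds = fd_bonds(c(1, 1), c(2, 3), c("double", "single"))),
    ethyl = list(elements = c("C", "C"), bonds = fd_bonds(1, 2, "single")),
    methyl = list(elements = "C", bonds = fd_empty_bonds()),
    hydroxyl = list(elements = "O", bonds = fd_empty_bonds()),
    amine = list(elements = "N", bonds = fd_empty_bonds()),
    ether_o = list(elements = "O", bonds = fd_empty_bonds()),
    fluoro = list(elements = "F", bonds = fd_empty_bonds()),
    chloro = list(elements = "Cl", bonds = fd_empty_bonds()),
    thio = list(elements = "S", bonds = fd_empty_bonds())
  )
}

#' Random synthetic molecule
#'
#' Assembles a random drug-like heavy-atom graph from a library of motifs
#' (aromatic and aliphatic rings, amide/ester groups, chains and terminal
#' decorations), connecting blocks by single bonds at valence-legal
#' positions, and embeds crude 3D coordinates. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param n_blocks Number of blocks to join (default drawn in 2..5).
#' @return An `fd_molecule`.
#' @export
fd_random_molecule <- function(seed, n_blocks = NULL) {
  fd_with_seed(seed, {
    blocks <- .fd_blocks()
    if (is.null(n_blocks)) n_blocks <- sample(2:5, 1)
    # weights favor rings + functional groups over terminals
    wts <- c(benzene = 3, pyridine = 2, cyclohexane = 1.5, amide = 2,
             ester = 1.5, ethyl = 2, methyl = 2, hydroxyl = 1.5, amine = 1.5,
             ether_o = 1.5, fluoro = 1, chloro = 1, thio = 0.5)
    els <- character(); bonds <- fd_empty_bonds()
    free_val <- numeric()
    add_block <- function(bl) {
      off <- length(els)
      els <<- c(els, bl$elements)
      if (nrow(bl$bonds)) {
        b <- bl$bonds; b$i <- b$i + off; b$j <- b$j + off
        bonds <<- rbind(bonds, b)
      }
      off + seq_along(bl$elements)
    }
    used_valence <- function() {
      u <- rep(0, length(els))
      if (nrow(bonds)) {
        ord <- fd_bond_order_num(bonds$class)
        for (k in seq_len(nrow(bonds))) {
          u[bonds$i[k]] <- u[bonds$i[k]] + ord[k]
          u[bonds$j[k]] <- u[bonds$j[k]] + ord[k]
        }
      }
      u
    }
    first <- sample(names(wts), 1, prob = wts)
    add_block(blocks[[first]])
    for (b in seq_len(n_blocks - 1)) {
      nm <- sample(names(wts), 1, prob = wts)
      bl <- blocks[[nm]]
      open_old <- which(fd_default_valence(els) - round(used_valence()) >= 1)
      if (!length(open_old)) break
      at_old <- if (length(open_old) == 1) open_old else sample(open_old, 1)
      new_idx <- add_block(bl)
      open_new <- new_idx[fd_default_valence(els[new_idx]) -
                            round(used_valence()[new_idx]) >= 1]
      at_new <- if (length(open_new) == 1) open_new else sample(open_new, 1)
      bonds <- rbind(bonds, fd_bonds(at_old, at_new, "single"))
    }
    # crude breadth-first 3D embedding
    n <- length(els)
    coords <- matrix(0, n, 3)
    placed <- rep(FALSE, n); placed[1] <- TRUE
    nb <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
      nb[[bonds$i[k]]] <- c(nb[[bonds$i[k]]], bonds$j[k])
      nb[[bonds$j[k]]] <- c(nb[[bonds$j[k]]], bonds$i[k])
    }
    queue <- 1L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (x in nb[[cur]]) {
        if (placed[x]) next
        d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
        coords[x, ] <- coords[cur, ] + 1.5 * d
        placed[x] <- TRUE
        queue <- c(queue, x)
      }
    }
    fd_molecule(fd_atomset(els, coords), bonds,
                name = paste0("rand", seed))
  })
}
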