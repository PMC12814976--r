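# Ideal-geometry template catalog. Every fixture molecule is constructed
# from tabulated bond lengths and canonical angles (tetrahedral 109.4712,
# trigonal 120, regular rings), so its geometry is exactly consistent with
# its reference bond list. This makes the catalog usable as ground truth for
# bond perception and for the geometric evaluator.

.fd_tet <- 109.4712206

fd_zm <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(el = r[[1]], ref1 = r[[2]], ref2 = r[[3]], ref3 = r[[4]],
               r = r[[5]], ang = r[[6]], dih = r[[7]],
               stringsAsFactors = FALSE)
  }))
  df
}

# Regular planar ring of side `s` (z = 0), returned as n x 3 coordinates.
fd_ring_coords <- function(n, s) {
  R <- s / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(th), R * sin(th), 0)
}

# Attach an atom radially outward from ring atom `k` (planar ring centered
# at the origin), at distance r.
fd_ring_substituent <- function(ring_xyz, k, r) {
  u <- fd_unit(ring_xyz[k, ])
  ring_xyz[k, ] + r * u
}

.fd_build_catalog <- function() {
  tpl <- list()
  add <- function(name, elements, coords, bonds, fragment, scaffold, rgroup,
                  anchors, attachment = NULL, hydrogens = NULL) {
    tpl[[name]] <<- list(
      name = name, elements = elements, coords = coords, bonds = bonds,
      fragment = fragment, scaffold = scaffold, rgroup = rgroup,
      anchors = anchors, attachment = attachment, hydrogens = hydrogens)
  }
  ringb <- function(n, class = "aromatic") {
    fd_bonds(seq_len(n), c(seq_len(n)[-1], 1), rep(class, n))
  }

  # -- acyclic, tetrahedral ------------------------------------------------
  add("methane", "C", matrix(0, 1, 3), fd_empty_bonds(),
      fragment = 1, scaffold = 1, rgroup = integer(), anchors = integer(),
      hydrogens = list(attach = c(1, 1, 1, 1),
                       coords = 1.09 / sqrt(3) *
                         rbind(c(1, 1, 1), c(1, -1, -1),
                               c(-1, 1, -1), c(-1, -1, 1))))
  add("ethane", c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
      fd_bonds(1, 2, "single"),
      fragment = 1, scaffold = 1, rgroup = 2, anchors = 1,
      attachment = c(1, 2))
  add("ethene", c("C", "C"), rbind(c(0, 0, 0), c(1.34, 0, 0)),
      fd_bonds(1, 2, "double"),
      fragment = 1, scaffold = 1, rgroup = 2, anchors = 1,
      attachment = c(1, 2))
  add("ethyne", c("C", "C"), rbind(c(0, 0, 0), c(1.20, 0, 0)),
      fd_bonds(1, 2, "triple"),
      fragment = 1, scaffold = 1, rgroup = 2, anchors = 1,
      attachment = c(1, 2))
  add("propane", c("C", "C", "C"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("C", 1, 0, 0, 1.54, 0, 0),
        list("C", 2, 1, 0, 1.54, .fd_tet, 0))),
      fd_bonds(c(1, 2), c(2, 3), c("single", "single")),
      fragment = c(1, 2), scaffold = c(1, 2), rgroup = 3, anchors = 2,
      attachment = c(2, 3))
  add("ethanol", c("C", "C", "O"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("C", 1, 0, 0, 1.54, 0, 0),
        list("O", 2, 1, 0, 1.43, .fd_tet, 0))),
      fd_bonds(c(1, 2), c(2, 3), c("single", "single")),
      fragment = 1, scaffold = c(1, 2), rgroup = 3, anchors = 1,
      attachment = c(2, 3))
  add("dimethyl-ether", c("C", "O", "C"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("O", 1, 0, 0, 1.43, 0, 0),
        list("C", 2, 1, 0, 1.43, .fd_tet, 0))),
      fd_bonds(c(1, 2), c(2, 3), c("single", "single")),
      fragment = 1, scaffold = c(1, 2), rgroup = 3, anchors = 1,
      attachment = c(2, 3))
  add("methylamine", c("C", "N"), rbind(c(0, 0, 0), c(1.47, 0, 0)),
      fd_bonds(1, 2, "single"),
      fragment = 1, scaffold = 1, rgroup = 2, anchors = 1,
      attachment = c(1, 2))
  add("methanethiol", c("C", "S"), rbind(c(0, 0, 0), c(1.82, 0, 0)),
      fd_bonds(1, 2, "single"),
      fragment = 1, scaffold = 1, rgroup = 2, anchors = 1,
      attachment = c(1, 2))

  # -- carbonyl chemistry --------------------------------------------------
  add("acetone", c("C", "C", "O", "C"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("C", 1, 0, 0, 1.51, 0, 0),
        list("O", 2, 1, 0, 1.22, 120, 0),
        list("C", 2, 1, 3, 1.51, 120, 180))),
      fd_bonds(c(1, 2, 2), c(2, 3, 4), c("single", "double", "single")),
      fragment = c(1, 2, 3), scaffold = c(1, 2, 3), rgroup = 4, anchors = 2,
      attachment = c(2, 4))
  add("acetic-acid", c("C", "C", "O", "O"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("C", 1, 0, 0, 1.51, 0, 0),
        list("O", 2, 1, 0, 1.22, 120, 0),
        list("O", 2, 1, 3, 1.36, 120, 180))),
      fd_bonds(c(1, 2, 2), c(2, 3, 4), c("single", "double", "single")),
      fragment = c(1, 2, 3), scaffold = c(1, 2, 3), rgroup = 4, anchors = 2,
      attachment = c(2, 4))
  add("n-methylacetamide", c("C", "C", "O", "N", "C"),
      fd_zmatrix_coords(fd_zm(
        list("C", 0, 0, 0, 0, 0, 0),
        list("C", 1, 0, 0, 1.51, 0, 0),
        list("O", 2, 1, 0, 1.23, 120, 0),
        list("N", 2, 1, 3, 1.35, 120, 180),
        list("C", 4, 2, 1, 1.45, 120, 180))),
      fd_bonds(c(1, 2, 2, 4), c(2, 3, 4, 5),
               c("single", "double", "single", "single")),
      fragment = c(1, 2, 3), scaffold = c(1, 2, 3, 4), rgroup = 5,
      anchors = 2, attachment = c(4, 5))

  # -- rings ---------------------------------------------------------------
  benz <- fd_ring_coords(6, 1.39)
  add("benzene", rep("C", 6), benz, ringb(6),
      fragment = 1:6, scaffold = 1:6, rgroup = integer(), anchors = 1)
  add("toluene", c(rep("C", 6), "C"),
      rbind(benz, fd_ring_substituent(benz, 1, 1.51)),
      rbind(ringb(6), fd_bonds(1, 7, "single")),
      fragment = 1:6, scaffold = 1:6, rgroup = 7, anchors = 1,
      attachment = c(1, 7))
  add("phenol", c(rep("C", 6), "O"),
      rbind(benz, fd_ring_substituent(benz, 1, 1.36)),
      rbind(ringb(6), fd_bonds(1, 7, "single")),
      fragment = 1:6, scaffold = 1:6, rgroup = 7, anchors = 1,
      attachment = c(1, 7))
  add("fluorobenzene", c(rep("C", 6), "F"),
      rbind(benz, fd_ring_substituent(benz, 1, 1.35)),
      rbind(ringb(6), fd_bonds(1, 7, "single")),
      fragment = 1:6, scaffold = 1:6, rgroup = 7, anchors = 1,
      attachment = c(1, 7))
  o7 <- fd_ring_substituent(benz, 1, 1.36)
  c8 <- fd_place_atom(o7, benz[1, ], benz[2, ], 1.43, 120, 180)
  add("methyl-phenyl-ether", c(rep("C", 6), "O", "C"),
      rbind(benz, o7, c8),
      rbind(ringb(6), fd_bonds(c(1, 7), c(7, 8), c("single", "single"))),
      fragment = 1:6, scaffold = 1:7, rgroup = 8, anchors = 1,
      attachment = c(7, 8))
  pyr <- fd_ring_coords(6, 1.37)
  add("pyridine", c("N", rep("C", 5)), pyr, ringb(6),
      fragment = 1:6, scaffold = 1:6, rgroup = integer(), anchors = 2)
  # near-ideal chair: alternating z, side exactly 1.54
  zc <- 0.25
  Rc <- sqrt((1.54^2 - (2 * zc)^2) / (2 - 2 * cos(pi / 3)))
  th <- 2 * pi * (0:5) / 6
  chair <- cbind(Rc * cos(th), Rc * sin(th), zc * rep(c(1, -1), 3))
  add("cyclohexane", rep("C", 6), chair, ringb(6, "single"),
      fragment = 1:6, scaffold = 1:6, rgroup = integer(), anchors = 1)

  tpl
}

.fd_catalog_env <- new.env(parent = emptyenv())

#' Ideal-geometry fixture catalog
#'
#' Names of the bundled ideal-geometry molecule templates. Each template
#' records elements, coordinates built from tabulated bond lengths and
#' canonical angles, a reference bond list, and a consistent
#' fragment / scaffold / R-group partition with growth anchors at the
#' partition boundary.
#'
#' @return Character vector of template names.
#' @export
fd_catalog_names <- function() {
  names(fd_catalog())
}

fd_catalog <- function() {
  if (is.null(.fd_catalog_env$tpl)) .fd_catalog_env$tpl <- .fd_build_catalog()
  .fd_catalog_env$tpl
}

fd_catalog_get <- function(name) {
  tpl <- fd_catalog()[[name]]
  if (is.null(tpl)) {
    stop("unknown template '", name, "'; available: ",
         paste(names(fd_catalog()), collapse = ", "))
  }
  tpl
}

#' Build a fixture molecule from the catalog
#'
#' @param name Template name (see [fd_catalog_names()]).
#' @param explicit_h Add explicit hydrogens where the template provides them
#'   (vocabulary is extended by an `H` category).
#' @return An `fd_molecule` with reference bonds and ideal geometry.
#' @export
fd_catalog_molecule <- function(name, explicit_h = FALSE) {
  tpl <- fd_catalog_get(name)
  if (explicit_h) {
    if (is.null(tpl$hydrogens)) {
      stop("template '", name, "' has no explicit-hydrogen variant")
    }
    nh <- nrow(tpl$hydrogens$coords)
    vocab <- c(fd_element_vocab(), "H")
    atoms <- fd_atomset(c(tpl$elements, rep("H", nh)),
                        rbind(tpl$coords, tpl$hydrogens$coords),
                        vocab = vocab)
    hb <- fd_bonds(tpl$hydrogens$attach,
                   length(tpl$elements) + seq_len(nh), rep("single", nh))
    return(fd_molecule(atoms, rbind(tpl$bonds, hb), name = name))
  }
  fd_molecule(fd_atomset(tpl$elements, tpl$coords), tpl$bonds, name = name)
}
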