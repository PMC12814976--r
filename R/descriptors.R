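# Fragment-likeness descriptors and the Rule-of-Three filter.
#
# MW, donor/acceptor counts and rotatable bonds are computed natively from
# the heavy-atom graph (donors = N/O atoms carrying at least one hydrogen,
# acceptors = N/O atoms, the counting rule used for fragment screening);
# logP (Wildman-Crippen) and TPSA (Ertl) are obtained from OpenBabel via
# ChemmineOB, the established implementations of those two estimators.

.fd_as_molecule <- function(x) {
  if (inherits(x, "fd_molecule")) return(x)
  if (inherits(x, "fd_fragment")) {
    # anchors are open valences, capped with implicit hydrogen
    return(fd_molecule(x$atoms, x$bonds, name = "fragment"))
  }
  stop("expected an fd_molecule or fd_fragment")
}

# Atom-contribution logP and polar-surface values for isolated heavy atoms
# (neutral hydrides); bondless single-atom records cannot go through the
# SDF route.
.fd_single_atom_props <- data.frame(
  el = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "other"),
  logP = c(0.6361, 0.162, -0.8247, 0.1525, 0.0581, 0.1128, 0.4218,
           0.5779, 0),
  TPSA = c(0, 35.0, 31.5, 0, 0, 0, 0, 0, 0))

# Batched OpenBabel descriptor computation over a list of molecules.
# Single-atom molecules are served from the hydride table.
fd_ob_props <- function(mols) {
  single <- vapply(mols, function(m) fd_n_atoms(m$atoms) == 1, logical(1))
  out <- data.frame(logP = numeric(length(mols)),
                    TPSA = numeric(length(mols)))
  if (any(single)) {
    el <- vapply(mols[single], function(m) fd_elements(m$atoms), character(1))
    hit <- match(el, .fd_single_atom_props$el)
    out$logP[single] <- .fd_single_atom_props$logP[hit]
    out$TPSA[single] <- .fd_single_atom_props$TPSA[hit]
  }
  if (any(!single)) {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf))
    fd_write_molecules(mols[!single], tf)
    sdf <- suppressWarnings(ChemmineR::read.SDFset(tf))
    ob <- suppressWarnings(ChemmineR::propOB(sdf))
    if (nrow(ob) != sum(!single)) {
      stop("descriptor backend returned ", nrow(ob), " records for ",
           sum(!single), " molecules")
    }
    out$logP[!single] <- ob$logP
    out$TPSA[!single] <- ob$TPSA
  }
  out
}

#' Fragment-likeness descriptor panel
#'
#' @param x An `fd_molecule` or `fd_fragment` (anchor positions are treated
#'   as hydrogen-capped open valences).
#' @return A one-row data frame: `mw` (Da), `logp`, `hbd`, `hba`,
#'   `tpsa` (Angstrom^2), `rot_bonds`.
#' @export
fd_compute_descriptors <- function(x) {
  fd_descriptor_table(list(x))
}

#' @rdname fd_compute_descriptors
#' @param xs List of molecules/fragments (batched, much faster than
#'   per-molecule calls).
#' @export
fd_descriptor_table <- function(xs) {
  mols <- lapply(xs, .fd_as_molecule)
  for (m in mols) {
    san <- fd_sanitize(m)
    if (!san$valid) stop("cannot compute descriptors: ", san$reason)
  }
  ob <- fd_ob_props(mols)
  native <- do.call(rbind, lapply(mols, function(m) {
    el <- fd_elements(m$atoms)
    hs <- fd_implicit_h(m)
    data.frame(
      mw = sum(fd_atomic_weight(el)) + 1.008 * sum(hs[el != "H"]),
      hbd = sum(el %in% c("N", "O") & hs > 0),
      hba = sum(el %in% c("N", "O")),
      rot_bonds = fd_rotatable_bonds(m))
  }))
  data.frame(mw = native$mw, logp = ob$logP, hbd = native$hbd,
             hba = native$hba, tpsa = ob$TPSA, rot_bonds = native$rot_bonds)
}

#' Rule-of-Three fragment filter
#'
#' Accepts a fragment exactly when all six criteria hold: molecular weight
#' below 300 Da, logP at most 3, at most 3 hydrogen-bond donors, at most 3
#' acceptors, TPSA at most 60 Angstrom^2, and no rotatable bonds.
#'
#' @param frag An `fd_fragment` or `fd_molecule`.
#' @param descriptors Optional precomputed row from
#'   [fd_compute_descriptors()] (used by batched callers).
#' @return Logical.
#' @export
fd_ro3_filter <- function(frag, descriptors = NULL) {
  d <- if (is.null(descriptors)) fd_compute_descriptors(frag) else descriptors
  isTRUE(d$mw < 300 & d$logp <= 3 & d$hbd <= 3 & d$hba <= 3 &
           d$tpsa <= 60 & d$rot_bonds == 0)
}
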