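# BRICS fragmentation: retrosynthetic cleavage of prototypical bonds.
#
# Link-atom environments (the L1..L16 typing of the BRICS rule set) are
# implemented as predicates over the heavy-atom graph, together with the
# standard compatibility matrix of cleavable environment pairs. Every
# matched acyclic single bond is cut simultaneously; the connected
# components of the remainder are the fragments, and the atoms incident to
# cut bonds become growth anchors.

# Per-atom context used by the environment predicates.
.fd_atom_ctx <- function(mol) {
  n <- fd_n_atoms(mol$atoms)
  el <- fd_elements(mol$atoms)
  ri <- fd_rings(mol)
  nb <- fd_neighbors(mol)
  cls <- matrix(NA_character_, n, n)
  inring_bond <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    cls[i, j] <- cls[j, i] <- mol$bonds$class[k]
    inring_bond[i, j] <- inring_bond[j, i] <- ri$bond_in_ring[k]
  }
  deg <- lengths(nb)
  aromatic <- vapply(seq_len(n), function(i) {
    any(cls[i, nb[[i]]] == "aromatic")
  }, logical(1))
  list(el = el, nb = nb, cls = cls, deg = deg, aromatic = aromatic,
       in_ring = ri$atom_in_ring, ring_bond = inring_bond)
}

# Environment typing for atom i (neighborhood conditions in the rule set
# are recursive constraints on the atom's own bonds, independent of which
# incident bond is being cleaved). Returns the link labels atom i carries.
.fd_brics_envs <- function(ctx, i) {
  el <- ctx$el; nb <- ctx$nb[[i]]; cls <- ctx$cls
  arom <- ctx$aromatic
  labs <- character()
  has_dbl_o <- any(el[nb] == "O" & cls[i, nb] == "double")
  all_single <- all(cls[i, nb] == "single")
  # acyclic single bond to some carbon
  acyc_c <- any(el[nb] == "C" & cls[i, nb] == "single" &
                  !ctx$ring_bond[i, nb])
  if (el[i] == "C" && !arom[i]) {
    if (ctx$deg[i] == 3 && has_dbl_o &&
        any(el[nb] %in% c("C", "N", "O"))) {
      labs <- c(labs, "1")
      if (!ctx$in_ring[i]) labs <- c(labs, "6")
    }
    no_multiple <- !any(cls[i, nb] %in% c("double", "triple", "aromatic"))
    if (ctx$deg[i] >= 2 && no_multiple && acyc_c) labs <- c(labs, "4")
    if (!ctx$in_ring[i] && ctx$deg[i] >= 2 && all_single) labs <- c(labs, "8")
    if (ctx$in_ring[i]) {
      ring_nb <- nb[ctx$ring_bond[i, nb]]
      if (any(el[ring_nb] %in% c("N", "O", "S")) &&
          any(el[ring_nb] %in% c("C", "N", "O", "S"))) labs <- c(labs, "13")
      if (sum(el[ring_nb] == "C") >= 2) labs <- c(labs, "15")
    }
  }
  if (el[i] == "C" && arom[i]) {
    arom_nb <- nb[cls[i, nb] == "aromatic"]
    n_arc <- sum(el[arom_nb] == "C" & arom[arom_nb])
    n_arh <- sum(el[arom_nb] %in% c("N", "O", "S") & arom[arom_nb])
    if (n_arc >= 2) labs <- c(labs, "16")
    if (n_arh >= 1 && length(arom_nb) >= 2) labs <- c(labs, "14")
  }
  if (el[i] == "N" && !arom[i]) {
    no_dbl <- !any(cls[i, nb] %in% c("double", "triple"))
    only_cs <- all(el[nb] %in% c("C", "S", "H"))
    ring_amide <- ctx$in_ring[i] && any(vapply(nb, function(x) {
      ctx$ring_bond[i, x] && el[x] == "C" &&
        any(el[ctx$nb[[x]]] == "O" & cls[x, ctx$nb[[x]]] == "double")
    }, logical(1)))
    if (ctx$deg[i] >= 2 && no_dbl && only_cs && !ring_amide) {
      labs <- c(labs, "5")
    }
    if (ctx$in_ring[i] && any(vapply(nb, function(x) {
      ctx$ring_bond[i, x] && el[x] == "C" &&
        any(el[ctx$nb[[x]]] == "O" & cls[x, ctx$nb[[x]]] == "double")
    }, logical(1)))) labs <- c(labs, "10")
  }
  if (el[i] == "N" && arom[i] && ctx$in_ring[i]) labs <- c(labs, "9")
  if (el[i] == "O" && ctx$deg[i] == 2 &&
      any(el[nb] == "C" & cls[i, nb] == "single" & !ctx$ring_bond[i, nb])) {
    labs <- c(labs, "3")
  }
  if (el[i] == "S") {
    n_dbl_o <- sum(el[nb] == "O" & cls[i, nb] == "double")
    if (ctx$deg[i] == 2 && n_dbl_o == 0 && acyc_c) labs <- c(labs, "11")
    if (ctx$deg[i] == 4 && n_dbl_o == 2) labs <- c(labs, "12")
  }
  labs
}

.fd_brics_pairs <- matrix(c(
  "1", "3",  "1", "5",  "1", "10",
  "3", "4",  "3", "13", "3", "14", "3", "15", "3", "16",
  "4", "5",  "4", "11",
  "5", "12", "5", "13", "5", "14", "5", "15", "5", "16",
  "6", "13", "6", "14", "6", "15", "6", "16",
  "8", "9",  "8", "10", "8", "13", "8", "14", "8", "15", "8", "16",
  "9", "13", "9", "14", "9", "15", "9", "16",
  "10", "13", "10", "14", "10", "15", "10", "16",
  "11", "13", "11", "14", "11", "15", "11", "16",
  "13", "14", "13", "15", "13", "16",
  "14", "14", "14", "15", "14", "16",
  "15", "16", "16", "16"), ncol = 2, byrow = TRUE)

#' Find cleavable bonds under the BRICS rule set
#'
#' @param mol A valid `fd_molecule`.
#' @return Data frame with columns `i`, `j`, `label_i`, `label_j`, one row
#'   per cleavable acyclic single bond.
#' @export
fd_brics_bonds <- function(mol) {
  out <- data.frame(i = integer(), j = integer(),
                    label_i = character(), label_j = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(mol$bonds)) return(out)
  ctx <- .fd_atom_ctx(mol)
  ri <- fd_rings(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$class[k] != "single" || ri$bond_in_ring[k]) next
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    li <- .fd_brics_envs(ctx, i)
    lj <- .fd_brics_envs(ctx, j)
    hit <- NULL
    for (p in seq_len(nrow(.fd_brics_pairs))) {
      a <- .fd_brics_pairs[p, 1]; b <- .fd_brics_pairs[p, 2]
      if (a %in% li && b %in% lj) { hit <- c(a, b); break }
      if (b %in% li && a %in% lj) { hit <- c(b, a); break }
    }
    if (!is.null(hit)) {
      out <- rbind(out, data.frame(i = i, j = j, label_i = hit[1],
                                   label_j = hit[2],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' BRICS fragmentation with anchor extraction
#'
#' Cuts every cleavable bond simultaneously; the resulting connected
#' components partition the molecule's heavy atoms. Atoms incident to cut
#' bonds become the fragment's growth anchors; 3D coordinates are inherited
#' from the parent molecule.
#'
#' @param mol A valid `fd_molecule`.
#' @return List of `fd_fragment`, each with an `atom_idx` attribute giving
#'   the parent-molecule indices.
#' @export
fd_brics_decompose <- function(mol) {
  san <- fd_sanitize(mol)
  if (!san$valid) stop("invalid molecule: ", san$reason)
  cut <- fd_brics_bonds(mol)
  cut_key <- paste(cut$i, cut$j)
  keep <- !(paste(mol$bonds$i, mol$bonds$j) %in% cut_key)
  residual <- fd_molecule(mol$atoms, mol$bonds[keep, , drop = FALSE])
  comps <- fd_components(residual)
  lapply(comps, function(idx) {
    idx <- sort(idx)
    b <- residual$bonds[residual$bonds$i %in% idx &
                          residual$bonds$j %in% idx, , drop = FALSE]
    b$i <- match(b$i, idx); b$j <- match(b$j, idx)
    anchors <- sort(match(intersect(idx, c(cut$i, cut$j)), idx))
    fr <- fd_fragment(fd_atomset_subset(mol$atoms, idx),
                      anchors = anchors, bonds = b)
    attr(fr, "atom_idx") <- idx
    fr
  })
}
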