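# Molecular-graph utilities shared by the fragmenter, the bond builder and
# the evaluator: ring perception, implicit hydrogens, rotatable bonds,
# circular fingerprints.

# Bond order as a number; aromatic counts 1.5 toward valence.
fd_bond_order_num <- function(class) {
  c(single = 1, double = 2, aromatic = 1.5, triple = 3)[class]
}

# igraph view of a molecule's heavy-atom connectivity.
fd_mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(fd_n_atoms(mol$atoms))))
}

# Neighbor lists: for each atom, the indices bonded to it.
fd_neighbors <- function(mol) {
  n <- fd_n_atoms(mol$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# Smallest-ring membership. Returns a list of rings (integer vectors) from a
# minimum cycle basis, plus per-atom and per-bond ring flags.
fd_rings <- function(mol) {
  g <- fd_mol_graph(mol)
  n <- fd_n_atoms(mol$atoms)
  in_ring_atom <- rep(FALSE, n)
  rings <- list()
  if (nrow(mol$bonds)) {
    # Fundamental cycles from a spanning forest, then reduce to minimal
    # cycles by shortest alternative path per chord.
    mst <- igraph::mst(g)
    mst_pairs <- igraph::as_edgelist(mst)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mst_keys <- key(as.integer(mst_pairs[, 1]), as.integer(mst_pairs[, 2]))
    all_keys <- key(mol$bonds$i, mol$bonds$j)
    chords <- which(!(all_keys %in% mst_keys))
    for (k in chords) {
      pth <- igraph::shortest_paths(mst, from = mol$bonds$i[k],
                                    to = mol$bonds$j[k])$vpath[[1]]
      ring <- as.integer(pth)
      rings[[length(rings) + 1L]] <- ring
      in_ring_atom[ring] <- TRUE
    }
  }
  ring_bond <- rep(FALSE, nrow(mol$bonds))
  for (r in rings) {
    edges <- cbind(r, c(r[-1], r[1]))
    for (e in seq_len(nrow(edges))) {
      hit <- (mol$bonds$i == min(edges[e, ]) & mol$bonds$j == max(edges[e, ]))
      ring_bond[hit] <- TRUE
    }
  }
  list(rings = rings, atom_in_ring = in_ring_atom, bond_in_ring = ring_bond)
}

#' Ring count of a molecular graph
#'
#' The cyclomatic number (bonds - atoms + components) of the heavy-atom
#' graph.
#' @param mol An `fd_molecule`.
#' @return Integer ring count.
#' @export
fd_n_rings <- function(mol) {
  n <- fd_n_atoms(mol$atoms)
  if (n == 0) return(0L)
  comps <- igraph::components(fd_mol_graph(mol))$no
  as.integer(nrow(mol$bonds) - n + comps)
}

# Aromatic ring count (rings in which every bond is of class "aromatic").
fd_n_aromatic_rings <- function(mol) {
  ri <- fd_rings(mol)
  if (!length(ri$rings)) return(0L)
  cls <- function(a, b) {
    hit <- mol$bonds$i == min(a, b) & mol$bonds$j == max(a, b)
    if (any(hit)) mol$bonds$class[which(hit)[1]] else NA_character_
  }
  cnt <- 0L
  for (r in ri$rings) {
    edges <- cbind(r, c(r[-1], r[1]))
    if (all(vapply(seq_len(nrow(edges)),
                   function(e) identical(cls(edges[e, 1], edges[e, 2]), "aromatic"),
                   logical(1)))) cnt <- cnt + 1L
  }
  cnt
}

# Valence currently used by explicit bonds, per atom.
fd_used_valence <- function(mol) {
  n <- fd_n_atoms(mol$atoms)
  used <- rep(0, n)
  if (nrow(mol$bonds)) {
    ord <- fd_bond_order_num(mol$bonds$class)
    for (k in seq_len(nrow(mol$bonds))) {
      used[mol$bonds$i[k]] <- used[mol$bonds$i[k]] + ord[k]
      used[mol$bonds$j[k]] <- used[mol$bonds$j[k]] + ord[k]
    }
  }
  used
}

#' Implicit hydrogens and rotatable bonds
#'
#' `fd_implicit_h`: per-atom implicit hydrogen count (default valence
#' minus bond-order sum, aromatic bonds counting 1.5, floored at zero).
#' `fd_rotatable_bonds`: acyclic single bonds between non-terminal heavy
#' atoms, excluding amide C-N bonds.
#' @param mol An `fd_molecule`.
#' @return Integer vector / count.
#' @export
fd_implicit_h <- function(mol) {
  el <- fd_elements(mol$atoms)
  used <- round(fd_used_valence(mol))
  pmax(0, fd_default_valence(el) - used)
}

#' @rdname fd_implicit_h
#' @export
fd_rotatable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(0L)
  ri <- fd_rings(mol)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = fd_n_atoms(mol$atoms))
  el <- fd_elements(mol$atoms)
  nb <- fd_neighbors(mol)
  is_amide_cn <- function(i, j) {
    # C-N single bond where the C carries a double-bonded O
    for (ord in list(c(i, j), c(j, i))) {
      a <- ord[1]; b <- ord[2]
      if (el[a] == "C" && el[b] == "N") {
        for (x in nb[[a]]) {
          hit <- mol$bonds$i == min(a, x) & mol$bonds$j == max(a, x)
          if (any(hit) && mol$bonds$class[which(hit)[1]] == "double" &&
              el[x] == "O") return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$class[k] != "single") next
    if (ri$bond_in_ring[k]) next
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (deg[i] < 2 || deg[j] < 2) next
    if (is_amide_cn(i, j)) next
    cnt <- cnt + 1L
  }
  cnt
}

# Connected components as lists of atom indices.
fd_components <- function(mol) {
  comp <- igraph::components(fd_mol_graph(mol))$membership
  split(seq_along(comp), comp)
}

# ---- Circular (Morgan-style) fingerprints ---------------------------------

# Per-atom initial invariant.
fd_atom_invariant <- function(mol) {
  el <- fd_elements(mol$atoms)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = fd_n_atoms(mol$atoms))
  hs <- fd_implicit_h(mol)
  ri <- fd_rings(mol)
  paste(el, deg, hs, as.integer(ri$atom_in_ring), sep = "|")
}

# Deterministic string hash onto [0, nbits).
fd_str_hash <- function(s, nbits) {
  vapply(s, function(x) {
    h <- 5381
    for (ch in utf8ToInt(x)) h <- (h * 33 + ch) %% 2147483647
    as.integer(h %% nbits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Circular fingerprint of a molecule
#'
#' A 2048-bit circular fingerprint (radius 2) over element / degree /
#' implicit-H / ring invariants, used for Tanimoto similarity and diversity.
#'
#' @param mol An `fd_molecule`.
#' @param nbits Fingerprint length.
#' @param radius Neighborhood radius.
#' @return Logical vector of length `nbits`.
#' @export
fd_fingerprint <- function(mol, nbits = 2048L, radius = 2L) {
  n <- fd_n_atoms(mol$atoms)
  bits <- rep(FALSE, nbits)
  if (n == 0) return(bits)
  ids <- fd_atom_invariant(mol)
  nb <- fd_neighbors(mol)
  cls <- matrix("", n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    cls[mol$bonds$i[k], mol$bonds$j[k]] <- mol$bonds$class[k]
    cls[mol$bonds$j[k], mol$bonds$i[k]] <- mol$bonds$class[k]
  }
  for (r in 0:radius) {
    bits[fd_str_hash(paste0("r", r, ":", ids), nbits) + 1L] <- TRUE
    if (r == radius) break
    ids <- vapply(seq_len(n), function(i) {
      env <- sort(paste0(cls[i, nb[[i]]], "~", ids[nb[[i]]]))
      paste0(ids[i], "(", paste(env, collapse = ","), ")")
    }, character(1))
  }
  bits
}

#' Tanimoto similarity between two fingerprints
#' @param a,b Logical fingerprint vectors of equal length.
#' @return Intersection-over-union in `[0, 1]` (1 for two empty prints).
#' @export
fd_tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
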