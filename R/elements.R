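# Element vocabulary and per-element chemistry tables.
#
# The shared one-hot vocabulary covers the heavy elements seen in drug-like
# ligands; anything else is collapsed onto "other". Hydrogens are implicit
# throughout (explicit H appears only in some fixture templates).

#' Element vocabulary used by the one-hot atom typing
#'
#' Nine heavy-element categories shared by pockets, fragments and generated
#' atoms: C, N, O, F, P, S, Cl, Br and a catch-all `other`. The R-group
#' diffusion stage appends a tenth `virtual` category for padding slots.
#'
#' @return Character vector of category labels.
#' @export
fd_element_vocab <- function() {
  c("C", "N", "O", "F", "P", "S", "Cl", "Br", "other")
}

#' @rdname fd_element_vocab
#' @export
fd_virtual_label <- function() "virtual"

# Covalent radii (Angstrom), Cordero et al. consensus values.
.fd_covalent_radius <- c(
  C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, other = 1.10, H = 0.31
)

# Standard atomic weights (Da).
.fd_atomic_weight <- c(
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, P = 30.974,
  S = 32.06, Cl = 35.45, Br = 79.904, other = 0, H = 1.008
)

# Default valences used for implicit-hydrogen completion and the
# deterministic bond-perception fallback. The second row gives the hard cap
# (hypervalent states allowed for S and P).
.fd_default_valence <- c(C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                         Cl = 1, Br = 1, other = 4, H = 1)
.fd_max_valence     <- c(C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                         Cl = 1, Br = 1, other = 6, H = 1)

fd_covalent_radius <- function(el) {
  r <- .fd_covalent_radius[el]
  if (anyNA(r)) stop("unknown element(s): ", paste(el[is.na(r)], collapse = ", "))
  unname(r)
}

fd_atomic_weight <- function(el) {
  w <- .fd_atomic_weight[el]
  if (anyNA(w)) stop("unknown element(s): ", paste(el[is.na(w)], collapse = ", "))
  unname(w)
}

fd_default_valence <- function(el) unname(.fd_default_valence[el])
fd_max_valence <- function(el) unname(.fd_max_valence[el])

# Map an arbitrary element symbol onto the shared vocabulary.
fd_map_element <- function(sym) {
  sym <- sub("^([A-Za-z]).*", "\\1\\U\\2", sym, perl = TRUE)
  sym <- ifelse(nchar(sym) > 1,
                paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2))),
                toupper(sym))
  vocab <- fd_element_vocab()
  out <- ifelse(sym %in% vocab, sym, "other")
  out
}

# Typical heavy-atom bond lengths (Angstrom) by unordered element pair and
# order ("1", "2", "3", "ar"). Used by the ideal-geometry catalog and the
# residual-valence bond-order heuristic.
.fd_bond_length_table <- local({
  tab <- rbind(
    c("C", "C", "1", 1.54), c("C", "C", "2", 1.34), c("C", "C", "3", 1.20),
    c("C", "C", "ar", 1.39),
    c("C", "N", "1", 1.47), c("C", "N", "2", 1.28), c("C", "N", "3", 1.16),
    c("C", "N", "ar", 1.34),
    c("C", "O", "1", 1.43), c("C", "O", "2", 1.22),
    c("C", "F", "1", 1.35), c("C", "Cl", "1", 1.77), c("C", "Br", "1", 1.94),
    c("C", "S", "1", 1.82), c("N", "N", "1", 1.45), c("N", "N", "2", 1.25),
    c("N", "O", "1", 1.40), c("N", "O", "2", 1.21),
    c("O", "O", "1", 1.48), c("O", "S", "2", 1.43), c("O", "P", "2", 1.48),
    c("O", "P", "1", 1.57), c("C", "P", "1", 1.84), c("S", "S", "1", 2.05)
  )
  data.frame(a = tab[, 1], b = tab[, 2], order = tab[, 3],
             length = as.numeric(tab[, 4]), stringsAsFactors = FALSE)
})

# Reference length for a given pair/order; falls back to the sum of covalent
# radii when the pair is not tabulated.
fd_bond_length <- function(el_a, el_b, order = "1") {
  key <- sort(c(el_a, el_b))
  hit <- .fd_bond_length_table$a == key[1] & .fd_bond_length_table$b == key[2] &
    .fd_bond_length_table$order == order
  if (any(hit)) return(.fd_bond_length_table$length[which(hit)[1]])
  sum(fd_covalent_radius(c(el_a, el_b)))
}

# All tabulated orders for a pair, used when perceiving bond order from an
# observed distance.
fd_bond_length_candidates <- function(el_a, el_b) {
  key <- sort(c(el_a, el_b))
  hit <- .fd_bond_length_table$a == key[1] & .fd_bond_length_table$b == key[2]
  if (!any(hit)) {
    return(data.frame(order = "1",
                      length = sum(fd_covalent_radius(c(el_a, el_b)))))
  }
  .fd_bond_length_table[hit, c("order", "length")]
}
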