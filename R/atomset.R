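# Core typed containers: AtomSet, PocketContext, FragmentSeed,
# MoleculeRecord. Lightweight S3 lists with validating constructors, in the
# style of ape's "phylo" objects: plain data, strict invariants.

#' Typed 3D point set
#'
#' The basic carrier of atoms: a one-hot element matrix over the shared
#' vocabulary, Cartesian coordinates in Angstrom and a logical mask marking
#' real atoms (`FALSE` marks virtual padding slots used by the R-group
#' diffusion stage).
#'
#' @param elements Character vector of element labels (vocabulary categories),
#'   or a one-hot matrix with vocabulary columns.
#' @param coords Numeric n x 3 matrix of coordinates (Angstrom).
#' @param real_mask Logical vector; `FALSE` flags virtual padding slots.
#' @param vocab Vocabulary of element categories (columns of the one-hot).
#' @return An object of class `fd_atomset` with fields `element_onehot`,
#'   `coords`, `real_mask`.
#' @export
fd_atomset <- function(elements, coords,
                       real_mask = NULL,
                       vocab = fd_element_vocab()) {
  if (is.matrix(elements)) {
    onehot <- elements
    if (is.null(colnames(onehot))) colnames(onehot) <- vocab
    stopifnot(ncol(onehot) == length(vocab))
  } else {
    if (!all(elements %in% vocab)) {
      stop("element labels outside the vocabulary: ",
           paste(setdiff(elements, vocab), collapse = ", "))
    }
    onehot <- matrix(0L, nrow = length(elements), ncol = length(vocab),
                     dimnames = list(NULL, vocab))
    if (length(elements)) onehot[cbind(seq_along(elements),
                                       match(elements, vocab))] <- 1L
  }
  n <- nrow(onehot)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) != n) stop("coords and elements disagree on atom count")
  if (n > 0 && !all(is.finite(coords))) stop("coordinates must be finite")
  if (n > 0 && !all(rowSums(onehot) == 1)) {
    stop("each one-hot row must sum to 1")
  }
  if (is.null(real_mask)) real_mask <- rep(TRUE, n)
  stopifnot(length(real_mask) == n)
  structure(list(element_onehot = onehot, coords = coords,
                 real_mask = as.logical(real_mask)),
            class = "fd_atomset")
}

#' @export
print.fd_atomset <- function(x, ...) {
  cat("<fd_atomset> ", fd_n_atoms(x), " atoms (",
      sum(x$real_mask), " real): ",
      paste(utils::head(fd_elements(x), 12), collapse = " "),
      if (fd_n_atoms(x) > 12) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of atoms / element labels of an atom set
#' @param x An `fd_atomset`.
#' @return `fd_n_atoms`: integer count; `fd_elements`: character labels.
#' @export
fd_n_atoms <- function(x) nrow(x$element_onehot)

#' @rdname fd_n_atoms
#' @export
fd_elements <- function(x) {
  if (fd_n_atoms(x) == 0) return(character())
  colnames(x$element_onehot)[max.col(x$element_onehot)]
}

#' Subset or concatenate atom sets
#'
#' `fd_atomset_subset` keeps the given rows (and the vocabulary);
#' `fd_atomset_bind` concatenates sets sharing a vocabulary.
#' @param x An `fd_atomset`.
#' @param idx Row indices.
#' @param ... Atom sets to bind.
#' @return An `fd_atomset`.
#' @export
fd_atomset_subset <- function(x, idx) {
  fd_atomset(x$element_onehot[idx, , drop = FALSE],
             x$coords[idx, , drop = FALSE],
             x$real_mask[idx],
             vocab = colnames(x$element_onehot))
}

#' @rdname fd_atomset_subset
#' @export
fd_atomset_bind <- function(...) {
  xs <- list(...)
  fd_atomset(do.call(rbind, lapply(xs, `[[`, "element_onehot")),
             do.call(rbind, lapply(xs, `[[`, "coords")),
             unlist(lapply(xs, `[[`, "real_mask")),
             vocab = colnames(xs[[1]]$element_onehot))
}

#' Protein pocket context
#'
#' Heavy atoms of the binding-site residues, with per-atom residue labels.
#' Pockets never contain virtual atoms and must be nonempty to condition
#' generation.
#'
#' @param atoms An `fd_atomset` of pocket heavy atoms.
#' @param residue_labels Character vector, one residue identifier per atom.
#' @param source_id Free-text provenance tag.
#' @return An object of class `fd_pocket`.
#' @export
fd_pocket <- function(atoms, residue_labels, source_id = "") {
  stopifnot(inherits(atoms, "fd_atomset"),
            length(residue_labels) == fd_n_atoms(atoms))
  if (!all(atoms$real_mask)) stop("pockets cannot contain virtual atoms")
  structure(list(atoms = atoms, residue_labels = as.character(residue_labels),
                 source_id = source_id),
            class = "fd_pocket")
}

#' @export
print.fd_pocket <- function(x, ...) {
  cat("<fd_pocket> ", fd_n_atoms(x$atoms), " heavy atoms, ",
      length(unique(x$residue_labels)), " residues [", x$source_id, "]\n",
      sep = "")
  invisible(x)
}

#' Seed fragment with growth anchors
#'
#' A fragment carries its atoms, the anchor indices marking cleavage sites
#' (valid growth positions for new scaffold atoms) and, internally, the bond
#' list inherited from the parent molecule (needed for descriptor and
#' filtering computations).
#'
#' @param atoms An `fd_atomset`.
#' @param anchors Integer indices into the fragment's atoms (may be empty for
#'   fragments that are whole molecules).
#' @param bonds Bond data frame with columns `i`, `j`, `class` (indices local
#'   to the fragment).
#' @return An object of class `fd_fragment`.
#' @export
fd_fragment <- function(atoms, anchors = integer(), bonds = NULL) {
  stopifnot(inherits(atoms, "fd_atomset"))
  anchors <- as.integer(anchors)
  n <- fd_n_atoms(atoms)
  if (length(anchors) && (any(anchors < 1) || any(anchors > n))) {
    stop("anchor indices out of range")
  }
  if (is.null(bonds)) bonds <- fd_empty_bonds()
  structure(list(atoms = atoms, anchors = anchors, bonds = bonds),
            class = "fd_fragment")
}

#' @export
print.fd_fragment <- function(x, ...) {
  cat("<fd_fragment> ", fd_n_atoms(x$atoms), " atoms, anchors {",
      paste(x$anchors, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Empty bond list
#' @return Zero-row bond data frame.
#' @export
fd_empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), class = character(),
             stringsAsFactors = FALSE)
}

#' Bond list constructor
#'
#' @param i,j 1-based atom indices (`i != j`, duplicates forbidden).
#' @param class Bond classes among `single`, `double`, `aromatic`, `triple`.
#' @return A validated bond data frame.
#' @export
fd_bonds <- function(i, j, class) {
  i <- as.integer(i); j <- as.integer(j); class <- as.character(class)
  stopifnot(length(i) == length(j), length(i) == length(class))
  if (any(i == j)) stop("self-bonds are not allowed")
  ok <- class %in% c("single", "double", "aromatic", "triple")
  if (!all(ok)) stop("unknown bond class: ", paste(unique(class[!ok]), collapse = ", "))
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (anyDuplicated(paste(lo, hi))) stop("duplicate bond pairs")
  data.frame(i = lo, j = hi, class = class, stringsAsFactors = FALSE)
}

#' Assembled molecule record
#'
#' The final product of generation and bond reconstruction: atoms, a typed
#' bond list, a validity flag set by sanitization and a free-form property
#' map (emitted as SDF data fields).
#'
#' @param atoms An `fd_atomset` (real atoms only are serialized).
#' @param bonds Bond data frame from [fd_bonds()].
#' @param valid Logical; `TRUE` only if sanitization passed.
#' @param properties Named list of scalar properties.
#' @param name Molecule title.
#' @return An object of class `fd_molecule`.
#' @export
fd_molecule <- function(atoms, bonds = fd_empty_bonds(), valid = TRUE,
                        properties = list(), name = "mol") {
  stopifnot(inherits(atoms, "fd_atomset"))
  n <- fd_n_atoms(atoms)
  if (nrow(bonds) && (any(bonds$i < 1) || any(bonds$j > n))) {
    stop("bond indices out of range")
  }
  structure(list(atoms = atoms, bonds = bonds, valid = isTRUE(valid),
                 properties = properties, name = name),
            class = "fd_molecule")
}

#' @export
print.fd_molecule <- function(x, ...) {
  cat("<fd_molecule> ", x$name, ": ", fd_n_atoms(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, valid=", x$valid, "\n", sep = "")
  invisible(x)
}
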