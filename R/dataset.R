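# Training-set assembly: template slicing, BRICS seeding of scaffolds,
# Rule-of-Three filtering and a seeded train/validation/test split.

#' Assemble the (pocket, seed, scaffold, R-group) training dataset
#'
#' For every complex: slice the ligand into scaffold/R-group pairs with the
#' reaction templates, cut each scaffold with the BRICS rules into candidate
#' seed fragments, and keep seeds that pass the Rule-of-Three filter. The
#' surviving tuples are shuffled deterministically and split.
#'
#' @param complexes List of lists with fields `pocket` (`fd_pocket`) and
#'   `ligand` (`fd_molecule`); entries may carry an `id`.
#' @param templates Templates from [fd_read_templates()].
#' @param split_ratios Train/validation/test proportions (sum to 1).
#' @param seed Integer seed for the shuffle.
#' @return List with `tuples` (each: `pocket`, `seed` (`fd_fragment`),
#'   `scaffold`, `rgroup`, `complex_id`, `template_id`) and `manifest`
#'   (data frame: complex_id, template_id, seed_atoms, scaffold_atoms,
#'   rgroup_atoms, split).
#' @export
fd_build_dataset <- function(complexes, templates = fd_read_templates(),
                             split_ratios = c(train = 0.8, validation = 0.1,
                                              test = 0.1),
                             seed = 1L) {
  if (!length(complexes)) stop("no complexes supplied")
  stopifnot(abs(sum(split_ratios) - 1) < 1e-8)
  tuples <- list()
  rows <- list()
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    cid <- if (!is.null(cx$id)) cx$id else paste0("complex", ci)
    pairs <- fd_slice_scaffold_rgroups(cx$ligand, templates)
    for (p in pairs) {
      sc_mol <- .fd_extract_submol(cx$ligand, p$scaffold_idx)
      seeds <- fd_brics_decompose(sc_mol)
      descs <- fd_descriptor_table(seeds)
      for (si in seq_along(seeds)) {
        sd <- seeds[[si]]
        if (!fd_ro3_filter(sd, descriptors = descs[si, , drop = FALSE])) next
        # seeds without cleavage anchors inherit the attachment anchor
        if (!length(sd$anchors)) {
          att <- p$scaffold$anchors[1]
          loc <- match(att, attr(sd, "atom_idx"))
          if (is.na(loc)) next
          sd$anchors <- loc
        }
        tuples[[length(tuples) + 1L]] <- list(
          pocket = cx$pocket, seed = sd,
          scaffold = p$scaffold, rgroup = p$rgroup,
          complex_id = cid, template_id = p$template_id)
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = cid, template_id = p$template_id,
          seed_atoms = fd_n_atoms(sd$atoms),
          scaffold_atoms = fd_n_atoms(p$scaffold$atoms),
          rgroup_atoms = fd_n_atoms(p$rgroup$atoms),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(tuples)) {
    stop("empty dataset: every candidate seed was filtered out")
  }
  manifest <- do.call(rbind, rows)
  n <- nrow(manifest)
  perm <- fd_with_seed(seed, sample.int(n))
  n_tr <- floor(split_ratios[1] * n)
  n_va <- floor(split_ratios[2] * n)
  split <- rep("test", n)
  split[perm[seq_len(n_tr)]] <- "train"
  if (n_va > 0) split[perm[n_tr + seq_len(n_va)]] <- "validation"
  if (n_tr == 0) split[perm[1]] <- "train"  # never an empty training split
  manifest$split <- split
  list(tuples = tuples, manifest = manifest)
}

#' Write / read a dataset manifest
#' @param dataset Output of [fd_build_dataset()].
#' @param path CSV path.
#' @return Invisibly, `path` (writer); data frame (reader).
#' @export
fd_write_manifest <- function(dataset, path) {
  utils::write.csv(dataset$manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname fd_write_manifest
#' @export
fd_read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
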