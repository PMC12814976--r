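# Reaction-template slicing of molecules into scaffold / R-group pairs, and
# assembly of the training dataset.
#
# Each shipped template names one chemically feasible retro-reaction that
# cleaves exactly one acyclic single bond. The shipped file is a 10-template
# starter subset of the reaction space commonly used for library design
# (the full curated set of 37 templates is not redistributable here); the
# SMIRKS strings document the transformations, while matching is performed
# by typed predicates over the molecular graph (see the methods vignette).

#' Load reaction templates
#'
#' @param path Template TSV (id, smirks, description); defaults to the
#'   shipped starter set.
#' @return Data frame of class `fd_templates`.
#' @export
fd_read_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reaction_templates.tsv",
                        package = "fragdiff")
    if (path == "") path <- file.path("inst", "extdata",
                                      "reaction_templates.tsv")
  }
  tpl <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "smirks", "description") %in% names(tpl)))
  bad <- !grepl(">>", tpl$smirks, fixed = TRUE)
  if (any(bad)) stop("template(s) without a reaction arrow: ",
                     paste(tpl$id[bad], collapse = ", "))
  known <- tpl$id %in% names(.fd_template_matchers())
  if (!all(known)) stop("no matcher registered for template(s): ",
                        paste(tpl$id[!known], collapse = ", "))
  class(tpl) <- c("fd_templates", "data.frame")
  tpl
}

# Bond-level matchers, one per template id. Each receives the atom context
# and a candidate acyclic single bond (i, j) and reports whether the
# template cleaves it.
.fd_template_matchers <- function() {
  is_acyl <- function(ctx, a) {
    ctx$el[a] == "C" &&
      any(ctx$el[ctx$nb[[a]]] == "O" &
            ctx$cls[a, ctx$nb[[a]]] == "double")
  }
  sp3c <- function(ctx, a) {
    ctx$el[a] == "C" && !ctx$aromatic[a] &&
      !any(ctx$cls[a, ctx$nb[[a]]] %in% c("double", "triple"))
  }
  plain_n <- function(ctx, a) {
    ctx$el[a] == "N" && !ctx$aromatic[a] &&
      !any(ctx$cls[a, ctx$nb[[a]]] %in% c("double", "triple"))
  }
  sulfonyl <- function(ctx, a) {
    ctx$el[a] == "S" &&
      sum(ctx$el[ctx$nb[[a]]] == "O" &
            ctx$cls[a, ctx$nb[[a]]] == "double") == 2
  }
  list(
    amide = function(ctx, i, j) {
      (is_acyl(ctx, i) && plain_n(ctx, j)) ||
        (is_acyl(ctx, j) && plain_n(ctx, i))
    },
    ester = function(ctx, i, j) {
      et <- function(a, b) is_acyl(ctx, a) && ctx$el[b] == "O" &&
        ctx$deg[b] == 2
      et(i, j) || et(j, i)
    },
    alkyl_ether = function(ctx, i, j) {
      et <- function(a, b) {
        sp3c(ctx, a) && !is_acyl(ctx, a) && ctx$el[b] == "O" &&
          ctx$deg[b] == 2 &&
          all(ctx$el[ctx$nb[[b]]] == "C") &&
          !any(vapply(ctx$nb[[b]], function(x) is_acyl(ctx, x), logical(1)))
      }
      et(i, j) || et(j, i)
    },
    aryl_ether = function(ctx, i, j) {
      et <- function(a, b) ctx$aromatic[a] && ctx$el[a] == "C" &&
        ctx$el[b] == "O" && ctx$deg[b] == 2
      et(i, j) || et(j, i)
    },
    sulfonamide = function(ctx, i, j) {
      (sulfonyl(ctx, i) && plain_n(ctx, j)) ||
        (sulfonyl(ctx, j) && plain_n(ctx, i))
    },
    aryl_amine = function(ctx, i, j) {
      et <- function(a, b) ctx$aromatic[a] && ctx$el[a] == "C" &&
        plain_n(ctx, b)
      et(i, j) || et(j, i)
    },
    alkyl_amine = function(ctx, i, j) {
      et <- function(a, b) sp3c(ctx, a) && !is_acyl(ctx, a) && plain_n(ctx, b)
      et(i, j) || et(j, i)
    },
    benzylic = function(ctx, i, j) {
      et <- function(a, b) ctx$aromatic[a] && ctx$el[a] == "C" &&
        sp3c(ctx, b)
      et(i, j) || et(j, i)
    },
    thioether = function(ctx, i, j) {
      et <- function(a, b) ctx$el[a] == "C" && ctx$el[b] == "S" &&
        ctx$deg[b] == 2 &&
        !any(ctx$el[ctx$nb[[b]]] == "O" &
               ctx$cls[b, ctx$nb[[b]]] == "double")
      et(i, j) || et(j, i)
    },
    aryl_halide = function(ctx, i, j) {
      et <- function(a, b) ctx$aromatic[a] && ctx$el[a] == "C" &&
        ctx$el[b] %in% c("F", "Cl", "Br")
      et(i, j) || et(j, i)
    }
  )
}

# Canonical signature of a component, used only as the deterministic
# tie-break when both halves have equal size.
.fd_component_signature <- function(mol, idx) {
  sub <- .fd_extract_submol(mol, idx)
  paste(sort(fd_atom_invariant(sub)), collapse = ";")
}

.fd_extract_submol <- function(mol, idx) {
  idx <- sort(idx)
  b <- mol$bonds[mol$bonds$i %in% idx & mol$bonds$j %in% idx, , drop = FALSE]
  b$i <- match(b$i, idx); b$j <- match(b$j, idx)
  fd_molecule(fd_atomset_subset(mol$atoms, idx), b, name = mol$name)
}

#' Slice a molecule into scaffold / R-group pairs by reaction template
#'
#' One pair is produced per (template, matched bond). The larger component
#' is the scaffold; ties go to the component with the lexicographically
#' smaller canonical signature. Coordinates are inherited from the parent.
#'
#' @param mol A valid `fd_molecule`.
#' @param templates Templates from [fd_read_templates()].
#' @return List of pairs; each has `scaffold` / `rgroup` (each an
#'   `fd_fragment` whose single anchor is the attachment atom),
#'   `scaffold_idx` / `rgroup_idx` (parent indices), `template_id`, `source`
#'   and `bond` (the cleaved parent bond). An empty list when nothing
#'   matches.
#' @export
fd_slice_scaffold_rgroups <- function(mol, templates) {
  san <- fd_sanitize(mol)
  if (!san$valid) stop("invalid molecule: ", san$reason)
  if (!nrow(templates)) stop("no templates supplied")
  if (!nrow(mol$bonds)) return(list())
  ctx <- .fd_atom_ctx(mol)
  ri <- fd_rings(mol)
  matchers <- .fd_template_matchers()
  pairs <- list()
  for (t in seq_len(nrow(templates))) {
    fn <- matchers[[templates$id[t]]]
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$class[k] != "single" || ri$bond_in_ring[k]) next
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (!fn(ctx, i, j)) next
      keep <- seq_len(nrow(mol$bonds)) != k
      res <- fd_molecule(mol$atoms, mol$bonds[keep, , drop = FALSE])
      comps <- fd_components(res)
      stopifnot(length(comps) == 2)
      sizes <- lengths(comps)
      if (sizes[1] != sizes[2]) {
        sc <- comps[[which.max(sizes)]]; rg <- comps[[which.min(sizes)]]
      } else {
        sig <- vapply(comps, function(x) .fd_component_signature(mol, x),
                      character(1))
        sc <- comps[[order(sig)[1]]]; rg <- comps[[order(sig)[2]]]
      }
      sc <- sort(sc); rg <- sort(rg)
      mk <- function(idx, attach_atom) {
        sub <- .fd_extract_submol(mol, idx)
        fd_fragment(sub$atoms, anchors = match(attach_atom, idx),
                    bonds = sub$bonds)
      }
      sc_at <- if (i %in% sc) i else j
      rg_at <- if (i %in% rg) i else j
      pairs[[length(pairs) + 1L]] <- list(
        scaffold = mk(sc, sc_at), rgroup = mk(rg, rg_at),
        scaffold_idx = sc, rgroup_idx = rg,
        template_id = templates$id[t], source = mol$name,
        bond = c(i = i, j = j))
    }
  }
  pairs
}

#' Reassemble a sliced pair into the parent graph
#'
#' Reattaches the R-group to the scaffold at the recorded attachment atoms
#' with a single bond; used by the slicing identity invariant.
#'
#' @param pair One element of [fd_slice_scaffold_rgroups()] output.
#' @return An `fd_molecule` on the parent atom ordering.
#' @export
fd_reassemble_pair <- function(pair) {
  idx <- c(pair$scaffold_idx, pair$rgroup_idx)
  ord <- order(idx)
  atoms <- fd_atomset_bind(pair$scaffold$atoms, pair$rgroup$atoms)
  # map local indices back to parent indices
  sc_b <- pair$scaffold$bonds
  if (nrow(sc_b)) { sc_b$i <- pair$scaffold_idx[sc_b$i]
                    sc_b$j <- pair$scaffold_idx[sc_b$j] }
  rg_b <- pair$rgroup$bonds
  if (nrow(rg_b)) { rg_b$i <- pair$rgroup_idx[rg_b$i]
                    rg_b$j <- pair$rgroup_idx[rg_b$j] }
  link <- fd_bonds(pair$scaffold_idx[pair$scaffold$anchors[1]],
                   pair$rgroup_idx[pair$rgroup$anchors[1]], "single")
  bonds <- rbind(sc_b, rg_b, link)
  bonds <- fd_bonds(bonds$i, bonds$j, bonds$class)
  all_idx <- sort(idx)
  # reorder atoms to parent order
  pos <- match(all_idx, idx)
  atoms <- fd_atomset_subset(atoms, pos)
  bonds$i <- match(bonds$i, all_idx); bonds$j <- match(bonds$j, all_idx)
  fd_molecule(atoms, fd_bonds(bonds$i, bonds$j, bonds$class),
              name = pair$source)
}
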