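# The molecule-quality battery: drug-likeness panel (QED, synthetic
# accessibility, logP, Lipinski compliance, heteroatom ratio), fingerprint
# similarity/diversity, geometric distributions and KL divergence, and
# joint-threshold counting.

# ---- QED ------------------------------------------------------------------

# Published asymmetric double-sigmoid desirability parameters, one set per
# descriptor, and the standard per-descriptor weights.
.fd_qed_ads <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764,
             D = 2.419764353, E = 49.22325677, F = 65.37051707,
             DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431,
             D = 4.581497897, E = 0.822739154, F = 0.576295591,
             DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657,
             D = 4.435986202, E = 0.290141953, F = 1.300669958,
             DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388,
             D = 0.000000001, E = 0.713820843, F = 0.920922555,
             DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554,
             D = 87.83366614, E = 12.01999824, F = 28.51324732,
             DMAX = 104.5686167),
  ROTB   = c(A = 0.010000000, B = 272.4121427, C = 2.558379970,
             D = 1.565547684, E = 1.271567166, F = 2.758063707,
             DMAX = 105.4420403),
  AROM   = c(A = 3.217788970, B = 957.7374108, C = 2.274627939,
             D = 0.000000001, E = 1.317690384, F = 0.375760881,
             DMAX = 312.3372610),
  ALERTS = c(A = 0.010000000, B = 1199.094025, C = -0.09002883,
             D = 0.000000001, E = 0.185904477, F = 0.875193782,
             DMAX = 417.7253140))

.fd_qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                     PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.fd_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p["C"] + p["D"] / 2) / p["E"])
  e2 <- 1 + exp(-(x - p["C"] - p["D"] / 2) / p["F"])
  unname((p["A"] + p["B"] / e1 * (1 - 1 / e2)) / p["DMAX"])
}

# Structural-alert count: a compact set of reactive / unstable motifs
# matched procedurally on the heavy-atom graph (aldehyde, acyl halide,
# sp3-carbon halide, nitro, N-N / azo, O-O peroxide, Michael acceptor,
# thiol, N-halogen). A reduced surrogate for the full published alert list.
fd_count_alerts <- function(mol) {
  el <- fd_elements(mol$atoms)
  nb <- fd_neighbors(mol)
  cls <- function(a, b) {
    hit <- mol$bonds$i == min(a, b) & mol$bonds$j == max(a, b)
    if (any(hit)) mol$bonds$class[which(hit)[1]] else NA_character_
  }
  hs <- fd_implicit_h(mol)
  hal <- c("F", "Cl", "Br")
  alerts <- 0L
  has_dbl_o <- function(a) any(el[nb[[a]]] == "O" &
                                 vapply(nb[[a]], function(x)
                                   identical(cls(a, x), "double"), logical(1)))
  # aldehyde: carbonyl C with an implicit H
  if (any(vapply(seq_along(el), function(a) {
    el[a] == "C" && has_dbl_o(a) && hs[a] > 0
  }, logical(1)))) alerts <- alerts + 1L
  # acyl halide
  if (any(vapply(seq_along(el), function(a) {
    el[a] == "C" && has_dbl_o(a) && any(el[nb[[a]]] %in% hal)
  }, logical(1)))) alerts <- alerts + 1L
  # sp3 C-halide (alkyl halide)
  arom <- vapply(seq_along(el), function(a) {
    any(vapply(nb[[a]], function(x) identical(cls(a, x), "aromatic"),
               logical(1)))
  }, logical(1))
  if (any(vapply(seq_along(el), function(a) {
    el[a] == "C" && !arom[a] && !has_dbl_o(a) && any(el[nb[[a]]] %in% hal)
  }, logical(1)))) alerts <- alerts + 1L
  # nitro-like: N with two O neighbors
  if (any(vapply(seq_along(el), function(a) {
    el[a] == "N" && sum(el[nb[[a]]] == "O") >= 2
  }, logical(1)))) alerts <- alerts + 1L
  # N-N / azo
  if (any(el[mol$bonds$i] == "N" & el[mol$bonds$j] == "N")) {
    alerts <- alerts + 1L
  }
  # O-O peroxide
  if (any(el[mol$bonds$i] == "O" & el[mol$bonds$j] == "O")) {
    alerts <- alerts + 1L
  }
  # thiol: terminal S-H
  if (any(el == "S" & lengths(nb) == 1 & hs > 0)) alerts <- alerts + 1L
  # N-halogen
  if (any((el[mol$bonds$i] == "N" & el[mol$bonds$j] %in% hal) |
            (el[mol$bonds$j] == "N" & el[mol$bonds$i] %in% hal))) {
    alerts <- alerts + 1L
  }
  alerts
}

# ---- Synthetic accessibility ----------------------------------------------

# Synthesis-complexity estimate on a 1 (easy) .. 10 (hard) raw scale,
# normalized to [0, 1] via (10 - raw) / 9 so higher means easier. Penalties:
# molecule size, ring fusion/spiro centers, macrocycles, heteroelement
# diversity, rotatable-chain flexibility.
fd_sa_score <- function(mol) {
  n <- sum(mol$atoms$real_mask)
  ri <- fd_rings(mol)
  ring_count_per_atom <- integer(fd_n_atoms(mol$atoms))
  for (r in ri$rings) {
    ring_count_per_atom[r] <- ring_count_per_atom[r] + 1L
  }
  fused_atoms <- sum(ring_count_per_atom >= 2)
  macro <- sum(lengths(ri$rings) > 8)
  el <- fd_elements(mol$atoms)
  hetero_kinds <- length(setdiff(unique(el), c("C", "H")))
  size_pen <- n^1.005 - n
  ring_pen <- log2(fused_atoms + 1) + macro * log2(9)
  het_pen <- max(0, hetero_kinds - 2) * 0.25
  flex_pen <- 0.15 * fd_rotatable_bonds(mol)
  raw <- min(10, max(1, 1 + size_pen + ring_pen + het_pen + flex_pen))
  list(raw = raw, norm = (10 - raw) / 9)
}

# ---- Panel ----------------------------------------------------------------

#' Heteroatom ratio (R value)
#'
#' Fraction of heavy atoms that are not carbon; drug-like molecules
#' typically fall in 0.05-0.50.
#'
#' @param mol An `fd_molecule` with at least one heavy atom.
#' @return Ratio in `[0, 1]`.
#' @export
fd_r_value <- function(mol) {
  el <- fd_elements(mol$atoms)[mol$atoms$real_mask]
  el <- el[el != "H"]
  if (!length(el)) stop("no heavy atoms")
  sum(el != "C") / length(el)
}

#' Drug-likeness property panel
#'
#' QED by the published desirability-product formulation (geometric mean of
#' weighted desirabilities over MW, logP, HBA, HBD, TPSA, rotatable bonds,
#' aromatic rings and structural alerts); synthetic accessibility
#' normalized to `[0, 1]` (higher = easier); Lipinski compliance as the
#' number of Rule-of-Five criteria met (MW <= 500, logP <= 5, HBD <= 5,
#' HBA <= 10, plus rotatable bonds <= 10).
#'
#' @param mol A valid `fd_molecule`.
#' @param descriptors Optional precomputed [fd_compute_descriptors()] row.
#' @return One-row data frame: `qed`, `sa_norm`, `logp`, `lipinski`, `mw`,
#'   `tpsa`, `r_value`, `n_heavy`, `n_total`, `n_rings`.
#' @export
fd_property_panel <- function(mol, descriptors = NULL) {
  san <- fd_sanitize(mol)
  if (!san$valid) stop("invalid molecule: ", san$reason)
  d <- if (is.null(descriptors)) fd_compute_descriptors(mol) else descriptors
  arom <- fd_n_aromatic_rings(mol)
  alerts <- fd_count_alerts(mol)
  vals <- c(MW = d$mw, ALOGP = d$logp, HBA = d$hba, HBD = d$hbd,
            PSA = d$tpsa, ROTB = d$rot_bonds, AROM = arom, ALERTS = alerts)
  dvals <- vapply(names(vals), function(k) {
    max(.fd_ads(vals[[k]], .fd_qed_ads[[k]]), 1e-6)
  }, numeric(1))
  w <- .fd_qed_weights
  qed <- exp(sum(w * log(dvals)) / sum(w))
  sa <- fd_sa_score(mol)
  lip <- sum(d$mw <= 500, d$logp <= 5, d$hbd <= 5, d$hba <= 10,
             d$rot_bonds <= 10)
  hs <- fd_implicit_h(mol)
  el <- fd_elements(mol$atoms)
  n_heavy <- sum(el != "H")
  data.frame(qed = qed, sa_norm = sa$norm, logp = d$logp,
             lipinski = lip, mw = d$mw, tpsa = d$tpsa,
             r_value = fd_r_value(mol),
             n_heavy = n_heavy,
             n_total = length(el) + sum(hs[el != "H"]),
             n_rings = fd_n_rings(mol))
}

#' @rdname fd_property_panel
#' @param mols List of valid molecules (batched descriptor computation).
#' @export
fd_property_panels <- function(mols) {
  descs <- fd_descriptor_table(mols)
  do.call(rbind, lapply(seq_along(mols), function(k) {
    fd_property_panel(mols[[k]], descriptors = descs[k, , drop = FALSE])
  }))
}

# ---- Similarity / diversity ----------------------------------------------

#' Structural diversity of a molecule set
#'
#' `1 - mean` pairwise Tanimoto similarity over circular fingerprints. A
#' singleton set has diversity 0 (with a warning).
#'
#' @param mols List of `fd_molecule`.
#' @return Scalar in `[0, 1]`.
#' @export
fd_diversity <- function(mols) {
  if (length(mols) < 2) {
    warning("diversity of fewer than 2 molecules is defined as 0")
    return(0)
  }
  fps <- lapply(mols, fd_fingerprint)
  sims <- c()
  for (a in seq_len(length(fps) - 1)) {
    for (b in seq(a + 1, length(fps))) {
      sims <- c(sims, fd_tanimoto(fps[[a]], fps[[b]]))
    }
  }
  1 - mean(sims)
}

#' Similarity to a reference set
#'
#' Mean over molecules of the maximum Tanimoto similarity against the
#' reference set (e.g. the training ligands); low values indicate novelty.
#'
#' @param mols List of generated molecules.
#' @param ref_set Nonempty list of reference molecules.
#' @return Scalar in `[0, 1]`.
#' @export
fd_similarity_to_ref <- function(mols, ref_set) {
  if (!length(ref_set)) stop("empty reference set")
  ref_fps <- lapply(ref_set, fd_fingerprint)
  mean(vapply(mols, function(m) {
    fp <- fd_fingerprint(m)
    max(vapply(ref_fps, function(r) fd_tanimoto(fp, r), numeric(1)))
  }, numeric(1)))
}

# ---- Geometric distributions ----------------------------------------------

.fd_parse_geom_key <- function(key) {
  parts <- strsplit(key, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:4) {
    stop("geometry key must have 2 (bond), 3 (angle) or 4 (dihedral) ",
         "elements: ", key)
  }
  parts
}

# Enumerate simple bonded paths of length `len` (atom count), undirected
# deduplicated (a path and its reversal count once).
.fd_bonded_paths <- function(mol, len) {
  nb <- fd_neighbors(mol)
  n <- fd_n_atoms(mol$atoms)
  out <- list()
  walk <- function(path) {
    if (length(path) == len) {
      if (path[1] < path[len]) out[[length(out) + 1L]] <<- path
      return()
    }
    last <- path[length(path)]
    for (x in nb[[last]]) {
      if (!(x %in% path)) walk(c(path, x))
    }
  }
  for (s in seq_len(n)) walk(s)
  out
}

#' Geometric feature distributions
#'
#' For each key pattern (element sequence such as `"C-O"`, `"C-O-C"`,
#' `"C-C-C-C"`), enumerates matching bonded paths across the molecules
#' (undirected, deduplicated), measures bond lengths (Angstrom), bond
#' angles or dihedral angles (radians), and returns a normalized histogram
#' on shared bin edges (lengths on `[0.5, 3]`, angles on `[0, pi]`,
#' dihedrals on `[-pi, pi]`, 64 bins).
#'
#' @param mols Nonempty list of `fd_molecule`.
#' @param keys Character vector of patterns.
#' @param n_bins Number of uniform bins.
#' @return List of `fd_geom_hist` objects (`key`, `kind`, `breaks`,
#'   `density`, `n_obs`).
#' @export
fd_geometry_distributions <- function(mols, keys, n_bins = 64L) {
  if (!length(mols)) stop("no molecules")
  lapply(keys, function(key) {
    pat <- .fd_parse_geom_key(key)
    len <- length(pat)
    vals <- c()
    for (mol in mols) {
      el <- fd_elements(mol$atoms)
      for (p in .fd_bonded_paths(mol, len)) {
        seq_el <- el[p]
        if (!(identical(seq_el, pat) || identical(rev(seq_el), pat))) next
        xyz <- mol$atoms$coords
        v <- switch(as.character(len),
                    "2" = sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)),
                    "3" = fd_angle(xyz[p[1], ], xyz[p[2], ], xyz[p[3], ]),
                    "4" = fd_dihedral(xyz[p[1], ], xyz[p[2], ],
                                      xyz[p[3], ], xyz[p[4], ]))
        vals <- c(vals, v)
      }
    }
    rng <- switch(as.character(len),
                  "2" = c(0.5, 3), "3" = c(0, pi), "4" = c(-pi, pi))
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    if (!length(vals)) {
      warning("key '", key, "' matched no paths")
      dens <- rep(0, n_bins)
    } else {
      vals <- pmin(pmax(vals, rng[1]), rng[2])
      cnt <- graphics::hist(vals, breaks = breaks, plot = FALSE)$counts
      dens <- cnt / sum(cnt)
    }
    structure(list(key = key,
                   kind = c("2" = "bond", "3" = "angle",
                            "4" = "dihedral")[[as.character(len)]],
                   breaks = breaks, density = dens,
                   n_obs = length(vals)),
              class = "fd_geom_hist")
  })
}

#' Kullback-Leibler divergence between two geometry histograms
#'
#' `sum p_i log(p_i / q_i)` with `q` floored at 1e-10 before the logarithm;
#' terms with `p_i = 0` contribute 0. Requires identical bin edges.
#'
#' @param p,q `fd_geom_hist` objects on the same bins.
#' @return Nonnegative scalar.
#' @export
fd_kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "fd_geom_hist"), inherits(q, "fd_geom_hist"))
  if (!isTRUE(all.equal(p$breaks, q$breaks))) {
    stop("histograms have different bin edges")
  }
  qd <- pmax(q$density, 1e-10)
  terms <- ifelse(p$density > 0, p$density * log(p$density / qd), 0)
  sum(terms)
}

#' Count molecules jointly satisfying SA and QED thresholds
#'
#' @param panels Data frame from [fd_property_panels()].
#' @param sa_min,qed_min Thresholds.
#' @return Integer count of rows with `sa_norm >= sa_min` and
#'   `qed >= qed_min`.
#' @export
fd_threshold_joint_count <- function(panels, sa_min, qed_min) {
  if (!nrow(panels)) stop("empty panel set")
  sum(panels$sa_norm >= sa_min & panels$qed >= qed_min)
}
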