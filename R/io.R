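# Standard-format I/O: protein pockets from PDB (bio3d), ligands from
# SDF V2000 (ChemmineR reader; the writer is in-package because coordinates
# must be emitted at full 4-decimal precision).

#' Read a protein pocket from a PDB file
#'
#' Selects the heavy atoms of all residues having at least one atom within
#' `radius` of the ligand's heavy atoms; with no ligand, all heavy atoms are
#' kept. Element symbols are mapped onto the shared vocabulary (unknown
#' elements become `other`).
#'
#' @param path PDB file.
#' @param ligand Optional `fd_molecule` defining the binding site.
#' @param radius Inclusion radius in Angstrom (residue-level).
#' @return An [fd_pocket()].
#' @export
fd_read_pocket <- function(path, ligand = NULL, radius = 10) {
  if (radius <= 0) stop("radius must be positive")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse PDB file '", path, "': ",
                         conditionMessage(e))
                  })
  at <- pdb$atom
  sym <- at$elesy
  blank <- is.na(sym) | sym == ""
  if (any(blank)) sym[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  heavy <- toupper(trimws(sym)) != "H"
  at <- at[heavy, , drop = FALSE]
  sym <- sym[heavy]
  if (!nrow(at)) stop("empty pocket: no heavy atoms in '", path, "'")
  res_id <- paste(at$chain, at$resno, at$resid, sep = ":")
  if (!is.null(ligand)) {
    lig_xyz <- ligand$atoms$coords[ligand$atoms$real_mask, , drop = FALSE]
    xyz <- cbind(at$x, at$y, at$z)
    d2 <- apply(xyz, 1, function(p) {
      min(colSums((t(lig_xyz) - p)^2))
    })
    keep_res <- unique(res_id[d2 <= radius^2])
    sel <- res_id %in% keep_res
    if (!any(sel)) stop("empty pocket: no residue within ", radius,
                        " A of the ligand")
    at <- at[sel, , drop = FALSE]; sym <- sym[sel]; res_id <- res_id[sel]
  }
  atoms <- fd_atomset(fd_map_element(sym), cbind(at$x, at$y, at$z))
  fd_pocket(atoms, residue_labels = res_id, source_id = basename(path))
}

#' Write a pocket to PDB
#'
#' @param pocket An [fd_pocket()].
#' @param path Output PDB file.
#' @return Invisibly, `path`.
#' @export
fd_write_pocket <- function(pocket, path) {
  el <- fd_elements(pocket$atoms)
  n <- fd_n_atoms(pocket$atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(pocket$atoms$coords)),
                   resno = match(pocket$residue_labels,
                                 unique(pocket$residue_labels)),
                   resid = rep("UNK", n),
                   elety = el, elesy = el, chain = rep("A", n))
  invisible(path)
}

# ---- SDF ------------------------------------------------------------------

.fd_sdf_class_from_type <- c(`1` = "single", `2` = "double", `3` = "triple",
                             `4` = "aromatic")
.fd_sdf_type_from_class <- c(single = 1L, double = 2L, triple = 3L,
                             aromatic = 4L)

#' Read ligands from a (possibly multi-record) SDF file
#'
#' Coordinates and bond blocks are preserved. Records that fail parsing or
#' sanitization are returned with `valid = FALSE` (with the failure reason
#' under `properties$invalid_reason`), never dropped.
#'
#' @param path SDF v2000 file.
#' @return List of `fd_molecule` records.
#' @export
fd_read_ligands <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (!length(ends)) ends <- length(txt)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- Map(function(s, e) txt[s:e], starts, ends)
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  if (!length(recs)) stop("no SDF records in '", path, "'")
  lapply(seq_along(recs), function(k) .fd_parse_sdf_record(recs[[k]], k))
}

.fd_parse_sdf_record <- function(lines, k) {
  name <- if (length(lines)) trimws(lines[1]) else ""
  if (name == "") name <- paste0("mol", k)
  bad <- function(reason) {
    fd_molecule(fd_atomset(character(), matrix(0, 0, 3)), valid = FALSE,
                properties = list(invalid_reason = reason), name = name)
  }
  counts_line <- if (length(lines) >= 4) lines[4] else ""
  n_at <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
  if (!is.na(n_at) && !is.na(n_bd) && n_bd == 0) {
    # bond-less records (single atoms, bare point clouds) are valid V2000
    # but the ChemmineR reader cannot represent them; parse directly
    return(.fd_parse_sdf_bondless(lines, n_at, name))
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(c(lines, if (!any(grepl("^\\$\\$\\$\\$", lines))) "$$$$"), tf)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                  error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0) return(bad("unparseable record"))
  ab <- tryCatch(ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
  bb <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  # single-row blocks drop to vectors
  if (!is.null(ab) && is.null(dim(ab))) ab <- t(as.matrix(ab))
  if (!is.null(bb) && is.null(dim(bb))) bb <- t(as.matrix(bb))
  if (is.null(ab) || nrow(ab) == 0) return(bad("empty atom block"))
  counts <- suppressWarnings(
    as.integer(substring(lines[4], c(1, 4), c(3, 6))))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  els <- fd_map_element(sub("_.*$", "", rownames(ab)))
  raw_el <- sub("_.*$", "", rownames(ab))
  heavy <- toupper(raw_el) != "H"
  bonds <- fd_empty_bonds()
  if (!is.null(bb) && nrow(bb) > 0) {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2])
    bt <- as.character(as.integer(bb[, 3]))
    if (anyNA(bi) || anyNA(bj) || any(bi < 1) || any(bj < 1) ||
        any(bi > nrow(ab)) || any(bj > nrow(ab)) || any(bi == bj) ||
        !all(bt %in% names(.fd_sdf_class_from_type))) {
      return(bad("corrupt bond block"))
    }
    bonds <- tryCatch(
      fd_bonds(bi, bj, unname(.fd_sdf_class_from_type[bt])),
      error = function(e) NULL)
    if (is.null(bonds)) return(bad("corrupt bond block"))
  }
  if (!is.na(counts[2]) && nrow(bonds) != counts[2]) {
    return(bad("corrupt bond block"))
  }
  # keep heavy atoms; remap bonds (H bonds dropped with their atoms)
  idx <- which(heavy)
  bonds <- bonds[bonds$i %in% idx & bonds$j %in% idx, , drop = FALSE]
  bonds$i <- match(bonds$i, idx); bonds$j <- match(bonds$j, idx)
  props <- as.list(ChemmineR::datablock(sdf[[1]]))
  mol <- fd_molecule(fd_atomset(els[idx], coords[idx, , drop = FALSE]),
                     bonds, properties = props, name = name)
  san <- fd_sanitize(mol)
  mol$valid <- san$valid
  if (!san$valid) mol$properties$invalid_reason <- san$reason
  mol
}

.fd_parse_sdf_bondless <- function(lines, n_at, name) {
  bad <- function(reason) {
    fd_molecule(fd_atomset(character(), matrix(0, 0, 3)), valid = FALSE,
                properties = list(invalid_reason = reason), name = name)
  }
  if (length(lines) < 4 + n_at) return(bad("truncated atom block"))
  at <- lines[4 + seq_len(n_at)]
  xyz <- matrix(NA_real_, n_at, 3)
  el <- character(n_at)
  for (k in seq_len(n_at)) {
    toks <- strsplit(trimws(at[k]), "\\s+")[[1]]
    if (length(toks) < 4) return(bad("malformed atom line"))
    xyz[k, ] <- suppressWarnings(as.numeric(toks[1:3]))
    el[k] <- toks[4]
  }
  if (anyNA(xyz)) return(bad("malformed atom line"))
  heavy <- toupper(el) != "H"
  props <- list()
  tags <- grep("^>\\s*<", lines)
  for (tg in tags) {
    key <- sub("^>\\s*<([^>]+)>.*$", "\\1", lines[tg])
    if (tg + 1 <= length(lines)) props[[key]] <- lines[tg + 1]
  }
  mol <- fd_molecule(fd_atomset(fd_map_element(el[heavy]),
                                xyz[heavy, , drop = FALSE]),
                     properties = props, name = name)
  san <- fd_sanitize(mol)
  mol$valid <- san$valid
  if (!san$valid) mol$properties$invalid_reason <- san$reason
  mol
}

#' Write molecule records to an SDF v2000 file
#'
#' Coordinates at 4 decimals; properties emitted as SDF data fields; virtual
#' atoms are never serialized.
#'
#' @param records Nonempty list of `fd_molecule`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
fd_write_molecules <- function(records, path) {
  if (inherits(records, "fd_molecule")) records <- list(records)
  if (!length(records)) stop("no molecule records to write")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  for (mol in records) {
    keep <- which(mol$atoms$real_mask)
    bonds <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, ,
                       drop = FALSE]
    bonds$i <- match(bonds$i, keep); bonds$j <- match(bonds$j, keep)
    el <- fd_elements(mol$atoms)[keep]
    xyz <- mol$atoms$coords[keep, , drop = FALSE]
    writeLines(c(mol$name, "  fragdiff", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         length(keep), nrow(bonds))), con)
    for (a in seq_along(keep)) {
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        xyz[a, 1], xyz[a, 2], xyz[a, 3], el[a]), con)
    }
    for (b in seq_len(nrow(bonds))) {
      writeLines(sprintf("%3d%3d%3d  0", bonds$i[b], bonds$j[b],
                         .fd_sdf_type_from_class[bonds$class[b]]), con)
    }
    writeLines("M  END", con)
    for (p in names(mol$properties)) {
      writeLines(c(sprintf(">  <%s>", p),
                   as.character(mol$properties[[p]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Sanitize a molecule record
#'
#' Checks finite coordinates, bond-index validity and per-element valence
#' caps (implicit hydrogens fill remaining valence; aromatic bonds count
#' 1.5). Never throws for chemistry failures; returns the verdict.
#'
#' @param mol An `fd_molecule`.
#' @return List with `valid` (logical) and `reason` (string or NA).
#' @export
fd_sanitize <- function(mol) {
  n <- fd_n_atoms(mol$atoms)
  if (n == 0) return(list(valid = FALSE, reason = "no atoms"))
  if (!all(is.finite(mol$atoms$coords))) {
    return(list(valid = FALSE, reason = "non-finite coordinates"))
  }
  if (nrow(mol$bonds)) {
    if (any(mol$bonds$i < 1 | mol$bonds$j > n)) {
      return(list(valid = FALSE, reason = "bond index out of range"))
    }
  }
  el <- fd_elements(mol$atoms)
  used <- round(fd_used_valence(mol))
  over <- used > fd_max_valence(el)
  if (any(over)) {
    return(list(valid = FALSE,
                reason = paste0("valence exceeded at atom ",
                                which(over)[1], " (", el[which(over)[1]],
                                ", used ", used[which(over)[1]], ")")))
  }
  list(valid = TRUE, reason = NA_character_)
}
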