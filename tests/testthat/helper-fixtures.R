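# Shared fixtures and small utilities for the suite.

# A random proper rotation matrix.
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_atomset <- function(a, R, tvec = c(0, 0, 0)) {
  a$coords <- sweep(a$coords %*% t(R), 2, tvec, `+`)
  a
}

# The full ideal-geometry fixture panel as molecules.
fixture_panel <- function() {
  lapply(fd_catalog_names(), fd_catalog_molecule)
}

# Seeded pool of random synthetic molecules.
random_pool <- function(n, seed_offset = 0) {
  lapply(seq_len(n) + seed_offset, fd_random_molecule)
}

# A small, fast toy complex for network tests.
tiny_complex <- function(template = "ethanol", seed = 2) {
  fd_make_toy_complex(fd_toy_spec(template, 6, seed, n_pocket_atoms = 5L))
}

# Canonical sort for bond data frames so comparisons ignore row order.
sort_bonds <- function(b) {
  b <- b[order(b$i, b$j), , drop = FALSE]
  rownames(b) <- NULL
  b
}
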