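# Internal-coordinate (z-matrix) placement for the ideal-geometry fixture
# catalog, plus small vector helpers shared by the evaluator.

fd_norm <- function(v) sqrt(sum(v^2))
fd_unit <- function(v) v / fd_norm(v)
fd_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension of reference frame: place a point at distance `r` from A,
# angle `ang` (degrees) with B-A, dihedral `dih` (degrees) about B-A relative
# to C (standard NeRF construction).
fd_place_atom <- function(A, B, C, r, ang, dih) {
  ang <- ang * pi / 180; dih <- dih * pi / 180
  bc <- fd_unit(A - B)
  n <- fd_unit(fd_cross(B - C, bc))
  m <- fd_cross(n, bc)
  d <- c(-r * cos(ang), r * sin(ang) * cos(dih), r * sin(ang) * sin(dih))
  A + d[1] * bc + d[2] * m + d[3] * n
}

# Build coordinates from a z-matrix data frame with columns
# ref1, ref2, ref3 (0 where unused), r, ang, dih.
fd_zmatrix_coords <- function(zm) {
  n <- nrow(zm)
  xyz <- matrix(0, n, 3)
  if (n >= 2) xyz[2, ] <- c(zm$r[2], 0, 0)
  if (n >= 3) {
    a <- zm$ang[3] * pi / 180
    u <- fd_unit(xyz[zm$ref2[3], ] - xyz[zm$ref1[3], ])
    perp <- c(-u[2], u[1], 0)
    xyz[3, ] <- xyz[zm$ref1[3], ] + zm$r[3] * (cos(a) * u + sin(a) * perp)
  }
  if (n >= 4) {
    for (k in 4:n) {
      xyz[k, ] <- fd_place_atom(xyz[zm$ref1[k], ], xyz[zm$ref2[k], ],
                                xyz[zm$ref3[k], ], zm$r[k], zm$ang[k],
                                zm$dih[k])
    }
  }
  xyz
}

#' Bond angle and dihedral measurement
#'
#' `fd_angle` returns the angle at `b` (radians) for points a-b-c;
#' `fd_dihedral` the signed torsion a-b-c-d in `(-pi, pi]`.
#' @param a,b,c,d Length-3 coordinate vectors.
#' @return Radians.
#' @export
fd_angle <- function(a, b, c) {
  u <- fd_unit(a - b); v <- fd_unit(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

#' @rdname fd_angle
#' @export
fd_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- fd_cross(b1, b2); n2 <- fd_cross(b2, b3)
  m1 <- fd_cross(n1, fd_unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Pairwise distance matrix for an n x 3 coordinate matrix.
fd_dist_matrix <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' Evaluate code under a temporary RNG state
#'
#' Seeds the generator, runs the expression, and restores the caller's RNG
#' state; every stochastic component of the package routes its draws
#' through this, which is what makes fixtures pure functions of their
#' specs.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The expression's value.
#' @export
fd_with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
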