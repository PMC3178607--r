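# Shrake-Rupley solvent-accessible surface area on a deterministic
# Fibonacci sphere lattice.  Heavy atoms only: hydrogens carry no surface
# in this parameterisation (their area is subsumed by the heavy-atom radii).

#' Per-atom solvent-accessible surface area
#'
#' Numerical SASA with a rolling probe: each heavy atom is sampled on a
#' quasi-uniform sphere of radius r_i + probe and a sample point counts as
#' accessible when it lies outside every neighbour's probe-extended sphere.
#' The point set is a fixed Fibonacci lattice, so results are deterministic.
#'
#' @param atoms data frame with columns x, y, z, radius, element
#' @param probe probe radius in Angstrom (water = 1.4)
#' @param n_points sphere sample points per atom; the area quantum per
#'   atom is 4*pi*(r+probe)^2 / n_points (about 0.05 A^2 at the default)
#' @return numeric vector of areas (A^2) for the heavy atoms, 0 for hydrogens
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  n <- nrow(atoms)
  area <- numeric(n)
  heavy <- which(atoms$element != "H")
  if (!length(heavy)) return(area)
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  rad <- atoms$radius[heavy] + probe
  pts <- fibonacci_sphere(n_points)
  maxr <- max(rad)
  for (k in seq_along(heavy)) {
    d2 <- (xyz[, 1] - xyz[k, 1])^2 + (xyz[, 2] - xyz[k, 2])^2 + (xyz[, 3] - xyz[k, 3])^2
    nb <- which(d2 < (rad[k] + maxr)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < rad[k] + rad[nb]]
    if (!length(nb)) {
      area[heavy[k]] <- 4 * pi * rad[k]^2
      next
    }
    sp <- pts * rad[k]
    sp <- sweep(sp, 2, xyz[k, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 + (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rad[j]^2
      if (!any(free)) break
    }
    area[heavy[k]] <- 4 * pi * rad[k]^2 * sum(free) / n_points
  }
  area
}

#' Analytic SASA of two intersecting spheres (cap formula)
#'
#' Closed-form accessible area of two probe-extended spheres of radii
#' R1, R2 (already including the probe) at centre distance d: each sphere
#' loses the spherical cap cut off by the radical plane.  Used as the
#' independent oracle for the numerical engine.
#'
#' @param R1,R2 extended radii (A); @param d centre distance (A)
#' @return numeric length-2: accessible area of each sphere (A^2)
#' @export
two_sphere_sasa <- function(R1, R2, d) {
  full <- 4 * pi * c(R1, R2)^2
  if (d >= R1 + R2) return(full)
  if (d + min(R1, R2) <= max(R1, R2)) {
    # one sphere engulfed
    if (R1 < R2) return(c(0, full[2])) else return(c(full[1], 0))
  }
  # cap heights from the radical plane
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(full[1] - 2 * pi * R1 * h1, full[2] - 2 * pi * R2 * h2)
}
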