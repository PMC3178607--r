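# The five semi-empirical interaction terms (HB, LIPO, BP, ROT, DESOLV)
# computed from a prepared peptide-MHC complex.  Pairwise terms use the
# ChemScore-family block (ramp) kernel; only intermolecular MHC<->peptide
# contacts count.

#' Default term parameters
#'
#' ChemScore-family defaults: ideal hydrogen bond H..A distance 1.85 A with
#' ramp 0.25-0.65 A, ideal D-H..A angle 180 deg with ramp 30-80 deg;
#' lipophilic/mismatch kernel from R1 = r_i + r_j + 0.5 A to R1 + 3.0 A;
#' water probe 1.4 A.  `bp_polar_classes` selects which classes count as
#' polar in the mismatch term.
#'
#' @param ... overrides of the listed defaults
#' @return named list of parameters
#' @export
term_params <- function(...) {
  p <- list(
    hb_d_ideal = 1.85, hb_d1 = 0.25, hb_d2 = 0.65,
    hb_a1 = 30, hb_a2 = 80,
    hb_heavy_mode = FALSE, hb_dda_ideal = 2.85,
    lipo_r1_offset = 0.5, lipo_width = 3.0,
    bp_polar_classes = c("donor", "acceptor", "donor_acceptor"),
    probe = 1.4, sasa_points = 960,
    pair_cutoff = 8.0
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown term parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  p
}

#' Block (ramp) weighting function
#'
#' The piecewise-linear kernel of the ChemScore family: 1 for `x <= x1`,
#' a linear ramp down to 0 between `x1` and `x2`, 0 beyond `x2`.
#'
#' @param x value(s) to weight
#' @param x1 inner bound (full weight); vectorised alongside `x`
#' @param x2 outer bound (zero weight); must exceed `x1` elementwise
#' @return weights in `[0, 1]`, vectorised over `x`
#' @examples
#' block_ramp(c(0.1, 0.45, 0.7), 0.25, 0.65)
#' @export
block_ramp <- function(x, x1, x2) {
  if (any(x1 >= x2)) stop("block_ramp: x1 must be < x2")
  w <- (x2 - x) / (x2 - x1)
  pmin(1, pmax(0, w))
}

.check_typed <- function(c) {
  if (any(is.na(c$atoms$class))) {
    stop("atoms are not typed; run prepare_complex() first")
  }
}

#' Hydrogen-bond term
#'
#' Sum over intermolecular donor-H...acceptor triples of
#' `block(|d_HA - 1.85|; 0.25, 0.65) * block(|theta_DHA - 180|; 30, 80)`.
#' Donors are typed `donor`/`donor_acceptor` heavy atoms with an attached
#' hydrogen; acceptors are typed `acceptor`/`donor_acceptor`.  Only pairs
#' with donor and acceptor on opposite sides of the interface contribute.
#' With `hb_heavy_mode` the geometry falls back to the heavy-atom D...A
#' distance (ideal 2.85 A) and D-H geometry is not required.
#'
#' @param c prepared `complex_structure`
#' @param params list from [term_params()]
#' @return non-negative dimensionless sum
#' @export
hb_term <- function(c, params = term_params()) {
  .check_typed(c)
  at <- c$atoms
  donor_cls <- c("donor", "donor_acceptor")
  acc_cls <- c("acceptor", "donor_acceptor")
  acc <- which(at$class %in% acc_cls & at$element != "H")
  if (params$hb_heavy_mode) {
    don <- which(at$class %in% donor_cls & at$element != "H")
    total <- 0
    for (i in don) {
      j <- acc[at$role[acc] != at$role[i]]
      if (!length(j)) next
      d <- sqrt((at$x[j] - at$x[i])^2 + (at$y[j] - at$y[i])^2 + (at$z[j] - at$z[i])^2)
      total <- total + sum(block_ramp(abs(d - params$hb_dda_ideal),
                                      params$hb_d1, params$hb_d2))
    }
    return(total)
  }
  hp <- hydrogen_parents(at)
  hidx <- as.integer(names(hp))
  keep <- !is.na(hp) & at$class[hp] %in% donor_cls
  hidx <- hidx[keep]; hpar <- hp[keep]
  total <- 0
  for (k in seq_along(hidx)) {
    h <- hidx[k]; d_at <- hpar[k]
    j <- acc[at$role[acc] != at$role[d_at]]
    if (!length(j)) next
    hxyz <- c(at$x[h], at$y[h], at$z[h])
    dxyz <- c(at$x[d_at], at$y[d_at], at$z[d_at])
    dha <- sqrt((at$x[j] - hxyz[1])^2 + (at$y[j] - hxyz[2])^2 + (at$z[j] - hxyz[3])^2)
    near <- which(dha < params$hb_d_ideal + params$hb_d2 + 0.01)
    for (m in near) {
      a <- j[m]
      theta <- bond_angle(dxyz, hxyz, c(at$x[a], at$y[a], at$z[a]))
      total <- total + block_ramp(abs(dha[m] - params$hb_d_ideal), params$hb_d1, params$hb_d2) *
        block_ramp(abs(theta - 180), params$hb_a1, params$hb_a2)
    }
  }
  total
}

# intermolecular pair sum of block(d; r_i+r_j+off, +width) over given classes
.pair_kernel_sum <- function(at, cls_mhc, cls_pep, params) {
  i <- which(at$role == "mhc" & at$class %in% cls_mhc)
  j <- which(at$role == "peptide" & at$class %in% cls_pep)
  if (!length(i) || !length(j)) return(0)
  xi <- as.matrix(at[i, c("x", "y", "z")]); ri <- at$radius[i]
  xj <- as.matrix(at[j, c("x", "y", "z")]); rj <- at$radius[j]
  total <- 0
  for (k in seq_along(i)) {
    d <- sqrt((xj[, 1] - xi[k, 1])^2 + (xj[, 2] - xi[k, 2])^2 + (xj[, 3] - xi[k, 3])^2)
    r1 <- ri[k] + rj + params$lipo_r1_offset
    sel <- d < r1 + params$lipo_width
    if (any(sel)) {
      total <- total + sum(block_ramp(d[sel], r1[sel], r1[sel] + params$lipo_width))
    }
  }
  total
}

#' Lipophilic contact term
#'
#' Sum over (MHC lipophilic, peptide lipophilic) heavy-atom pairs of
#' `block(d; R1, R1 + 3.0)` with `R1 = r_i + r_j + 0.5` A.
#'
#' @inheritParams hb_term
#' @return non-negative dimensionless sum
#' @export
lipo_term <- function(c, params = term_params()) {
  .check_typed(c)
  .pair_kernel_sum(c$atoms, "lipophilic", "lipophilic", params)
}

#' Polar-lipophilic mismatch term
#'
#' Same distance kernel as [lipo_term()], summed over intermolecular mixed
#' pairs: a polar-class heavy atom (`bp_polar_classes`) on one side against
#' a lipophilic atom on the other, both directions.
#'
#' @inheritParams hb_term
#' @return non-negative dimensionless sum
#' @export
bp_term <- function(c, params = term_params()) {
  .check_typed(c)
  pol <- params$bp_polar_classes
  .pair_kernel_sum(c$atoms, "lipophilic", pol, params) +
    .pair_kernel_sum(c$atoms, pol, "lipophilic", params)
}

#' Rotatable-bond term
#'
#' Number of peptide side-chain rotatable bonds frozen on binding: a fixed
#' per-residue count summed over the sequence (coordinates never enter).
#'
#' @param sequence peptide in one-letter code
#' @return non-negative integer
#' @examples
#' rot_term("TLTSCNTSV")
#' @export
rot_term <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(ROTATABLE_BONDS))
  if (length(bad)) stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  as.integer(sum(ROTATABLE_BONDS[aa]))
}

#' Desolvation term
#'
#' `dG_desolv = G_solv(complex) - G_solv(MHC alone) - G_solv(peptide alone)`
#' in kJ/mol.  The default backend estimates `G_solv` as the sum over heavy
#' atoms of a per-class atomic solvation parameter times the atom's
#' solvent-accessible surface area (probe 1.4 A).  The `external` backend
#' reads a per-complex value from a table of precomputed continuum-
#' electrostatics (Poisson-Boltzmann) energies keyed by complex id.
#'
#' @inheritParams hb_term
#' @param backend `"sasa"` (default) or `"external"`
#' @param external_table named numeric vector (kJ/mol) keyed by complex id
#' @param sigma per-class solvation parameters; default bundled table
#' @return kJ/mol
#' @export
desolv_term <- function(c, params = term_params(), backend = c("sasa", "external"),
                        external_table = NULL, sigma = load_sigma_table()) {
  backend <- match.arg(backend)
  if (backend == "external") {
    if (is.null(external_table) || !(c$pdb_id %in% names(external_table))) {
      stop("no external desolvation value for complex '", c$pdb_id, "'")
    }
    return(unname(external_table[c$pdb_id]))
  }
  .check_typed(c)
  at <- c$atoms
  gsolv <- function(df) {
    a <- atom_sasa(df, probe = params$probe, n_points = params$sasa_points)
    sum(sigma[df$class] * a, na.rm = TRUE)
  }
  gsolv(at) - gsolv(at[at$role == "mhc", , drop = FALSE]) -
    gsolv(at[at$role == "peptide", , drop = FALSE])
}

#' Compute the five-term descriptor vector of a complex
#'
#' Assembles HB, LIPO, BP, ROT and DESOLV for one prepared complex into a
#' one-row data frame keyed by `complex_id`; deterministic for identical
#' input.
#'
#' @inheritParams desolv_term
#' @return data frame with columns complex_id, HB, LIPO, BP, ROT, DESOLV
#' @export
compute_terms <- function(c, params = term_params(), backend = "sasa",
                          external_table = NULL) {
  .check_typed(c)
  data.frame(
    complex_id = c$pdb_id,
    HB = hb_term(c, params),
    LIPO = lipo_term(c, params),
    BP = bp_term(c, params),
    ROT = rot_term(c$peptide_sequence),
    DESOLV = desolv_term(c, params, backend = backend, external_table = external_table),
    stringsAsFactors = FALSE
  )
}
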