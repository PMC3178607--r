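# Self-contained synthetic fixtures: (i) toy two-chain PDB complexes whose
# interface realises exactly a requested list of contact geometries, with
# analytically known term values; (ii) simulated binding datasets drawn
# from a known linear model of the five terms.  Toy complexes are
# scoring-kernel probes: each engineered contact lives in an isolated
# "arena" 40 A away from everything else, so no unintended atom pair falls
# inside any kernel's support.  Probe atoms are detached from their
# residue's bonded geometry on purpose; the fixtures are not meant to look
# like proteins.

#' Specification for a toy complex fixture
#'
#' @param n_hbonds number of engineered intermolecular hydrogen bonds
#' @param hbond_geometries list of `c(d_HA, theta)` pairs (A, degrees);
#'   sampled from the informative kernel range when omitted
#' @param n_lipo number of engineered lipophilic contacts
#' @param lipo_distances their C...C distances (A); sampled when omitted
#' @param n_bp number of engineered polar-lipophilic mismatch contacts
#' @param bp_distances their O...C distances (A); sampled when omitted
#' @param seed integer seed for any sampled geometry
#' @return list of class `toy_fixture_spec`
#' @export
toy_fixture_spec <- function(n_hbonds = 0, hbond_geometries = NULL,
                             n_lipo = 0, lipo_distances = NULL,
                             n_bp = 0, bp_distances = NULL,
                             seed = 1) {
  # force every argument before touching the RNG (callers may pass
  # expressions that themselves draw random numbers)
  force(n_hbonds); force(hbond_geometries); force(n_lipo)
  force(lipo_distances); force(n_bp); force(bp_distances); force(seed)
  needs_rng <- (is.null(hbond_geometries) && n_hbonds > 0) ||
    (is.null(lipo_distances) && n_lipo > 0) ||
    (is.null(bp_distances) && n_bp > 0)
  if (needs_rng) {
    orig <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(orig)) assign(".Random.seed", orig, globalenv()))
  }
  if (is.null(hbond_geometries) && n_hbonds > 0) {
    hbond_geometries <- replicate(n_hbonds,
      c(stats::runif(1, 1.7, 2.4), stats::runif(1, 110, 180)), simplify = FALSE)
  }
  if (!is.null(hbond_geometries)) n_hbonds <- length(hbond_geometries)
  if (is.null(lipo_distances) && n_lipo > 0) {
    lipo_distances <- stats::runif(n_lipo, 3.9, 6.8)
  }
  if (!is.null(lipo_distances)) n_lipo <- length(lipo_distances)
  if (is.null(bp_distances) && n_bp > 0) {
    bp_distances <- stats::runif(n_bp, 3.6, 6.5)
  }
  if (!is.null(bp_distances)) n_bp <- length(bp_distances)
  if (any(unlist(hbond_geometries) <= 0) || any(lipo_distances <= 0) ||
      any(bp_distances <= 0)) stop("all distances must be positive")
  if (n_hbonds > 0 && any(vapply(hbond_geometries, function(g) g[2] <= 0 || g[2] > 180,
                                 logical(1)))) {
    stop("hydrogen-bond angles must lie in (0, 180]")
  }
  structure(list(n_hbonds = n_hbonds, hbond_geometries = hbond_geometries,
                 n_lipo = n_lipo, lipo_distances = lipo_distances,
                 n_bp = n_bp, bp_distances = bp_distances, seed = seed),
            class = "toy_fixture_spec")
}

# ideal local backbone for one residue at an offset
.toy_backbone <- function(offset) {
  N <- c(0, 0, 0) + offset
  CA <- c(1.458, 0, 0) + offset
  C <- place_atom(c(-1, 0.5, 0) + offset, N, CA, 1.525, 111.2, 180)
  O <- place_atom(N, CA, C, 1.231, 120.8, 45)
  list(N = N, CA = CA, C = C, O = O)
}

#' Build a toy two-chain complex with analytically known terms
#'
#' Writes a minimal PDB (chain A = MHC stand-in, chain C = peptide) whose
#' only intermolecular contacts are the engineered ones, and returns the
#' exactly expected term vector.  Hydrogen-bond arenas use a serine
#' hydroxyl donor against a backbone carbonyl acceptor, lipophilic arenas
#' an alanine C-beta pair, and mismatch arenas a backbone carbonyl oxygen
#' against an alanine C-beta.  Expected HB/LIPO/BP come from the scalar
#' ramp formula on the (coordinate-rounded) geometry; expected DESOLV from
#' the closed-form two-sphere cap area of each arena pair; expected ROT
#' from the sequence table.  Identical specs give byte-identical files.
#'
#' @param spec a [toy_fixture_spec()]
#' @param params term parameters (kernel bounds; used for the expectation)
#' @param sigma per-class solvation parameters for the DESOLV expectation
#' @return list: `pdb_text` (character vector of lines), `expected`
#'   (one-row term data frame), `chain_roles`, `peptide_sequence`, `spec`
#' @export
make_toy_complex <- function(spec, params = term_params(),
                             sigma = load_sigma_table()) {
  stopifnot(inherits(spec, "toy_fixture_spec"))
  r3 <- function(x) round(x, 3)
  radii <- load_radius_table()
  contacts <- c(rep("hb", spec$n_hbonds), rep("lipo", spec$n_lipo),
                rep("bp", spec$n_bp))
  if (!length(contacts)) contacts <- character(0)
  n_res <- max(1, length(contacts))
  pep_letters <- c(hb = "S", lipo = "A", bp = "G")[contacts]
  if (!length(pep_letters)) pep_letters <- "G"
  sequence <- paste(pep_letters, collapse = "")

  atoms <- list()
  addatom <- function(name, el, xyz, resid, resno, chain) {
    atoms[[length(atoms) + 1]] <<- data.frame(
      name = name, element = el, x = r3(xyz[1]), y = r3(xyz[2]), z = r3(xyz[3]),
      resid = resid, resno = resno, insert = "", chain = chain,
      occ = 1, stringsAsFactors = FALSE)
  }
  # peptide backbone row (y = 0) and MHC backbone row (y = 300)
  kh <- 0; kl <- 0; kb <- 0
  pairs <- list()   # per-arena: pep heavy class/radius/xyz, mhc same
  for (i in seq_len(n_res)) {
    off_p <- c(40 * (i - 1), 0, 0)
    bb <- .toy_backbone(off_p)
    resid <- unname(AA3[substr(sequence, i, i)])
    arena <- c(40 * (i - 1), 150, 0)
    kind <- if (i <= length(contacts)) contacts[i] else "none"

    # peptide residue ------------------------------------------------
    addatom("N", "N", bb$N, resid, i, "C")
    addatom("CA", "C", bb$CA, resid, i, "C")
    addatom("C", "C", bb$C, resid, i, "C")
    if (kind == "bp") {
      kb <- kb + 1
      d <- spec$bp_distances[kb]
      o_xyz <- arena                         # displaced carbonyl O (acceptor)
      addatom("O", "O", o_xyz, resid, i, "C")
      m_xyz <- arena + c(d, 0, 0)            # MHC alanine CB (lipophilic)
      pairs[[length(pairs) + 1]] <- list(kind = "bp",
        p = r3(o_xyz), p_class = "acceptor", p_r = radii["O"],
        m = r3(m_xyz), m_class = "lipophilic", m_r = radii["C"])
    } else {
      addatom("O", "O", bb$O, resid, i, "C")
    }
    if (resid == "ALA" || resid == "SER") {
      sc <- .build_sidechain(resid, bb, chis = c(180))
      if (kind == "lipo") {
        kl <- kl + 1
        d <- spec$lipo_distances[kl]
        cb_xyz <- arena                      # displaced peptide CB
        addatom("CB", "C", cb_xyz, resid, i, "C")
        m_xyz <- arena + c(d, 0, 0)
        pairs[[length(pairs) + 1]] <- list(kind = "lipo",
          p = r3(cb_xyz), p_class = "lipophilic", p_r = radii["C"],
          m = r3(m_xyz), m_class = "lipophilic", m_r = radii["C"])
      } else {
        addatom("CB", "C", sc["CB", ], resid, i, "C")
      }
      if (resid == "SER") {
        if (kind == "hb") {
          kh <- kh + 1
          g <- spec$hbond_geometries[[kh]]
          og <- arena
          hg <- arena + c(0.96, 0, 0)
          th <- g[2] * pi / 180
          acc <- hg + g[1] * c(-cos(th), sin(th), 0)
          addatom("OG", "O", og, resid, i, "C")
          addatom("HG", "H", hg, resid, i, "C")
          m_xyz <- acc
          pairs[[length(pairs) + 1]] <- list(kind = "hb",
            p = r3(og), p_class = "donor_acceptor", p_r = radii["O"],
            h = r3(hg),
            m = r3(m_xyz), m_class = "acceptor", m_r = radii["O"])
        } else {
          addatom("OG", "O", sc["OG", ], resid, i, "C")
          addatom("HG", "H", place_atom(bb$CA, sc["CB", ], sc["OG", ],
                                        0.96, 109.5, 180), resid, i, "C")
        }
      }
    }

    # matching MHC residue at the far row ----------------------------
    off_m <- c(40 * (i - 1), 300, 0)
    mb <- .toy_backbone(off_m)
    mres <- if (kind %in% c("lipo", "bp")) "ALA" else "GLY"
    addatom("N", "N", mb$N, mres, i, "A")
    addatom("CA", "C", mb$CA, mres, i, "A")
    addatom("C", "C", mb$C, mres, i, "A")
    if (kind == "hb") {
      # displaced carbonyl O is the acceptor probe
      addatom("O", "O", pairs[[length(pairs)]]$m, mres, i, "A")
    } else {
      addatom("O", "O", mb$O, mres, i, "A")
    }
    if (mres == "ALA") {
      addatom("CB", "C", pairs[[length(pairs)]]$m, mres, i, "A")
    }
  }
  at <- do.call(rbind, atoms)

  # feasibility: arenas must stay isolated (they are by construction,
  # but a pathological request, e.g. a 40 A contact distance, breaks it)
  for (p in pairs) {
    if (sqrt(sum((p$p - p$m)^2)) > 35) {
      stop("infeasible geometry request: contact distance breaches arena isolation")
    }
  }

  # expected terms from the rounded coordinates ----------------------
  exp_hb <- 0; exp_lipo <- 0; exp_bp <- 0; exp_desolv <- 0
  for (p in pairs) {
    d <- sqrt(sum((p$p - p$m)^2))
    if (p$kind == "hb") {
      dha <- sqrt(sum((p$h - p$m)^2))
      theta <- bond_angle(p$p, p$h, p$m)
      exp_hb <- exp_hb +
        block_ramp(abs(dha - params$hb_d_ideal), params$hb_d1, params$hb_d2) *
        block_ramp(abs(theta - 180), params$hb_a1, params$hb_a2)
    } else {
      r1 <- p$p_r + p$m_r + params$lipo_r1_offset
      w <- block_ramp(d, r1, r1 + params$lipo_width)
      if (p$kind == "lipo") exp_lipo <- exp_lipo + w else exp_bp <- exp_bp + w
    }
    a <- two_sphere_sasa(p$p_r + params$probe, p$m_r + params$probe, d)
    full <- 4 * pi * (c(p$p_r, p$m_r) + params$probe)^2
    exp_desolv <- exp_desolv + sigma[p$p_class] * (a[1] - full[1]) +
      sigma[p$m_class] * (a[2] - full[2])
  }
  expected <- data.frame(complex_id = "toy", HB = exp_hb, LIPO = exp_lipo,
                         BP = exp_bp, ROT = rot_term(sequence),
                         DESOLV = unname(exp_desolv), stringsAsFactors = FALSE)

  # serialise via the standard writer
  at$role <- ifelse(at$chain == "A", "mhc", "peptide")
  at$class <- NA_character_
  at$radius <- unname(ifelse(at$element %in% names(radii), radii[at$element], radii["X"]))
  cx <- structure(list(atoms = at[order(match(at$chain, c("A", "C"))), ],
                       peptide_sequence = sequence, pdb_id = "toy",
                       resolution = NA_real_,
                       chain_roles = c(A = "mhc", C = "peptide")),
                  class = "complex_structure")
  list(pdb_text = write_complex(cx),
       expected = expected,
       chain_roles = c(A = "mhc", C = "peptide"),
       peptide_sequence = sequence,
       spec = spec)
}

#' Specification for a simulated binding dataset
#'
#' Stands in for a curated experimental binding set: the five terms are
#' sampled uniformly over realistic ranges and the binding free energy is
#' a known linear model of them plus Gaussian noise.
#'
#' @param true_intercept intercept (kJ/mol)
#' @param true_coefficients named 5-vector over HB, LIPO, BP, ROT, DESOLV
#' @param noise_sd Gaussian noise standard deviation (kJ/mol), >= 0
#' @param n_samples number of peptides (>= 4)
#' @param term_ranges named list of `c(lo, hi)` sampling intervals
#' @param seed integer seed
#' @return list of class `sim_spec`
#' @export
sim_spec <- function(true_intercept = -15,
                     true_coefficients = c(HB = -4, LIPO = -0.8, BP = 1.5,
                                           ROT = 2.5, DESOLV = 0.05),
                     noise_sd = 0.5, n_samples = 20,
                     term_ranges = list(HB = c(0, 10), LIPO = c(10, 80),
                                        BP = c(0, 40), ROT = c(5, 30),
                                        DESOLV = c(-60, 20)),
                     seed = 1) {
  stopifnot(noise_sd >= 0, n_samples >= 4,
            all(c("HB", "LIPO", "BP", "ROT", "DESOLV") %in% names(true_coefficients)))
  structure(list(true_intercept = true_intercept,
                 true_coefficients = true_coefficients[c("HB", "LIPO", "BP", "ROT", "DESOLV")],
                 noise_sd = noise_sd, n_samples = n_samples,
                 term_ranges = term_ranges, seed = seed),
            class = "sim_spec")
}

#' Simulate a binding dataset from a known linear model
#'
#' @param spec a [sim_spec()]
#' @return list: `X` (n x 5 term matrix), `y` (dG_bind vector, kJ/mol),
#'   `spec`
#' @export
simulate_binding <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  X <- sapply(c("HB", "LIPO", "BP", "ROT", "DESOLV"), function(t) {
    r <- spec$term_ranges[[t]]
    stats::runif(n, r[1], r[2])
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, c("HB", "LIPO", "BP", "ROT", "DESOLV")))
  y <- spec$true_intercept + drop(X %*% spec$true_coefficients) +
    stats::rnorm(n, 0, spec$noise_sd)
  list(X = X, y = y, spec = spec)
}
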