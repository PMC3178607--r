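# The five scoring terms: ramp kernel, per-term fixtures against
# exhaustive-loop oracles, and the geometric invariances.

test_that("the ramp kernel matches its piecewise definition and rejects bad bounds", {
  expect_equal(block_ramp(0.1, 0.25, 0.65), 1)
  expect_equal(block_ramp(0.45, 0.25, 0.65), 0.5)
  expect_equal(block_ramp(0.7, 0.25, 0.65), 0)
  expect_equal(block_ramp(c(0, 0.25, 0.65, 1), 0.25, 0.65), c(1, 1, 0, 0))
  expect_error(block_ramp(0.5, 0.65, 0.25), "x1")
  expect_error(block_ramp(0.5, 0.4, 0.4), "x1")
})

test_that("an ideal engineered hydrogen bond scores exactly 1", {
  fx <- make_toy_complex(toy_fixture_spec(n_hbonds = 1,
                                          hbond_geometries = list(c(1.85, 180))))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  expect_equal(hb_term(cx), 1.0)
  expect_equal(fx$expected$HB, 1.0)
})

test_that("intramolecular donor/acceptor geometry contributes nothing", {
  fx <- make_toy_complex(toy_fixture_spec(n_hbonds = 1,
                                          hbond_geometries = list(c(1.85, 180))))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  # move the whole hydrogen-bond arena into the MHC: relabel the peptide
  # serine donor atoms as an MHC chain serine
  at <- cx$atoms
  don <- at$resid == "SER" & at$name %in% c("OG", "HG")
  at$chain[don] <- "A"; at$role[don] <- "mhc"
  cx$atoms <- at
  expect_equal(hb_term(cx), 0)
})

test_that("engineered fixtures reproduce the exhaustive triple/pair-loop oracles to 1e-9", {
  for (seed in c(2, 7, 13)) {
    spec <- toy_fixture_spec(n_hbonds = 3, n_lipo = 4, n_bp = 3, seed = seed)
    fx <- make_toy_complex(spec)
    cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
    expect_equal(hb_term(cx), oracle_hb(cx$atoms), tolerance = 1e-9)
    expect_equal(lipo_term(cx), oracle_pair_sum(cx$atoms, "lipophilic", "lipophilic"),
                 tolerance = 1e-9)
    expect_equal(bp_term(cx), oracle_bp(cx$atoms), tolerance = 1e-9)
    expect_equal(hb_term(cx), fx$expected$HB, tolerance = 1e-9)
    expect_equal(lipo_term(cx), fx$expected$LIPO, tolerance = 1e-9)
    expect_equal(bp_term(cx), fx$expected$BP, tolerance = 1e-9)
  }
})

test_that("a realistic interface matches the oracles too (non-engineered geometry)", {
  cx <- prepare_complex(make_close_complex("SKL", gap = 4.2))
  expect_gt(lipo_term(cx) + bp_term(cx), 0)   # strands actually touch
  expect_equal(hb_term(cx), oracle_hb(cx$atoms), tolerance = 1e-9)
  expect_equal(lipo_term(cx), oracle_pair_sum(cx$atoms, "lipophilic", "lipophilic"),
               tolerance = 1e-9)
  expect_equal(bp_term(cx), oracle_bp(cx$atoms), tolerance = 1e-9)
})

test_that("lipophilic pairs score 1 at the inner bound and 0 past the cutoff", {
  r1 <- 2 * 1.70 + 0.5
  fx_in <- make_toy_complex(toy_fixture_spec(n_lipo = 2, lipo_distances = c(r1, r1)))
  cx_in <- prepare_complex(read_complex(fx_in$pdb_text, fx_in$chain_roles))
  expect_equal(lipo_term(cx_in), 2.0)
  fx_out <- make_toy_complex(toy_fixture_spec(n_lipo = 1, lipo_distances = r1 + 3.01))
  cx_out <- prepare_complex(read_complex(fx_out$pdb_text, fx_out$chain_roles))
  expect_equal(lipo_term(cx_out), 0)
})

test_that("mismatch term needs mixed polarity: carbonyl-O vs CB counts, all-lipophilic gives 0", {
  r1 <- 1.40 + 1.70 + 0.5
  fx <- make_toy_complex(toy_fixture_spec(n_bp = 1, bp_distances = r1))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  expect_equal(bp_term(cx), 1.0)
  fx2 <- make_toy_complex(toy_fixture_spec(n_lipo = 2, lipo_distances = c(4, 4.5)))
  cx2 <- prepare_complex(read_complex(fx2$pdb_text, fx2$chain_roles))
  expect_equal(bp_term(cx2), 0)
})

test_that("rotatable-bond counts follow the residue table and reject unknown letters", {
  expect_equal(rot_term("GAGA"), 0L)
  expect_equal(rot_term("KKKK"), 16L)
  expect_equal(rot_term("TLTSCNTSV"), 11L)  # independent per-letter sum
  tab <- c(A=0,G=0,P=0,S=1,C=1,T=1,V=1,D=2,N=2,I=2,L=2,F=2,W=2,H=2,Y=2,E=3,Q=3,M=3,K=4,R=4)
  set.seed(42)
  for (k in 1:10) {
    s <- paste(sample(names(tab), 12, replace = TRUE), collapse = "")
    expect_equal(rot_term(s), as.integer(sum(tab[strsplit(s, "")[[1]]])))
  }
  expect_error(rot_term("AXA"), "unknown")
})

test_that("desolvation vanishes with no interface, matches the two-sphere cap oracle, and passes external values through", {
  # no engineered contacts: chains are hundreds of Angstrom apart
  fx0 <- make_toy_complex(toy_fixture_spec())
  cx0 <- prepare_complex(read_complex(fx0$pdb_text, fx0$chain_roles))
  expect_equal(desolv_term(cx0), 0)
  # single lipophilic contact: analytic spherical-cap expectation
  fx1 <- make_toy_complex(toy_fixture_spec(n_lipo = 1, lipo_distances = 4.2))
  cx1 <- prepare_complex(read_complex(fx1$pdb_text, fx1$chain_roles))
  expect_equal(desolv_term(cx1), fx1$expected$DESOLV, tolerance = 0.05)
  # external backend is a keyed passthrough
  cx1$pdb_id <- "complexX"
  expect_equal(desolv_term(cx1, backend = "external",
                           external_table = c(complexX = -12.3)), -12.3)
  expect_error(desolv_term(cx1, backend = "external",
                           external_table = c(other = 1)), "complexX")
})

test_that("numerical SASA agrees with the closed-form two-sphere formula", {
  for (d in c(2.0, 3.1, 4.5, 5.9)) {
    atoms <- data.frame(name = c("CB", "CB"), element = c("C", "O"),
                        x = c(0, d), y = 0, z = 0,
                        radius = c(1.7, 1.4))
    num <- atom_sasa(atoms, n_points = 4000)
    ana <- two_sphere_sasa(1.7 + 1.4, 1.4 + 1.4, d)
    expect_equal(num, ana, tolerance = 0.01)
  }
})

test_that("all terms are invariant under rigid motion of the whole complex", {
  fx <- make_toy_complex(toy_fixture_spec(n_hbonds = 2, n_lipo = 2, n_bp = 1, seed = 9))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  t0 <- compute_terms(cx)
  t1 <- compute_terms(rigid_move(cx))
  for (cn in c("HB", "LIPO", "BP", "ROT")) {
    expect_equal(t1[[cn]], t0[[cn]], tolerance = 1e-6)
  }
  # DESOLV is numerically rotation-invariant only up to the SASA quadrature
  # resolution (the sphere point lattice is fixed in space; ~0.05 kJ/mol
  # at the default 960 points per atom)
  expect_lt(abs(t1$DESOLV - t0$DESOLV), 0.1)
})

test_that("pulling the peptide away never increases the contact terms", {
  fx <- make_toy_complex(toy_fixture_spec(n_hbonds = 1,
                                          hbond_geometries = list(c(1.85, 180)),
                                          n_lipo = 2, lipo_distances = c(3.9, 5),
                                          n_bp = 1, bp_distances = 4))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  prev <- c(Inf, Inf, Inf)
  for (shift in c(0, 0.5, 1.5, 3, 6, 12)) {
    cs <- cx
    pep <- cs$atoms$role == "peptide"
    cs$atoms$y[pep] <- cs$atoms$y[pep] - shift   # away from the MHC probes
    cur <- c(hb_term(cs), lipo_term(cs), bp_term(cs))
    expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
})

test_that("compute_terms is deterministic and composes the per-term values", {
  fx <- make_toy_complex(toy_fixture_spec(n_hbonds = 1, n_lipo = 1, seed = 3))
  cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles))
  a <- compute_terms(cx); b <- compute_terms(cx)
  expect_identical(a, b)
  expect_equal(a$HB, hb_term(cx))
  expect_equal(a$LIPO, lipo_term(cx))
  expect_equal(a$BP, bp_term(cx))
  expect_equal(a$ROT, rot_term(cx$peptide_sequence))
  expect_equal(a$DESOLV, desolv_term(cx))
  expect_error(compute_terms(read_complex(fx$pdb_text, fx$chain_roles)), "typed")
})
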