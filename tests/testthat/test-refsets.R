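# Superposition/RMSD, rank correlation, reference-set enumeration and the
# combination experiment.

fxA <- make_toy_complex(toy_fixture_spec(n_hbonds = 1, n_lipo = 2, seed = 21))
cxA <- prepare_complex(read_complex(fxA$pdb_text, fxA$chain_roles, pdb_id = "A1"))

test_that("superposition of a structure onto itself and onto rigid copies is exact", {
  s <- superpose_structures(cxA, cxA)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  moved <- rigid_move(cxA, angle = 1.2, axis = c(1, 2, 0.5))
  s2 <- superpose_structures(cxA, moved)
  expect_lt(s2$rmsd, 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
})

test_that("superposition RMSD matches the quaternion-method oracle on noisy copies", {
  set.seed(8)
  for (rep in 1:5) {
    b <- rigid_move(cxA, angle = runif(1, 0, 3), axis = runif(3))
    b$atoms$x <- b$atoms$x + rnorm(nrow(b$atoms), 0, 0.4)
    b$atoms$y <- b$atoms$y + rnorm(nrow(b$atoms), 0, 0.4)
    b$atoms$z <- b$atoms$z + rnorm(nrow(b$atoms), 0, 0.4)
    s <- superpose_structures(cxA, b)
    heavy <- cxA$atoms$element != "H"
    P <- as.matrix(b$atoms[heavy, c("x", "y", "z")])
    Q <- as.matrix(cxA$atoms[heavy, c("x", "y", "z")])
    expect_equal(s$rmsd, oracle_quaternion_rmsd(P, Q), tolerance = 1e-9)
  }
})

test_that("superposition is symmetric and respects atom selections", {
  b <- rigid_move(cxA, angle = 0.8)
  set.seed(3)
  b$atoms$z <- b$atoms$z + rnorm(nrow(b$atoms), 0, 0.5)
  expect_lt(abs(superpose_structures(cxA, b)$rmsd -
                superpose_structures(b, cxA)$rmsd), 1e-9)
  sm <- superpose_structures(cxA, b, "mhc")
  sp <- superpose_structures(cxA, b, "peptide")
  sw <- superpose_structures(cxA, b, "whole")
  expect_equal(sm$n_atoms_matched + sp$n_atoms_matched, sw$n_atoms_matched)
  # fewer than 3 shared atom keys must error
  tiny <- cxA
  tiny$atoms <- tiny$atoms[tiny$atoms$name == "CA", ][1:2, ]
  expect_error(superpose_structures(cxA, tiny), "matched")
})

test_that("mean pairwise RMSD averages the per-pair values", {
  b <- cxA; b$atoms$x <- b$atoms$x + 0.3; b$pdb_id <- "B"   # pure shift: rmsd 0
  expect_equal(mean_pairwise_rmsd(list(cxA, b)), 0, tolerance = 1e-9)
  set.seed(5)
  mk <- function(sd, id) {
    s <- cxA
    s$atoms$x <- s$atoms$x + rnorm(nrow(s$atoms), 0, sd)
    s$pdb_id <- id
    s
  }
  trio <- list(mk(0.2, "a"), mk(0.4, "b"), mk(0.6, "c"))
  prs <- c(superpose_structures(trio[[1]], trio[[2]])$rmsd,
           superpose_structures(trio[[1]], trio[[3]])$rmsd,
           superpose_structures(trio[[2]], trio[[3]])$rmsd)
  expect_equal(mean_pairwise_rmsd(trio), mean(prs), tolerance = 1e-12)
})

test_that("Spearman correlation: perfect monotone cases, ties, and invariances", {
  x <- c(3, 9, 1, 7, 5)
  expect_equal(spearman_rho(x, x^3), 1)
  expect_equal(spearman_rho(x, -2 * x + 1), -1)
  set.seed(9)
  xt <- sample(rep(1:4, times = c(3, 3, 2, 2)))
  yt <- rnorm(10) + xt
  expect_equal(spearman_rho(xt, yt), oracle_spearman(xt, yt), tolerance = 1e-12)
  expect_equal(spearman_rho(xt, yt), stats::cor(xt, yt, method = "spearman"),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(spearman_rho(exp(xt), yt^3 + 10 * yt), spearman_rho(xt, yt))
  expect_error(spearman_rho(rep(1, 5), 1:5), "variance")
})

test_that("reference-set enumeration is the product over shared-peptide groups", {
  tb <- utils::read.delim(bundled_table("hla_a2"), comment.char = "#")
  sets <- enumerate_reference_sets(tb)
  expect_length(sets, 4 * 3 * 7)      # 84
  expect_true(all(vapply(sets, function(s) nrow(s$members), 0L) == 6))
  # every set uses each shared peptide exactly once
  for (s in sets[c(1, 40, 84)]) {
    expect_equal(anyDuplicated(s$members$peptide), 0)
  }
  expect_equal(anyDuplicated(vapply(sets, function(s)
    paste(sort(s$members$pdb_id), collapse = "+"), "")), 0)
  # no choices: single structure per peptide
  one <- data.frame(pdb_id = c("X1", "X2", "X3"),
                    peptide = c("AAA", "CCC", "DDD"))
  expect_length(enumerate_reference_sets(one), 1)
  # groups of 2 and 3 plus a singleton -> 6 sets of 3 members
  g <- data.frame(pdb_id = c("A1", "A2", "B1", "B2", "B3", "S1"),
                  peptide = c("AA", "AA", "BB", "BB", "BB", "SS"))
  sets6 <- enumerate_reference_sets(g)
  expect_length(sets6, 6)
  expect_true(all(vapply(sets6, function(s) nrow(s$members), 0L) == 3))
})

test_that("enumeration count equals brute force on random grouping tables", {
  set.seed(14)
  for (rep in 1:8) {
    sizes <- sample(1:4, sample(2:5, 1), replace = TRUE)
    tb <- do.call(rbind, lapply(seq_along(sizes), function(g) {
      data.frame(pdb_id = paste0("P", g, "_", seq_len(sizes[g])),
                 peptide = paste0("pep", g))
    }))
    sets <- enumerate_reference_sets(tb)
    expect_length(sets, prod(sizes[sizes > 1]))
  }
})

# a small synthetic universe for the experiment: structures with varying
# engineered contacts, affinities generated from the true term model
make_refset_universe <- function(n_struct = 6, noise_xyz = 0, seed = 1,
                                 coef = c(HB = -6, LIPO = -2, BP = 1.5,
                                          ROT = 2, DESOLV = 0.1)) {
  set.seed(seed)
  structures <- list(); terms <- list()
  for (i in seq_len(n_struct)) {
    fx <- make_toy_complex(toy_fixture_spec(
      n_hbonds = 1, hbond_geometries = list(c(runif(1, 1.7, 2.1), runif(1, 150, 180))),
      n_lipo = 2, lipo_distances = runif(2, 4, 6),
      n_bp = 1, bp_distances = runif(1, 3.7, 6)))
    id <- sprintf("S%02d", i)
    cx <- prepare_complex(read_complex(fx$pdb_text, fx$chain_roles, pdb_id = id))
    tm <- compute_terms(cx)
    if (noise_xyz > 0) {
      jit <- which(cx$atoms$role == "mhc")
      cx$atoms$x[jit] <- cx$atoms$x[jit] + rnorm(length(jit), 0, noise_xyz)
      cx$atoms$y[jit] <- cx$atoms$y[jit] + rnorm(length(jit), 0, noise_xyz)
      cx$atoms$z[jit] <- cx$atoms$z[jit] + rnorm(length(jit), 0, noise_xyz)
    }
    # distinct native "peptides" so each structure has its own record
    pepname <- paste0(cx$peptide_sequence, substr("ACDEFGHIKLMNPQRS", i, i))
    cx$peptide_sequence <- pepname
    structures[[id]] <- cx
    terms[[id]] <- tm
  }
  X <- do.call(rbind, lapply(terms, function(t)
    as.numeric(t[c("HB", "LIPO", "BP", "ROT", "DESOLV")])))
  y <- -20 + drop(X %*% coef)
  bindings <- data.frame(
    peptide = vapply(structures, function(s) s$peptide_sequence, ""),
    dg_bind = y, stringsAsFactors = FALSE)
  list(structures = structures, bindings = bindings)
}

test_that("a clean linear universe gives near-perfect q2; identical copies are flagged", {
  u <- make_refset_universe(6, noise_xyz = 0, seed = 31)
  sets <- list(list(set_id = "set001",
                    members = data.frame(
                      pdb_id = names(u$structures),
                      peptide = u$bindings$peptide, stringsAsFactors = FALSE)))
  ex <- run_refset_experiment(sets, u$bindings, u$structures, n_components = 4)
  expect_gt(ex$results$q2, 0.9)
  # degenerate: six copies of one structure with distinct y values
  cop <- u$structures[rep(1, 6)]
  names(cop) <- sprintf("C%02d", 1:6)
  for (i in seq_along(cop)) {
    cop[[i]]$pdb_id <- names(cop)[i]
    cop[[i]]$peptide_sequence <- u$bindings$peptide[i]
  }
  sets2 <- list(list(set_id = "set001",
                     members = data.frame(pdb_id = names(cop),
                                          peptide = u$bindings$peptide,
                                          stringsAsFactors = FALSE)))
  ex2 <- run_refset_experiment(sets2, u$bindings, cop)
  expect_true(is.na(ex2$results$q2))
  expect_equal(ex2$results$rmsd_whole, 0, tolerance = 1e-9)
})

test_that("growing structural perturbation drives q2 down: negative rank correlation with RMSD", {
  rows <- lapply(seq(0, 1.8, length.out = 10), function(noise) {
    u <- make_refset_universe(6, noise_xyz = noise, seed = 100 + round(noise * 10))
    sets <- list(list(set_id = "s", members = data.frame(
      pdb_id = names(u$structures), peptide = u$bindings$peptide,
      stringsAsFactors = FALSE)))
    ex <- run_refset_experiment(sets, u$bindings, u$structures, n_components = 3)
    ex$results[, c("q2", "rmsd_whole")]
  })
  df <- do.call(rbind, rows)
  expect_lt(spearman_rho(df$q2, df$rmsd_whole), 0)
})
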