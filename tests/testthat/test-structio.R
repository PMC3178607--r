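# Structure ingestion: chain-role filtering, altloc resolution, protonation
# geometry and atom typing.

toy2 <- make_toy_complex(toy_fixture_spec(n_lipo = 1, lipo_distances = 4.5))

test_that("a two-chain file reads back with the declared roles and sequence", {
  cx <- read_complex(toy2$pdb_text, toy2$chain_roles)
  expect_s3_class(cx, "complex_structure")
  expect_equal(cx$peptide_sequence, toy2$peptide_sequence)
  expect_true(all(cx$atoms$role[cx$atoms$chain == "A"] == "mhc"))
  expect_true(all(cx$atoms$role[cx$atoms$chain == "C"] == "peptide"))
})

test_that("a discarded extra chain (TCR stand-in) changes nothing", {
  base <- read_complex(toy2$pdb_text, toy2$chain_roles)
  tcr <- c("ATOM      1  N   GLY D  99      90.000  90.000  90.000  1.00  0.00           N",
           "ATOM      2  CA  GLY D  99      91.458  90.000  90.000  1.00  0.00           C",
           "ATOM      3  C   GLY D  99      92.000  91.400  90.000  1.00  0.00           C",
           "ATOM      4  O   GLY D  99      91.400  92.400  90.000  1.00  0.00           O")
  txt <- c(toy2$pdb_text[toy2$pdb_text != "END"], tcr, "END")
  with_d <- read_complex(txt, c(toy2$chain_roles, D = "discarded"))
  expect_equal(nrow(with_d$atoms), nrow(base$atoms))
  expect_equal(with_d$atoms$name, base$atoms$name)
})

test_that("declared-but-absent chains and missing backbone raise structural errors", {
  expect_error(read_complex(toy2$pdb_text, c(A = "mhc", Z = "peptide")), "Z")
  broken <- toy2$pdb_text[!grepl("CA  ...\\sC   1", toy2$pdb_text)]
  expect_error(read_complex(broken, toy2$chain_roles), "backbone")
})

test_that("altloc resolution keeps one atom: highest occupancy, ties to A", {
  hdr <- function(alt, occ, x) sprintf(
    "ATOM      1  CB AALA C   1      %6.3f   0.000   0.000  %4.2f  0.00           C", x, occ)
  mk <- function(lines) c(
    "ATOM      1  N   ALA C   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA C   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA C   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA C   1       1.400   2.400   0.000  1.00  0.00           O",
    lines,
    "ATOM      7  N   GLY A   9      50.000   0.000   0.000  1.00  0.00           N",
    "ATOM      8  CA  GLY A   9      51.458   0.000   0.000  1.00  0.00           C",
    "ATOM      9  C   GLY A   9      52.000   1.400   0.000  1.00  0.00           C",
    "END")
  two <- c(sub(" CB A", " CB A", hdr("A", 0.60, 5)),
           sub(" CB A", " CB B", hdr("B", 0.40, 9)))
  cx <- read_complex(mk(two), c(A = "mhc", C = "peptide"))
  cb <- cx$atoms[cx$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 5)          # occupancy 0.6 wins
  tie <- c(sub(" CB A", " CB B", hdr("B", 0.50, 9)),
           sub(" CB A", " CB A", hdr("A", 0.50, 5)))
  cx2 <- read_complex(mk(tie), c(A = "mhc", C = "peptide"))
  expect_equal(cx2$atoms$x[cx2$atoms$name == "CB"], 5)   # tie -> altloc A
})

test_that("write/read round trip preserves names and coordinates to 0.001 A", {
  cx <- read_complex(toy2$pdb_text, toy2$chain_roles)
  txt <- write_complex(cx)
  cx2 <- read_complex(txt, toy2$chain_roles)
  expect_equal(cx2$atoms$name, cx$atoms$name)
  expect_equal(cx2$atoms$resid, cx$atoms$resid)
  expect_equal(as.matrix(cx2$atoms[, c("x", "y", "z")]),
               as.matrix(cx$atoms[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("polar hydrogen placement: canonical lengths, no proline amide H, idempotent, heavy atoms fixed", {
  cx <- make_close_complex("SKP")
  before <- cx$atoms
  cxh <- place_polar_hydrogens(cx)
  heavy <- cxh$atoms[cxh$atoms$element != "H", ]
  expect_equal(max(abs(as.matrix(heavy[, c("x", "y", "z")]) -
                       as.matrix(before[, c("x", "y", "z")]))), 0)
  hs <- cxh$atoms[cxh$atoms$element == "H", ]
  # every H sits at a canonical bond length from its parent
  par <- groovescore:::hydrogen_parents(cxh$atoms)
  for (k in seq_along(par)) {
    i <- as.integer(names(par)[k]); j <- par[k]
    d <- sqrt(sum((as.numeric(cxh$atoms[i, c("x", "y", "z")]) -
                   as.numeric(cxh$atoms[j, c("x", "y", "z")]))^2))
    expected <- if (cxh$atoms$element[j] == "O") 0.96 else 1.01
    expect_equal(d, expected, tolerance = 0.01)
  }
  # proline: no amide H on its backbone N
  pro_n <- which(cxh$atoms$resid == "PRO" & cxh$atoms$name == "N")
  expect_false(any(par == pro_n))
  # lysine ammonium: three H on NZ
  nz <- which(cxh$atoms$resid == "LYS" & cxh$atoms$name == "NZ")
  expect_equal(sum(par == nz), 3)
  # idempotence
  cxh2 <- place_polar_hydrogens(cxh)
  expect_equal(nrow(cxh2$atoms), nrow(cxh$atoms))
})

test_that("backbone amide H is placed anti to the preceding carbonyl", {
  cx <- place_polar_hydrogens(make_close_complex("AAA"))
  at <- cx$atoms
  geo <- asNamespace("groovescore")
  pepsel <- at$role == "peptide"
  getp <- function(rn, nm) as.numeric(at[pepsel & at$resno == rn & at$name == nm,
                                         c("x", "y", "z")][1, ])
  dih <- geo$dihedral_angle(getp(1, "O"), getp(1, "C"), getp(2, "N"), getp(2, "H"))
  expect_gt(abs(dih), 150)
})

test_that("atom typing follows the ChemScore table and is total over standard residues", {
  cx <- assign_atom_classes(make_close_complex("SKL"))
  at <- cx$atoms
  cls <- function(resid, nm) at$class[at$resid == resid & at$name == nm][1]
  expect_equal(cls("LYS", "NZ"), "donor")
  expect_equal(cls("LEU", "CD1"), "lipophilic")
  expect_equal(cls("SER", "OG"), "donor_acceptor")
  expect_equal(cls("GLY", "O"), "acceptor")
  expect_equal(cls("GLY", "N"), "donor")
  expect_equal(cls("GLY", "C"), "polar_neutral")
  expect_equal(cls("LYS", "CE"), "polar_neutral")   # carbon bonded to N
  expect_false(any(is.na(at$class)))
  # determinism / coordinate independence
  cx2 <- assign_atom_classes(rigid_move(make_close_complex("SKL")))
  expect_equal(cx2$atoms$class, at$class)
  # full 20-residue coverage: every heavy atom of every residue classified
  for (r3 in names(groovescore:::SIDECHAIN_TEMPLATES)) {
    tab <- groovescore:::residue_class_table(r3)
    expect_true(all(tab %in% c("lipophilic", "donor", "acceptor",
                               "donor_acceptor", "polar_neutral")),
                info = r3)
  }
})

test_that("unknown residues warn and type as other", {
  cx <- make_close_complex("AAA")
  cx$atoms$resid[cx$atoms$resno == 2 & cx$atoms$role == "mhc"] <- "LIG"
  expect_warning(cx2 <- assign_atom_classes(cx), "other")
  expect_true(all(cx2$atoms$class[cx2$atoms$resid == "LIG"] == "other"))
})
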