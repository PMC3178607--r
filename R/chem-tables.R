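# Chemistry reference tables for the 20 standard amino acids: 1/3-letter
# codes, side-chain internal-coordinate templates, heavy-atom connectivity,
# standard-protonation hydrogen counts and the rotatable-bond table used by
# the ROT term.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- structure(names(AA3), names = AA3)

#' Rotatable side-chain bonds per residue (one-letter code).
#'
#' The ROT term counts the side-chain single bonds frozen on binding:
#' 0 for Ala/Gly/Pro, 1 for Ser/Cys/Thr/Val, 2 for Asp/Asn/Ile/Leu/Phe/
#' Trp/His/Tyr, 3 for Glu/Gln/Met, 4 for Lys/Arg.
#' @noRd
ROTATABLE_BONDS <- c(A = 0, G = 0, P = 0,
                     S = 1, C = 1, T = 1, V = 1,
                     D = 2, N = 2, I = 2, L = 2, F = 2, W = 2, H = 2, Y = 2,
                     E = 3, Q = 3, M = 3,
                     K = 4, R = 4)

# Side-chain template rows: atom placed from parent chain p-gp-ggp with
# given bond length / angle; dihedral = chi[k] + off when chi > 0, else
# the fixed value in off.  CB uses the backbone improper (verified to give
# L-configuration).  Ring geometries are idealised planar values.
sc_row <- function(name, p, gp, ggp, bond, angle, chi, off) {
  data.frame(name = name, p = p, gp = gp, ggp = ggp, bond = bond,
             angle = angle, chi = chi, off = off, stringsAsFactors = FALSE)
}

.cb <- sc_row("CB", "CA", "N", "C", 1.53, 110.5, 0, 122.6)

SIDECHAIN_TEMPLATES <- list(
  GLY = NULL,
  ALA = .cb,
  SER = rbind(.cb, sc_row("OG",  "CB", "CA", "N", 1.42, 110.8, 1, 0)),
  CYS = rbind(.cb, sc_row("SG",  "CB", "CA", "N", 1.81, 113.8, 1, 0)),
  THR = rbind(.cb,
              sc_row("OG1", "CB", "CA", "N", 1.43, 109.6, 1, 0),
              sc_row("CG2", "CB", "CA", "N", 1.53, 110.5, 1, -120)),
  VAL = rbind(.cb,
              sc_row("CG1", "CB", "CA", "N", 1.53, 110.5, 1, 0),
              sc_row("CG2", "CB", "CA", "N", 1.53, 110.5, 1, 120)),
  LEU = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.53, 116.3, 1, 0),
              sc_row("CD1", "CG", "CB", "CA", 1.53, 110.5, 2, 0),
              sc_row("CD2", "CG", "CB", "CA", 1.53, 110.5, 2, 120)),
  ILE = rbind(.cb,
              sc_row("CG1", "CB", "CA", "N",  1.53, 110.4, 1, 0),
              sc_row("CG2", "CB", "CA", "N",  1.53, 110.5, 1, -120),
              sc_row("CD1", "CG1", "CB", "CA", 1.53, 113.8, 2, 0)),
  MET = rbind(.cb,
              sc_row("CG", "CB", "CA", "N",  1.52, 114.1, 1, 0),
              sc_row("SD", "CG", "CB", "CA", 1.81, 112.7, 2, 0),
              sc_row("CE", "SD", "CG", "CB", 1.79, 100.9, 3, 0)),
  PRO = rbind(.cb,
              sc_row("CG", "CB", "CA", "N",  1.50, 104.5, 0, 30),
              sc_row("CD", "CG", "CB", "CA", 1.51, 105.5, 0, -35)),
  PHE = rbind(.cb,
              sc_row("CG",  "CB",  "CA", "N",   1.50, 113.8, 1, 0),
              sc_row("CD1", "CG",  "CB", "CA",  1.39, 120.8, 2, 0),
              sc_row("CD2", "CG",  "CB", "CA",  1.39, 120.8, 2, 180),
              sc_row("CE1", "CD1", "CG", "CB",  1.39, 120.0, 0, 180),
              sc_row("CE2", "CD2", "CG", "CB",  1.39, 120.0, 0, 180),
              sc_row("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0, 0)),
  TYR = rbind(.cb,
              sc_row("CG",  "CB",  "CA", "N",   1.51, 113.8, 1, 0),
              sc_row("CD1", "CG",  "CB", "CA",  1.39, 120.8, 2, 0),
              sc_row("CD2", "CG",  "CB", "CA",  1.39, 120.8, 2, 180),
              sc_row("CE1", "CD1", "CG", "CB",  1.39, 120.0, 0, 180),
              sc_row("CE2", "CD2", "CG", "CB",  1.39, 120.0, 0, 180),
              sc_row("CZ",  "CE1", "CD1", "CG", 1.39, 120.0, 0, 0),
              sc_row("OH",  "CZ",  "CE1", "CD1", 1.38, 119.9, 0, 180)),
  TRP = rbind(.cb,
              sc_row("CG",  "CB",  "CA",  "N",   1.50, 113.6, 1, 0),
              sc_row("CD1", "CG",  "CB",  "CA",  1.37, 126.9, 2, 0),
              sc_row("CD2", "CG",  "CB",  "CA",  1.43, 126.8, 2, 180),
              sc_row("NE1", "CD1", "CG",  "CB",  1.38, 110.2, 0, 180),
              sc_row("CE2", "CD2", "CG",  "CD1", 1.41, 107.2, 0, 0),
              sc_row("CE3", "CD2", "CG",  "CD1", 1.40, 133.9, 0, 180),
              sc_row("CZ2", "CE2", "CD2", "CG",  1.40, 122.4, 0, 180),
              sc_row("CZ3", "CE3", "CD2", "CG",  1.39, 118.6, 0, 180),
              sc_row("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0, 180)),
  ASP = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.52, 112.6, 1, 0),
              sc_row("OD1", "CG", "CB", "CA", 1.25, 118.4, 2, 0),
              sc_row("OD2", "CG", "CB", "CA", 1.25, 118.4, 2, 180)),
  ASN = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.52, 112.6, 1, 0),
              sc_row("OD1", "CG", "CB", "CA", 1.23, 120.8, 2, 0),
              sc_row("ND2", "CG", "CB", "CA", 1.33, 116.4, 2, 180)),
  GLU = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 112.6, 2, 0),
              sc_row("OE1", "CD", "CG", "CB", 1.25, 118.4, 3, 0),
              sc_row("OE2", "CD", "CG", "CB", 1.25, 118.4, 3, 180)),
  GLN = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 112.6, 2, 0),
              sc_row("OE1", "CD", "CG", "CB", 1.23, 120.8, 3, 0),
              sc_row("NE2", "CD", "CG", "CB", 1.33, 116.4, 3, 180)),
  HIS = rbind(.cb,
              sc_row("CG",  "CB",  "CA", "N",  1.49, 113.8, 1, 0),
              sc_row("ND1", "CG",  "CB", "CA", 1.38, 122.7, 2, 0),
              sc_row("CD2", "CG",  "CB", "CA", 1.35, 131.0, 2, 180),
              sc_row("CE1", "ND1", "CG", "CB", 1.32, 109.2, 0, 180),
              sc_row("NE2", "CD2", "CG", "CB", 1.37, 107.2, 0, 180)),
  LYS = rbind(.cb,
              sc_row("CG", "CB", "CA", "N",  1.52, 114.1, 1, 0),
              sc_row("CD", "CG", "CB", "CA", 1.52, 111.3, 2, 0),
              sc_row("CE", "CD", "CG", "CB", 1.52, 111.3, 3, 0),
              sc_row("NZ", "CE", "CD", "CG", 1.49, 111.9, 4, 0)),
  ARG = rbind(.cb,
              sc_row("CG",  "CB", "CA", "N",  1.52, 114.1, 1, 0),
              sc_row("CD",  "CG", "CB", "CA", 1.52, 111.3, 2, 0),
              sc_row("NE",  "CD", "CG", "CB", 1.46, 111.5, 3, 0),
              sc_row("CZ",  "NE", "CD", "CG", 1.33, 124.2, 4, 0),
              sc_row("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0, 0),
              sc_row("NH2", "CZ", "NE", "CD", 1.33, 120.0, 0, 180))
)

# Ring-closure bonds not expressed by the parent relation above.
RING_CLOSURES <- list(
  PHE = list(c("CE2", "CZ")),
  TYR = list(c("CE2", "CZ")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  HIS = list(c("CE1", "NE2")),
  PRO = list(c("CD", "N"))
)

# Heavy-atom connectivity within one residue (backbone + side chain).
residue_bonds <- function(resid) {
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"))
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  if (!is.null(tpl)) {
    for (i in seq_len(nrow(tpl))) bonds <- c(bonds, list(c(tpl$p[i], tpl$name[i])))
  }
  cl <- RING_CLOSURES[[resid]]
  if (!is.null(cl)) bonds <- c(bonds, cl)
  bonds
}

# Nitrogens/oxygens carrying at least one hydrogen at standard protonation
# (pH ~7, epsilon tautomer for His).  Backbone N handled separately.
DONOR_HEAVY <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2", GLN = "NE2",
  TRP = "NE1",
  HIS = "NE2"
)

# Classes forced regardless of the generic bonded-H rule.
CLASS_OVERRIDES <- list(
  SER = c(OG = "donor_acceptor"),
  THR = c(OG1 = "donor_acceptor"),
  TYR = c(OH = "donor_acceptor"),
  HIS = c(ND1 = "donor_acceptor", NE2 = "donor_acceptor"),
  PRO = c(N = "polar_neutral")
)

#' Infer the element from a PDB atom name
#' @noRd
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  el <- substr(nm, 1, 1)
  ifelse(el %in% c("C", "N", "O", "S", "H", "P"), el, "X")
}

#' Load the bundled PARSE-style van der Waals radius table
#'
#' Per-element radii (Angstrom) in the PARSE parameterisation used for the
#' contact kernels, clash detection and solvent-accessible surface areas.
#' A user table with columns `element` and `radius` may override it.
#'
#' @param path optional TSV with columns element, radius
#' @return named numeric vector of radii by element symbol
#' @export
load_radius_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parse_radii.tsv", package = "groovescore")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  structure(tab$radius, names = tab$element)
}

#' Per-class atomic solvation parameters (kJ mol-1 A-2)
#' @noRd
load_sigma_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solvation_sigma.tsv", package = "groovescore")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  structure(tab$sigma, names = tab$atom_class)
}
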