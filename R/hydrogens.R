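# Geometric placement of polar hydrogens.  Only hydrogens on nitrogen and
# oxygen donors are needed by the hydrogen-bond term, so apolar C-H
# hydrogens are never generated.  Bond lengths: N-H 1.01 A, O-H 0.96 A.

NH_BOND <- 1.01
OH_BOND <- 0.96

#' Add polar hydrogens at idealised geometry
#'
#' Every donor nitrogen or oxygen of the standard residues receives
#' hydrogens at canonical bond lengths along idealised directions: the
#' backbone amide H anti to the preceding carbonyl (in-plane bisector of
#' CA and the preceding C), sp2 ring/amide hydrogens in the plane of their
#' neighbours, sp3 ammonium/hydroxyl hydrogens staggered.  Proline has no
#' amide hydrogen.  Heavy atoms are never moved and donors that already
#' carry a hydrogen (within 1.25 A) are left untouched, so the operation
#' is idempotent.  Non-standard residues are skipped with a warning.
#'
#' @param c a `complex_structure`
#' @return the structure with hydrogen rows appended per residue
#' @export
place_polar_hydrogens <- function(c) {
  at <- c$atoms
  rkey <- residue_keys(at)
  hyd <- at$element == "H"
  # map existing hydrogens to their heavy parent (nearest N/O/C within 1.25 A)
  out <- list()
  for (rk in unique(rkey)) {
    idx <- which(rkey == rk)
    res <- at[idx, , drop = FALSE]
    resid <- res$resid[1]
    out[[length(out) + 1]] <- res
    if (!(resid %in% c(names(SIDECHAIN_TEMPLATES), "GLY"))) {
      warning("non-standard residue ", resid, " skipped during protonation")
      next
    }
    newh <- .residue_polar_h(res, at, idx, rkey)
    if (!is.null(newh)) out[[length(out) + 1]] <- newh
  }
  c$atoms <- do.call(rbind, out)
  rownames(c$atoms) <- NULL
  c
}

# coordinates of a named atom in a residue data frame (or NULL)
.xyz_of <- function(res, name) {
  i <- match(name, res$name)
  if (is.na(i)) NULL else c(res$x[i], res$y[i], res$z[i])
}

.has_h_on <- function(res, heavy_xyz, thresh = 1.25) {
  h <- res[res$element == "H", , drop = FALSE]
  if (!nrow(h)) return(FALSE)
  d <- sqrt((h$x - heavy_xyz[1])^2 + (h$y - heavy_xyz[2])^2 + (h$z - heavy_xyz[3])^2)
  any(d < thresh)
}

.h_row <- function(res, name, xyz) {
  data.frame(name = name, element = "H", x = xyz[1], y = xyz[2], z = xyz[3],
             resid = res$resid[1], resno = res$resno[1], insert = res$insert[1],
             chain = res$chain[1], role = res$role[1], occ = 1,
             class = "hydrogen", radius = 1.0, stringsAsFactors = FALSE)
}

# H along the in-plane direction opposite the bisector of two neighbours
.bisector_h <- function(x, n1, n2, bond) x + bond * unit(unit(x - n1) + unit(x - n2))

.residue_polar_h <- function(res, at, idx, rkey) {
  resid <- res$resid[1]
  rows <- list()
  add <- function(name, xyz) rows[[length(rows) + 1]] <<- .h_row(res, name, xyz)

  n <- .xyz_of(res, "N"); ca <- .xyz_of(res, "CA"); cc <- .xyz_of(res, "C")
  # backbone amide H (not proline)
  if (resid != "PRO" && !is.null(n) && !.has_h_on(res, n)) {
    prev_c <- .prev_carbonyl_c(at, idx, rkey, res)
    if (!is.null(prev_c)) {
      add("H", .bisector_h(n, ca, prev_c, NH_BOND))
    } else if (!is.null(ca) && !is.null(cc)) {
      # chain terminus: single H anti to the carbonyl carbon
      add("H", place_atom(cc, ca, n, NH_BOND, 109.5, 180))
    }
  }

  sc <- function(a, b, cth, bond, angle, dihedrals, names) {
    A <- .xyz_of(res, a); B <- .xyz_of(res, b); C <- .xyz_of(res, cth)
    if (is.null(A) || is.null(B) || is.null(C) || .has_h_on(res, C)) return()
    for (k in seq_along(dihedrals)) add(names[k], place_atom(A, B, C, bond, angle, dihedrals[k]))
  }
  bis <- function(cth, n1, n2, bond, name) {
    X <- .xyz_of(res, cth); A <- .xyz_of(res, n1); B <- .xyz_of(res, n2)
    if (is.null(X) || is.null(A) || is.null(B) || .has_h_on(res, X)) return()
    add(name, .bisector_h(X, A, B, bond))
  }

  switch(resid,
    SER = sc("CA", "CB", "OG", OH_BOND, 109.5, 180, "HG"),
    THR = sc("CA", "CB", "OG1", OH_BOND, 109.5, 180, "HG1"),
    TYR = sc("CE1", "CZ", "OH", OH_BOND, 110.0, 0, "HH"),
    LYS = sc("CD", "CE", "NZ", NH_BOND, 109.5, c(180, 60, -60),
             c("HZ1", "HZ2", "HZ3")),
    ASN = sc("OD1", "CG", "ND2", NH_BOND, 120, c(0, 180), c("HD21", "HD22")),
    GLN = sc("OE1", "CD", "NE2", NH_BOND, 120, c(0, 180), c("HE21", "HE22")),
    ARG = {
      bis("NE", "CD", "CZ", NH_BOND, "HE")
      sc("NE", "CZ", "NH1", NH_BOND, 120, c(0, 180), c("HH11", "HH12"))
      sc("NE", "CZ", "NH2", NH_BOND, 120, c(0, 180), c("HH21", "HH22"))
    },
    TRP = bis("NE1", "CD1", "CE2", NH_BOND, "HE1"),
    HIS = bis("NE2", "CD2", "CE1", NH_BOND, "HE2"),
    NULL
  )
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# carbonyl C of the residue preceding this one in the same chain
.prev_carbonyl_c <- function(at, idx, rkey, res) {
  ch <- res$chain[1]
  chain_keys <- unique(rkey[at$chain == ch])
  pos <- match(rkey[idx[1]], chain_keys)
  if (is.na(pos) || pos == 1) return(NULL)
  prev <- at[rkey == chain_keys[pos - 1] & at$name == "C", , drop = FALSE]
  if (!nrow(prev)) return(NULL)
  # only a genuinely bonded predecessor counts (C-N about 1.33 A)
  n <- .xyz_of(res, "N")
  d <- sqrt(sum((c(prev$x[1], prev$y[1], prev$z[1]) - n)^2))
  if (d > 2.0) return(NULL)
  c(prev$x[1], prev$y[1], prev$z[1])
}
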