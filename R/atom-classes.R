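# ChemScore-style atom typing.  Classification is a pure function of
# residue name + atom name: lipophilic = C or S bonded only to C/S/H;
# donor = N/O carrying a hydrogen at standard protonation; acceptor = O,
# or N with no hydrogen; donor_acceptor = hydroxyl oxygens and the
# histidine ring nitrogens; everything else polar_neutral.

.class_cache <- new.env(parent = emptyenv())

#' Atom class table for one standard residue
#' @noRd
residue_class_table <- function(resid) {
  if (!is.null(.class_cache[[resid]])) return(.class_cache[[resid]])
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  heavy <- c("N", "CA", "C", "O", "OXT", if (!is.null(tpl)) tpl$name)
  bonds <- residue_bonds(resid)
  neigh <- function(a) unique(unlist(lapply(bonds, function(b) {
    if (b[1] == a) b[2] else if (b[2] == a) b[1] else NULL
  })))
  donors <- c(if (resid != "PRO") "N", DONOR_HEAVY[[resid]])
  cls <- vapply(heavy, function(a) {
    el <- element_from_name(a)
    if (el %in% c("C", "S")) {
      nb <- neigh(a)
      nb_el <- element_from_name(nb)
      if (length(nb) && all(nb_el %in% c("C", "S"))) "lipophilic" else "polar_neutral"
    } else if (el == "N") {
      if (a %in% donors) "donor" else "acceptor"
    } else if (el == "O") {
      if (a %in% donors) "donor_acceptor" else "acceptor"
    } else "other"
  }, character(1))
  ov <- CLASS_OVERRIDES[[resid]]
  if (!is.null(ov)) cls[names(ov)] <- ov
  .class_cache[[resid]] <- cls
  cls
}

#' Assign ChemScore-style classes to every atom
#'
#' Fills the `class` column of the atom table: one of `lipophilic`,
#' `donor`, `acceptor`, `donor_acceptor`, `polar_neutral`, `hydrogen`
#' or `other`.  The assignment depends only on residue and atom names,
#' never on coordinates, so it is deterministic and total over the 20
#' standard residues.  Atoms of unknown residues, or unknown atom names
#' within a known residue, fall back to `other` with a warning.
#'
#' @param c a `complex_structure` (hydrogens may or may not be present)
#' @return the structure with the `class` column populated
#' @export
assign_atom_classes <- function(c) {
  at <- c$atoms
  cls <- rep("other", nrow(at))
  cls[at$element == "H"] <- "hydrogen"
  unknown <- character(0)
  for (resid in unique(at$resid)) {
    sel <- which(at$resid == resid & at$element != "H")
    if (!length(sel)) next
    if (!(resid %in% c(names(SIDECHAIN_TEMPLATES), "GLY"))) {
      unknown <- c(unknown, resid)
      next
    }
    tab <- residue_class_table(resid)
    known <- at$name[sel] %in% names(tab)
    cls[sel[known]] <- unname(tab[at$name[sel[known]]])
    if (any(!known)) unknown <- c(unknown, paste0(resid, ":", at$name[sel[!known]]))
  }
  if (length(unknown)) {
    warning("atoms classified 'other' (unknown residue/atom): ",
            paste(unique(unknown), collapse = ", "))
  }
  c$atoms$class <- cls
  c
}

#' Prepare a complex for term calculation
#'
#' Convenience wrapper: place polar hydrogens, then assign atom classes.
#' @param c a `complex_structure`
#' @return prepared structure
#' @export
prepare_complex <- function(c) assign_atom_classes(place_polar_hydrogens(c))

#' Index of the heavy parent for each hydrogen (nearest N/O/S/C within 1.25 A)
#' @noRd
hydrogen_parents <- function(atoms) {
  hidx <- which(atoms$element == "H")
  parents <- integer(length(hidx))
  heavy <- which(atoms$element != "H")
  hx <- as.matrix(atoms[heavy, c("x", "y", "z")])
  for (k in seq_along(hidx)) {
    i <- hidx[k]
    same_res <- heavy[atoms$chain[heavy] == atoms$chain[i] &
                      atoms$resno[heavy] == atoms$resno[i] &
                      atoms$insert[heavy] == atoms$insert[i]]
    if (!length(same_res)) { parents[k] <- NA_integer_; next }
    p <- as.matrix(atoms[same_res, c("x", "y", "z")])
    d2 <- (p[, 1] - atoms$x[i])^2 + (p[, 2] - atoms$y[i])^2 + (p[, 3] - atoms$z[i])^2
    j <- which.min(d2)
    parents[k] <- if (d2[j] < 1.25^2) same_res[j] else NA_integer_
  }
  structure(parents, names = hidx)
}
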