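#' @importFrom stats setNames
NULL

#' Read and clean a peptide-MHC complex from PDB text
#'
#' Parses PDB-format coordinates (via bio3d), keeps only the chains named in
#' `chain_roles`, strips waters and other heteroatoms, resolves alternate
#' locations (highest occupancy wins, ties go to altloc "A") and derives the
#' bound peptide sequence from the peptide chain in residue-number order.
#'
#' Chain roles are explicit rather than inferred because chain naming is
#' inconsistent across crystal structures: for HLA class I the heavy chain
#' and beta-2-microglobulin are both given role `"mhc"`, for class II the
#' alpha and beta chains are; a co-crystallised T-cell receptor is declared
#' `"discarded"` and removed before any analysis.
#'
#' @param pdb PDB-format text (single string or character vector of lines),
#'   or the path to a PDB file.
#' @param chain_roles named character vector mapping chain identifiers to
#'   `"mhc"`, `"peptide"` or `"discarded"`; exactly one chain must be the
#'   peptide.
#' @param pdb_id identifier stored with the structure (defaults to the file
#'   name, or `"complex"` for literal text).
#' @param radii named per-element van der Waals radius vector, as returned
#'   by [load_radius_table()].
#' @return a `complex_structure`: list with an `atoms` data frame (name,
#'   element, x/y/z, residue, chain, role, occupancy, class, radius),
#'   `peptide_sequence`, `pdb_id`, `resolution` (Angstrom or `NA`) and
#'   `chain_roles`.
#' @examples
#' fx <- make_toy_complex(toy_fixture_spec(n_lipo = 1))
#' cx <- read_complex(fx$pdb_text, fx$chain_roles)
#' cx$peptide_sequence
#' @export
read_complex <- function(pdb, chain_roles, pdb_id = NULL, radii = load_radius_table()) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(pdb_id)) pdb_id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
    if (is.null(pdb_id)) pdb_id <- "complex"
  }
  stopifnot(is.character(chain_roles), !is.null(names(chain_roles)))
  bad_role <- setdiff(unique(chain_roles), c("mhc", "peptide", "discarded"))
  if (length(bad_role)) stop("unknown chain role(s): ", paste(bad_role, collapse = ", "))
  if (sum(chain_roles == "peptide") != 1) stop("exactly one chain must have role 'peptide'")

  resolution <- .parse_resolution(lines)
  pdbobj <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  missing_chain <- setdiff(names(chain_roles), unique(at$chain))
  if (length(missing_chain)) {
    stop("declared chain(s) not present in structure: ",
         paste(missing_chain, collapse = ", "))
  }
  keep_roles <- chain_roles[chain_roles != "discarded"]
  at <- at[at$chain %in% names(keep_roles), , drop = FALSE]
  if (!nrow(at)) stop("no atoms left after chain filtering")

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: one atom per (chain, resno, insert, name);
  # highest occupancy wins, ties prefer altloc 'A' (blank counts as 'A').
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  altord <- ifelse(at$alt %in% c("", "A"), 0L, match(at$alt, LETTERS))
  ord <- order(key, -at$o, altord)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), , drop = FALSE]

  # stable order: role (mhc first), chain, residue, atom
  role <- unname(keep_roles[at$chain])
  at <- at[order(match(role, c("mhc", "peptide")), at$chain, at$resno, at$insert), , drop = FALSE]
  role <- unname(keep_roles[at$chain])

  element <- at$elesy
  element[is.na(element) | element == ""] <- element_from_name(at$elety[is.na(element) | element == ""])
  element <- toupper(trimws(element))

  atoms <- data.frame(
    name = trimws(at$elety), element = element,
    x = at$x, y = at$y, z = at$z,
    resid = at$resid, resno = at$resno, insert = at$insert,
    chain = at$chain, role = role, occ = at$o,
    class = NA_character_,
    radius = unname(ifelse(element %in% names(radii), radii[element], radii["X"])),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in input")
  }

  # residues must carry a complete backbone for the geometry downstream
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert)
  for (rk in unique(rkey)) {
    sel <- rkey == rk
    if (atoms$resid[sel][1] %in% names(SIDECHAIN_TEMPLATES) || atoms$resid[sel][1] == "GLY") {
      if (!all(c("N", "CA", "C") %in% atoms$name[sel])) {
        stop("residue ", atoms$resid[sel][1], " ", rk,
             " lacks backbone N/CA/C atoms")
      }
    }
  }

  pep <- atoms[atoms$role == "peptide", , drop = FALSE]
  pres <- unique(paste(pep$resno, pep$insert, sep = "|"))
  pseq <- vapply(pres, function(k) {
    r3 <- pep$resid[paste(pep$resno, pep$insert, sep = "|") == k][1]
    if (r3 %in% names(AA1)) unname(AA1[r3]) else "X"
  }, character(1))

  structure(list(
    atoms = atoms,
    peptide_sequence = paste(pseq, collapse = ""),
    pdb_id = pdb_id,
    resolution = resolution,
    chain_roles = chain_roles
  ), class = "complex_structure")
}

.parse_resolution <- function(lines) {
  hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
  if (!length(m)) NA_real_ else as.numeric(m)
}

#' Write a complex back to PDB-format text
#'
#' Emits standard fixed-width ATOM records (wwPDB v3.3 columns) with TER
#' records between chains; coordinates keep three decimals, so a write/read
#' round trip preserves them to 0.001 Angstrom.
#'
#' @param c a `complex_structure`
#' @param path optional output file; when `NULL` the text is returned
#' @return invisibly, the character vector of PDB lines
#' @export
write_complex <- function(c, path = NULL) {
  at <- c$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sel <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      serial <- serial + 1L
      nm <- sel$name[i]
      # PDB name field: element right-justified in cols 13-14 for short names
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nmf, sel$resid[i], ch, sel$resno[i],
        ifelse(sel$insert[i] == "", " ", sel$insert[i]),
        sel$x[i], sel$y[i], sel$z[i], sel$occ[i], 0, sel$element[i]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L, sel$resid[nrow(sel)], ch,
                              sel$resno[nrow(sel)]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure>", x$pdb_id, "\n")
  cat("  peptide:", x$peptide_sequence,
      sprintf("(%d residues)", nchar(x$peptide_sequence)), "\n")
  cat("  atoms:", sum(x$atoms$role == "mhc"), "MHC /",
      sum(x$atoms$role == "peptide"), "peptide",
      if (any(x$atoms$element == "H")) "(protonated)" else "", "\n")
  if (!is.na(x$resolution)) cat("  resolution:", x$resolution, "A\n")
  invisible(x)
}

#' Extract the MHC or peptide atoms of a complex
#' @param c a `complex_structure`
#' @return data frame of atoms
#' @export
mhc_atoms <- function(c) c$atoms[c$atoms$role == "mhc", , drop = FALSE]

#' @rdname mhc_atoms
#' @export
peptide_atoms <- function(c) c$atoms[c$atoms$role == "peptide", , drop = FALSE]

#' Residue keys (chain|resno|insert) in atom order
#' @noRd
residue_keys <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
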