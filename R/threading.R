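# Thread a new peptide sequence onto the backbone of a reference complex.
# Backbone atoms are copied verbatim; mutated side chains are rebuilt from
# idealised internal coordinates with a small canonical rotamer search
# (each rotatable chi in {-60, 60, 180} degrees), placed greedily from the
# N- to the C-terminus minimising steric clashes with the MHC and with the
# already-placed peptide atoms.  Externally rebuilt models (e.g. from a
# dedicated side-chain packer) can be supplied as pre-threaded PDB files
# and read with read_complex() instead.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

.graph_cache <- new.env(parent = emptyenv())

# intra-residue heavy-atom graph distances (capped at 3)
residue_graph_dist <- function(resid) {
  if (!is.null(.graph_cache[[resid]])) return(.graph_cache[[resid]])
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  atoms <- c("N", "CA", "C", "O", "OXT", if (!is.null(tpl)) tpl$name)
  n <- length(atoms)
  D <- matrix(Inf, n, n, dimnames = list(atoms, atoms))
  diag(D) <- 0
  for (b in residue_bonds(resid)) {
    if (all(b %in% atoms)) D[b[1], b[2]] <- D[b[2], b[1]] <- 1
  }
  for (k in 1:2) {              # two rounds of relaxation reach distance 3
    for (i in seq_len(n)) for (j in seq_len(n)) {
      D[i, j] <- min(D[i, j], min(D[i, ] + D[, j]))
    }
  }
  .graph_cache[[resid]] <- D
  D
}

#' Count steric clashes in a complex
#'
#' Number of non-bonded heavy-atom pairs, peptide side-chain atom against
#' any other atom, whose distance is below `0.8 * (r_i + r_j)`.  Pairs at
#' intra-residue graph distance <= 2 (1-2 and 1-3 neighbours) are excluded;
#' pairs between different residues are always counted.  Pairs of two
#' side-chain atoms are counted once.
#'
#' @param c a `complex_structure` with radii assigned
#' @param factor clash threshold as a fraction of the radius sum
#' @return non-negative integer
#' @export
clash_count <- function(c, factor = 0.8) {
  at <- c$atoms[c$atoms$element != "H", , drop = FALSE]
  sc <- which(at$role == "peptide" & !(at$name %in% BACKBONE_NAMES))
  if (!length(sc)) return(0L)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rkey <- residue_keys(at)
  n_cl <- 0L
  for (i in sc) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    thr <- factor * (at$radius[i] + at$radius)
    hit <- which(d < thr)
    hit <- hit[hit != i]
    for (j in hit) {
      if (rkey[j] == rkey[i]) {
        D <- residue_graph_dist(at$resid[i])
        if (at$name[i] %in% rownames(D) && at$name[j] %in% rownames(D) &&
            D[at$name[i], at$name[j]] <= 2) next
      }
      # count unordered side-chain/side-chain pairs once
      if (j %in% sc && j < i) next
      n_cl <- n_cl + 1L
    }
  }
  n_cl
}

# clashes of a candidate side-chain placement against fixed context atoms
.cand_clashes <- function(cand_xyz, cand_rad, cand_names, resid,
                          ctx_xyz, ctx_rad, ctx_names, ctx_same_res,
                          factor = 0.8) {
  D <- residue_graph_dist(resid)
  n_cl <- 0L
  for (k in seq_len(nrow(cand_xyz))) {
    d <- sqrt(colSums((t(ctx_xyz) - cand_xyz[k, ])^2))
    hit <- which(d < factor * (cand_rad[k] + ctx_rad))
    for (j in hit) {
      if (ctx_same_res[j] && ctx_names[j] %in% rownames(D) &&
          cand_names[k] %in% rownames(D) &&
          D[cand_names[k], ctx_names[j]] <= 2) next
      n_cl <- n_cl + 1L
    }
    # intra-candidate pairs (rings etc.) beyond 1-3
    if (k > 1) {
      for (m in seq_len(k - 1)) {
        dkm <- sqrt(sum((cand_xyz[k, ] - cand_xyz[m, ])^2))
        if (dkm < factor * (cand_rad[k] + cand_rad[m]) &&
            D[cand_names[k], cand_names[m]] > 2) n_cl <- n_cl + 1L
      }
    }
  }
  n_cl
}

# build side-chain atom coordinates for a residue from its template
# given backbone N/CA/C coordinates and a chi vector
.build_sidechain <- function(resid, bb, chis) {
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  if (is.null(tpl)) return(NULL)
  pos <- list(N = bb$N, CA = bb$CA, C = bb$C)
  out <- matrix(NA_real_, nrow(tpl), 3, dimnames = list(tpl$name, NULL))
  for (i in seq_len(nrow(tpl))) {
    dih <- if (tpl$chi[i] > 0) chis[tpl$chi[i]] + tpl$off[i] else tpl$off[i]
    xyz <- place_atom(pos[[tpl$ggp[i]]], pos[[tpl$gp[i]]], pos[[tpl$p[i]]],
                      tpl$bond[i], tpl$angle[i], dih)
    pos[[tpl$name[i]]] <- xyz
    out[i, ] <- xyz
  }
  out
}

.n_chis <- function(resid) {
  tpl <- SIDECHAIN_TEMPLATES[[resid]]
  if (is.null(tpl)) 0L else max(0L, tpl$chi)
}

#' Thread a peptide sequence onto a reference complex
#'
#' The new peptide keeps the reference backbone (N, CA, C, O) exactly.
#' Positions whose residue is unchanged keep their native side-chain
#' coordinates; mutated positions are rebuilt from idealised geometry,
#' scanning every combination of canonical chi values ({-60, 60, 180}
#' degrees per rotatable bond) and keeping the placement with the fewest
#' clashes against the MHC and the already-placed peptide atoms (greedy,
#' N- to C-terminal; ties broken by the smallest absolute chi sum, then
#' enumeration order).  MHC atoms are never touched.  Hydrogens are
#' dropped; run [prepare_complex()] on the result before scoring.
#'
#' @param reference a `complex_structure`
#' @param sequence one-letter peptide sequence, same length as the
#'   reference peptide
#' @param keep_identical keep native side-chain coordinates where the
#'   sequence letter matches the reference (default TRUE)
#' @return a `complex_structure` for the threaded model; attribute
#'   `rotamer_choices` records per-position chi angles and clash counts
#' @export
thread_peptide <- function(reference, sequence, keep_identical = TRUE) {
  sequence <- toupper(sequence)
  refseq <- reference$peptide_sequence
  if (nchar(sequence) != nchar(refseq)) {
    stop("peptide length mismatch: reference has ", nchar(refseq),
         " residues, query has ", nchar(sequence),
         " (only peptides matching the reference length can be threaded)")
  }
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(AA3))
  if (length(bad)) stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))

  at <- reference$atoms[reference$atoms$element != "H", , drop = FALSE]
  mhc <- at[at$role == "mhc", , drop = FALSE]
  pep <- at[at$role == "peptide", , drop = FALSE]
  pkeys <- unique(residue_keys(pep))

  # pass 1: backbone + retained native side chains
  res_rows <- vector("list", length(pkeys))
  rebuild <- logical(length(pkeys))
  for (i in seq_along(pkeys)) {
    sel <- pep[residue_keys(pep) == pkeys[i], , drop = FALSE]
    new3 <- unname(AA3[letters1[i]])
    same <- identical(sel$resid[1], new3)
    keep <- if (same && keep_identical) sel else sel[sel$name %in% BACKBONE_NAMES, , drop = FALSE]
    keep$resid <- new3
    res_rows[[i]] <- keep
    rebuild[i] <- !(same && keep_identical)
  }

  # pass 2: greedy N->C side-chain construction for rebuilt positions
  choices <- data.frame(residue_index = integer(0), chi1 = numeric(0),
                        chi2 = numeric(0), chi3 = numeric(0), chi4 = numeric(0),
                        clash_count = integer(0))
  for (i in seq_along(pkeys)) {
    if (!rebuild[i]) next
    resi <- res_rows[[i]]
    new3 <- resi$resid[1]
    bb <- list(N = .xyz_of(resi, "N"), CA = .xyz_of(resi, "CA"), C = .xyz_of(resi, "C"))
    if (any(vapply(bb, is.null, logical(1)))) {
      stop("peptide residue ", pkeys[i], " lacks backbone atoms for threading")
    }
    nchi <- .n_chis(new3)
    if (new3 %in% c("GLY")) { choices <- rbind(choices,
        data.frame(residue_index = i - 1L, chi1 = NA, chi2 = NA, chi3 = NA,
                   chi4 = NA, clash_count = 0L)); next }
    combos <- if (nchi == 0 || new3 == "PRO") {
      matrix(0, 1, max(1, nchi))
    } else {
      as.matrix(expand.grid(rep(list(c(-60, 60, 180)), nchi)))
    }
    ctx <- rbind(mhc, do.call(rbind, res_rows[seq_along(pkeys) != i]),
                 resi[resi$name %in% BACKBONE_NAMES, , drop = FALSE])
    ctx_xyz <- as.matrix(ctx[, c("x", "y", "z")])
    ctx_same <- residue_keys(ctx) == pkeys[i] & ctx$chain == resi$chain[1]
    radii <- load_radius_table()
    best <- NULL
    for (ci in seq_len(nrow(combos))) {
      chis <- combos[ci, ]
      sc <- .build_sidechain(new3, bb, chis)
      rad <- unname(ifelse(element_from_name(rownames(sc)) %in% names(radii),
                           radii[element_from_name(rownames(sc))], radii["X"]))
      ncl <- .cand_clashes(sc, rad, rownames(sc), new3,
                           ctx_xyz, ctx$radius, ctx$name, ctx_same)
      score <- c(ncl, sum(abs(chis)), ci)
      if (is.null(best) || ncl < best$score[1] ||
          (ncl == best$score[1] && score[2] < best$score[2])) {
        best <- list(sc = sc, rad = rad, chis = chis, score = score)
      }
    }
    scdf <- resi[rep(1, nrow(best$sc)), , drop = FALSE]
    scdf$name <- rownames(best$sc)
    scdf$element <- element_from_name(scdf$name)
    scdf$x <- best$sc[, 1]; scdf$y <- best$sc[, 2]; scdf$z <- best$sc[, 3]
    scdf$radius <- best$rad
    scdf$class <- NA_character_
    res_rows[[i]] <- rbind(resi[resi$name %in% BACKBONE_NAMES, , drop = FALSE], scdf)
    chis4 <- rep(NA_real_, 4)
    if (.n_chis(new3) > 0 && new3 != "PRO") chis4[seq_along(best$chis)] <- best$chis
    choices <- rbind(choices, data.frame(
      residue_index = i - 1L, chi1 = chis4[1], chi2 = chis4[2],
      chi3 = chis4[3], chi4 = chis4[4], clash_count = best$score[1]))
  }

  out <- reference
  out$atoms <- rbind(mhc, do.call(rbind, res_rows))
  rownames(out$atoms) <- NULL
  out$atoms$class <- NA_character_
  out$peptide_sequence <- sequence
  out$pdb_id <- paste0(reference$pdb_id, ":", sequence)
  attr(out, "rotamer_choices") <- choices
  out
}
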