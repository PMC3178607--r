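# Reference-set experiments: how the choice of reference crystal
# structures, and their mutual structural similarity, governs the
# predictive power of the calibrated scoring function.

#' Least-squares rigid superposition (Kabsch) and RMSD
#'
#' Superposes structure `b` onto structure `a` over matched heavy atoms
#' (matched by chain role, residue index within that role, and atom name)
#' and reports the optimal rotation, translation and RMSD.  `selection`
#' restricts matching to the MHC atoms, the peptide atoms, or the whole
#' complex.
#'
#' @param a,b `complex_structure` objects
#' @param selection `"whole"`, `"mhc"` or `"peptide"`
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_atoms_matched`
#' @export
superpose_structures <- function(a, b, selection = c("whole", "mhc", "peptide")) {
  selection <- match.arg(selection)
  ma <- .match_frame(a, selection)
  mb <- .match_frame(b, selection)
  key <- intersect(ma$key, mb$key)
  if (length(key) < 3) {
    stop("fewer than 3 matched atoms between ", a$pdb_id, " and ", b$pdb_id,
         " (selection ", selection, ")")
  }
  P <- as.matrix(mb[match(key, mb$key), c("x", "y", "z")])   # moving
  Q <- as.matrix(ma[match(key, ma$key), c("x", "y", "z")])   # target
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  C <- crossprod(Pc, Qc)
  sv <- svd(C)
  dsign <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, dsign)) %*% t(sv$v)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = t(R),
                 translation = cq - drop(cp %*% R),
                 rmsd = rmsd, n_atoms_matched = length(key)),
            class = "superposition")
}

.match_frame <- function(c, selection) {
  at <- c$atoms[c$atoms$element != "H", , drop = FALSE]
  if (selection != "whole") at <- at[at$role == selection, , drop = FALSE]
  # residue index within each role, in atom order
  idx <- integer(nrow(at))
  for (r in unique(at$role)) {
    sel <- at$role == r
    rk <- residue_keys(at[sel, , drop = FALSE])
    idx[sel] <- match(rk, unique(rk))
  }
  at$key <- paste(at$role, idx, at$name, sep = "|")
  at[!duplicated(at$key), , drop = FALSE]
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd =", format(x$rmsd, digits = 4), "A over",
      x$n_atoms_matched, "atoms\n")
  invisible(x)
}

#' Mean pairwise RMSD of a set of structures
#'
#' Unweighted mean of [superpose_structures()] RMSDs over all unordered
#' pairs.
#'
#' @param structures list of `complex_structure` (length >= 2)
#' @param selection passed to [superpose_structures()]
#' @return mean RMSD in Angstrom
#' @export
mean_pairwise_rmsd <- function(structures, selection = "whole") {
  n <- length(structures)
  stopifnot(n >= 2)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, superpose_structures(structures[[i]], structures[[j]],
                                         selection)$rmsd)
  }
  mean(vals)
}

#' Spearman rank correlation
#'
#' Pearson correlation of the rank vectors, with average ranks for ties.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in `[-1, 1]`
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    stop("rank variance is zero; Spearman correlation undefined")
  }
  stats::cor(rx, ry)
}

#' Enumerate reference-structure combinations
#'
#' Structures are grouped by their native peptide.  Every group with a
#' single structure contributes that structure to every set; for each
#' group with several structures, exactly one is chosen.  The result is
#' the Cartesian product over the multi-structure groups, in deterministic
#' lexicographic order (groups by peptide, members by PDB id), so the set
#' count is the product of the multi-group sizes.
#'
#' @param table data frame with columns `pdb_id` and `peptide`
#' @return list of reference sets; each has `set_id` and a `members`
#'   data frame (pdb_id, peptide)
#' @export
enumerate_reference_sets <- function(table) {
  stopifnot(nrow(table) > 0, all(c("pdb_id", "peptide") %in% names(table)))
  groups <- split(table$pdb_id, table$peptide)
  groups <- lapply(groups, sort)
  groups <- groups[order(names(groups))]
  multi <- groups[lengths(groups) > 1]
  single <- unlist(groups[lengths(groups) == 1], use.names = FALSE)
  if (!length(multi)) {
    combos <- matrix(character(0), nrow = 1, ncol = 0)
  } else {
    grid <- expand.grid(rev(multi), stringsAsFactors = FALSE)
    combos <- as.matrix(grid[, rev(seq_along(multi)), drop = FALSE])
    colnames(combos) <- names(multi)
  }
  pep_of <- stats::setNames(table$peptide, table$pdb_id)
  out <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ids <- c(single, unname(combos[i, ]))
    out[[i]] <- list(
      set_id = sprintf("set%03d", i),
      members = data.frame(pdb_id = ids, peptide = unname(pep_of[ids]),
                           stringsAsFactors = FALSE)
    )
  }
  out
}

#' Run the reference-set experiment
#'
#' For every reference set, the native complex of each member is scored
#' (terms from its own crystal structure), the term matrix is calibrated
#' against the members' experimental binding free energies by PLS, and
#' leave-one-out q2 / S_press are recorded together with the set's mean
#' pairwise RMSD (whole / MHC / peptide selections) and mean resolution.
#' Finally q2 and S_press are rank-correlated (Spearman) against each
#' structural descriptor across sets.
#'
#' Sets whose descriptor matrix is degenerate (zero variance) are flagged
#' with `NA` q2 rather than dropped silently.
#'
#' @param sets list from [enumerate_reference_sets()]
#' @param bindings binding records with `peptide` and `dg_bind` columns
#' @param structures named list of prepared `complex_structure`s keyed by
#'   pdb_id (see [prepare_complex()])
#' @param params term parameters
#' @param n_components PLS components (default `min(5, n - 2)` per set)
#' @param external_desolv optional named desolvation table (kJ/mol)
#' @return list with `results` (one row per set: q2, s_press, rmsd_whole,
#'   rmsd_mhc, rmsd_peptide, mean_resolution) and `correlations`
#'   (Spearman rho of q2 and S_press against each descriptor)
#' @export
run_refset_experiment <- function(sets, bindings, structures,
                                  params = term_params(), n_components = NULL,
                                  external_desolv = NULL) {
  ids <- unique(unlist(lapply(sets, function(s) s$members$pdb_id)))
  missing_s <- setdiff(ids, names(structures))
  if (length(missing_s)) {
    stop("no structure provided for set member(s): ",
         paste(missing_s, collapse = ", "))
  }
  backend <- if (is.null(external_desolv)) "sasa" else "external"
  term_cache <- lapply(structures[ids], function(s) {
    compute_terms(s, params, backend = backend, external_table = external_desolv)
  })
  rmsd_cache <- new.env(parent = emptyenv())
  pair_rmsd <- function(i1, i2, sel) {
    k <- paste(sort(c(i1, i2))[1], sort(c(i1, i2))[2], sel)
    if (is.null(rmsd_cache[[k]])) {
      rmsd_cache[[k]] <- superpose_structures(structures[[i1]], structures[[i2]], sel)$rmsd
    }
    rmsd_cache[[k]]
  }
  set_rmsd <- function(members, sel) {
    v <- c()
    for (i in seq_len(nrow(members) - 1)) for (j in (i + 1):nrow(members)) {
      v <- c(v, pair_rmsd(members$pdb_id[i], members$pdb_id[j], sel))
    }
    mean(v)
  }

  rows <- lapply(sets, function(s) {
    m <- s$members
    dg <- bindings$dg_bind[match(m$peptide, bindings$peptide)]
    if (any(is.na(dg))) {
      stop("no binding record for peptide(s): ",
           paste(m$peptide[is.na(dg)], collapse = ", "), " in ", s$set_id)
    }
    tm <- do.call(rbind, term_cache[m$pdb_id])
    X <- as.matrix(tm[, c("HB", "LIPO", "BP", "ROT", "DESOLV")])
    rownames(X) <- m$pdb_id
    cv <- tryCatch({
      nc <- if (is.null(n_components)) max(1L, min(5L, nrow(X) - 2L)) else n_components
      loocv_pls(X, dg, n_components = nc)
    }, error = function(e) NULL)
    res <- vapply(structures[m$pdb_id], function(s) s$resolution, numeric(1))
    data.frame(
      set_id = s$set_id,
      members = paste(m$pdb_id, collapse = "+"),
      n = nrow(m),
      q2 = if (is.null(cv)) NA_real_ else cv$q2,
      s_press = if (is.null(cv)) NA_real_ else cv$s_press,
      rmsd_whole = set_rmsd(m, "whole"),
      rmsd_mhc = set_rmsd(m, "mhc"),
      rmsd_peptide = tryCatch(set_rmsd(m, "peptide"), error = function(e) NA_real_),
      mean_resolution = if (all(is.na(res))) NA_real_ else mean(res, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  results <- do.call(rbind, rows)

  ok <- !is.na(results$q2)
  corr_against <- function(metric) {
    vapply(c("rmsd_whole", "rmsd_mhc", "rmsd_peptide", "mean_resolution"),
           function(d) {
             v <- results[[d]][ok]
             if (sum(!is.na(v)) < 3) return(NA_real_)
             tryCatch(spearman_rho(results[[metric]][ok][!is.na(v)], v[!is.na(v)]),
                      error = function(e) NA_real_)
           }, numeric(1))
  }
  correlations <- data.frame(
    descriptor = c("rmsd_whole", "rmsd_mhc", "rmsd_peptide", "mean_resolution"),
    q2 = unname(corr_against("q2")),
    s_press = unname(corr_against("s_press")),
    stringsAsFactors = FALSE
  )
  list(results = results, correlations = correlations)
}
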