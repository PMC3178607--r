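# Independent reference implementations used as oracles.  These are
# deliberately naive (plain loops, no shared helpers with the package
# internals) so they can catch errors in the vectorised code paths.

blockf <- function(x, x1, x2) {
  if (x <= x1) 1 else if (x >= x2) 0 else (x2 - x) / (x2 - x1)
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

.coords <- function(at, i) c(at$x[i], at$y[i], at$z[i])

# exhaustive-loop hydrogen-bond sum over all donor-H / acceptor triples
oracle_hb <- function(atoms, d_ideal = 1.85, d1 = 0.25, d2 = 0.65,
                      a1 = 30, a2 = 80) {
  total <- 0
  hs <- which(atoms$element == "H")
  accs <- which(atoms$class %in% c("acceptor", "donor_acceptor") & atoms$element != "H")
  for (h in hs) {
    # parent = nearest heavy atom in the same residue
    same <- which(atoms$element != "H" & atoms$chain == atoms$chain[h] &
                  atoms$resno == atoms$resno[h] & atoms$insert == atoms$insert[h])
    if (!length(same)) next
    dd <- vapply(same, function(j) .dist3(.coords(atoms, h), .coords(atoms, j)), 0)
    par <- same[which.min(dd)]
    if (min(dd) > 1.25) next
    if (!(atoms$class[par] %in% c("donor", "donor_acceptor"))) next
    for (a in accs) {
      if (atoms$role[a] == atoms$role[par]) next
      dha <- .dist3(.coords(atoms, h), .coords(atoms, a))
      v1 <- .coords(atoms, par) - .coords(atoms, h)
      v2 <- .coords(atoms, a) - .coords(atoms, h)
      theta <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      total <- total + blockf(abs(dha - d_ideal), d1, d2) * blockf(abs(theta - 180), a1, a2)
    }
  }
  total
}

# exhaustive pair-loop for LIPO/BP-style kernels
oracle_pair_sum <- function(atoms, cls_mhc, cls_pep, offset = 0.5, width = 3.0) {
  total <- 0
  for (i in which(atoms$role == "mhc" & atoms$class %in% cls_mhc)) {
    for (j in which(atoms$role == "peptide" & atoms$class %in% cls_pep)) {
      d <- .dist3(.coords(atoms, i), .coords(atoms, j))
      r1 <- atoms$radius[i] + atoms$radius[j] + offset
      total <- total + blockf(d, r1, r1 + width)
    }
  }
  total
}

oracle_bp <- function(atoms, polar = c("donor", "acceptor", "donor_acceptor")) {
  oracle_pair_sum(atoms, "lipophilic", polar) +
    oracle_pair_sum(atoms, polar, "lipophilic")
}

# exhaustive clash pair loop (peptide side chain vs anything, 1-2/1-3
# neighbours excluded via a crude same-residue bonded-distance check)
oracle_clashes <- function(cx, factor = 0.8) {
  at <- cx$atoms[cx$atoms$element != "H", ]
  bb <- c("N", "CA", "C", "O", "OXT")
  sc <- which(at$role == "peptide" & !(at$name %in% bb))
  seen <- character(0)
  n <- 0L
  for (i in sc) {
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      same_res <- at$chain[j] == at$chain[i] & at$resno[j] == at$resno[i] &
        at$insert[j] == at$insert[i]
      if (same_res) {
        D <- groovescore:::residue_graph_dist(at$resid[i])
        if (at$name[i] %in% rownames(D) && at$name[j] %in% rownames(D) &&
            D[at$name[i], at$name[j]] <= 2) next
      }
      d <- .dist3(.coords(at, i), .coords(at, j))
      if (d >= factor * (at$radius[i] + at$radius[j])) next
      key <- paste(sort(c(i, j)), collapse = "-")
      if (j %in% sc && key %in% seen) next
      seen <- c(seen, key)
      n <- n + 1L
    }
  }
  n
}

# Horn quaternion superposition: independent of the SVD/Kabsch route
oracle_quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- t(Pc) %*% Qc
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# rank-then-Pearson Spearman with average ties, written out longhand
oracle_spearman <- function(x, y) {
  rk <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force LOOCV via lm() refits (full-rank, all-component case)
oracle_loocv_lm <- function(X, y) {
  n <- nrow(X)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    preds[i] <- stats::predict(fit, newdata = as.data.frame(X)[i, , drop = FALSE])
  }
  press <- sum((y - preds)^2)
  list(predictions = preds, q2 = 1 - press / sum((y - mean(y))^2),
       s_press = sqrt(press / n))
}

# a small realistic-geometry tripeptide complex builder used across tests:
# one MHC glycine strand next to a peptide strand, close enough to interact
make_close_complex <- function(pep_seq = "SAL", gap = 4.5, seed = 1,
                               mhc_seq = NULL) {
  fx <- make_toy_complex(toy_fixture_spec(seed = seed))
  geo <- asNamespace("groovescore")
  pa <- geo$place_atom
  build_strand <- function(nres, resids, chain, origin) {
    at <- list()
    prevC <- NULL; prevCA <- NULL; prevN <- NULL
    for (i in seq_len(nres)) {
      if (is.null(prevC)) {
        N <- origin; CA <- origin + c(1.458, 0, 0)
        C <- pa(origin + c(0, 1, 0), N, CA, 1.525, 111.2, -60)
      } else {
        N <- pa(prevN, prevCA, prevC, 1.329, 116.2, 180)
        CA <- pa(prevCA, prevC, N, 1.458, 121.7, 180)
        C <- pa(prevC, N, CA, 1.525, 111.2, -60)
      }
      O <- pa(N, CA, C, 1.231, 120.8, 0)
      rs <- resids[i]
      at[[length(at) + 1]] <- data.frame(
        name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
        x = c(N[1], CA[1], C[1], O[1]), y = c(N[2], CA[2], C[2], O[2]),
        z = c(N[3], CA[3], C[3], O[3]),
        resid = rs, resno = i, insert = "", chain = chain,
        occ = 1, stringsAsFactors = FALSE)
      if (rs != "GLY") {
        tpl <- groovescore:::SIDECHAIN_TEMPLATES[[rs]]
        nchi <- max(0, tpl$chi)
        sc <- geo$.build_sidechain(rs, list(N = N, CA = CA, C = C),
                                   chis = rep(180, max(1, nchi)))
        at[[length(at) + 1]] <- data.frame(
          name = rownames(sc), element = groovescore:::element_from_name(rownames(sc)),
          x = sc[, 1], y = sc[, 2], z = sc[, 3],
          resid = rs, resno = i, insert = "", chain = chain,
          occ = 1, stringsAsFactors = FALSE)
      }
      prevN <- N; prevCA <- CA; prevC <- C
    }
    do.call(rbind, at)
  }
  aa3 <- groovescore:::AA3
  pep <- build_strand(nchar(pep_seq), unname(aa3[strsplit(pep_seq, "")[[1]]]),
                      "C", c(0, 0, 0))
  if (is.null(mhc_seq)) mhc_seq <- "GGGG"
  mhc <- build_strand(nchar(mhc_seq), unname(aa3[strsplit(mhc_seq, "")[[1]]]),
                      "A", c(0, gap, 1.0))
  at <- rbind(mhc, pep)
  radii <- load_radius_table()
  at$role <- ifelse(at$chain == "A", "mhc", "peptide")
  at$class <- NA_character_
  at$radius <- unname(radii[at$element])
  cx <- structure(list(atoms = at, peptide_sequence = pep_seq, pdb_id = "close",
                       resolution = NA_real_,
                       chain_roles = c(A = "mhc", C = "peptide")),
                  class = "complex_structure")
  cx
}

rigid_move <- function(cx, angle = 0.35, axis = c(0, 0, 1), shift = c(3, -7, 11)) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  R <- ct * diag(3) + st * matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) +
    (1 - ct) * (u %o% u)
  xyz <- as.matrix(cx$atoms[, c("x", "y", "z")]) %*% R
  cx$atoms$x <- xyz[, 1] + shift[1]
  cx$atoms$y <- xyz[, 2] + shift[2]
  cx$atoms$z <- xyz[, 3] + shift[3]
  cx
}
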