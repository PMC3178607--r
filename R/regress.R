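# Calibration of the scoring-function coefficients: PLS1 (NIPALS) with
# leave-one-out cross-validation, reporting q2 and S_press (RMSEP).

#' Fit a partial-least-squares model of binding free energy on the terms
#'
#' PLS1 by the NIPALS algorithm on mean-centred (and by default
#' unit-variance-scaled) descriptor columns.  With as many components as
#' the descriptor rank, the training predictions coincide with ordinary
#' least squares; with fewer, collinear descriptors are handled gracefully
#' (the usual reason to prefer PLS on correlated interaction terms).
#'
#' @param X numeric matrix, n x p (rows = complexes, columns = terms)
#' @param y numeric vector of experimental binding free energies (kJ/mol)
#' @param n_components number of latent components, 1..p; default
#'   `min(p, n - 2)`
#' @param scale unit-variance scale the columns (default TRUE)
#' @return object of class `groove_pls`: coefficients and intercept on the
#'   original scale, plus centring/scaling and training metadata
#' @export
fit_pls <- function(X, y, n_components = NULL, scale = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 training rows")
  if (length(y) != n) stop("X and y sizes disagree")
  if (is.null(n_components)) n_components <- max(1L, min(p, n - 2L))
  if (n_components < 1 || n_components > p) stop("n_components must be in 1..ncol(X)")

  xbar <- colMeans(X)
  xsd <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  xsd[xsd < 1e-12] <- 1      # constant column: leave unscaled (coefficient 0)
  Xs <- sweep(sweep(X, 2, xbar), 2, xsd, "/")
  ybar <- mean(y)
  ys <- y - ybar

  if (stats::sd(y) < 1e-12) {
    # degenerate target: zero coefficients, intercept = mean
    coefs <- stats::setNames(rep(0, p), colnames(X))
    return(structure(list(coefficients = coefs, intercept = ybar,
                          centering = xbar, scaling = xsd, scale = scale,
                          n_components = 0L, n = n,
                          training_ids = rownames(X)),
                     class = "groove_pls"))
  }

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  qv <- numeric(n_components)
  Xr <- Xs; yr <- ys
  for (h in seq_len(n_components)) {
    w <- crossprod(Xr, yr)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-10) {
      stop("descriptor matrix rank (", h - 1L,
           ") is below the requested number of components (", n_components, ")")
    }
    w <- w / nw
    t <- Xr %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) stop("degenerate latent component ", h)
    pvec <- crossprod(Xr, t)[, 1] / tt
    qh <- sum(yr * t) / tt
    W[, h] <- w; P[, h] <- pvec; qv[h] <- qh
    Xr <- Xr - t %*% t(pvec)
    yr <- yr - qh * t
  }
  Bstar <- W %*% solve(t(P) %*% W, qv)        # coefficients on scaled X
  coefs <- (Bstar[, 1] / xsd)
  names(coefs) <- colnames(X)
  intercept <- ybar - sum(coefs * xbar)
  structure(list(coefficients = coefs, intercept = intercept,
                 centering = xbar, scaling = xsd, scale = scale,
                 n_components = as.integer(n_components), n = n,
                 training_ids = rownames(X)),
            class = "groove_pls")
}

#' @export
print.groove_pls <- function(x, ...) {
  cat("<groove_pls>", x$n_components, "component(s),", x$n, "training rows\n")
  cat("  intercept:", format(x$intercept, digits = 4), "kJ/mol\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict binding free energy from a term vector
#'
#' @param object a fitted `groove_pls` model
#' @param newdata numeric vector, matrix or data frame of term values in
#'   the training column order (data frames may carry a `complex_id`
#'   column, which is ignored)
#' @param ... unused
#' @return predicted dG_bind in kJ/mol
#' @export
predict.groove_pls <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, setdiff(names(newdata), "complex_id"), drop = FALSE])
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  drop(object$intercept + newdata %*% object$coefficients)
}

#' Leave-one-out cross-validation of the PLS calibration
#'
#' For each row i the model is refit on the remaining n - 1 rows (a
#' genuine refit loop, no shortcut formulas) and row i is predicted.
#' `PRESS = sum (y_i - yhat_(-i))^2`, `q2 = 1 - PRESS / sum (y_i - ybar)^2`
#' and `S_press = sqrt(PRESS / n)` (the RMSEP cross-validation estimator).
#' Folds follow input order; nothing here is randomised.
#'
#' @inheritParams fit_pls
#' @return list of class `groove_cv`: `q2`, `s_press`, `press`,
#'   `predictions` (named per-fold predictions), `n`
#' @export
loocv_pls <- function(X, y, n_components = NULL, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("leave-one-out cross-validation needs at least 4 rows")
  if (stats::sd(y) < 1e-12) stop("q2 is undefined for a zero-variance response")
  if (is.null(n_components)) n_components <- max(1L, min(ncol(X), n - 3L))
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components = n_components,
                   scale = scale)
    preds[i] <- predict(fit, X[i, ])
  }
  press <- sum((y - preds)^2)
  structure(list(
    q2 = 1 - press / sum((y - mean(y))^2),
    s_press = sqrt(press / n),
    press = press,
    predictions = stats::setNames(preds, ids),
    n = n,
    n_components = as.integer(n_components)
  ), class = "groove_cv")
}

#' @export
print.groove_cv <- function(x, ...) {
  cat("<groove_cv> n =", x$n, " q2 =", format(x$q2, digits = 4),
      " S_press =", format(x$s_press, digits = 4), "kJ/mol\n")
  invisible(x)
}

#' Choose the component count minimising PRESS
#'
#' Runs [loocv_pls()] for 1..`max_components` latent components and returns
#' the count with the lowest PRESS (the "optimised for each dataset"
#' selection rule).
#'
#' @inheritParams fit_pls
#' @param max_components upper bound on components tried
#' @return integer component count
#' @export
select_components <- function(X, y, max_components = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(max_components)) max_components <- min(ncol(X), nrow(X) - 3L)
  max_components <- max(1L, max_components)
  press <- vapply(seq_len(max_components), function(h) {
    tryCatch(loocv_pls(X, y, n_components = h, scale = scale)$press,
             error = function(e) Inf)
  }, numeric(1))
  which.min(press)
}
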