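#' SIMPLS partial least squares regression
#'
#' Compact SIMPLS (de Jong 1993) for a single response: columns of `X` and
#' `y` are mean-centred, latent components extracted sequentially, and
#' regression coefficients returned for every component count up to `ncomp`.
#' This kernel backs both the CARS selector (which refits it thousands of
#' times inside Monte-Carlo/CV loops) and the PLS-DA baseline.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Numeric response vector.
#' @param ncomp Maximum number of latent components; silently truncated to
#'   the effective rank encountered.
#' @return List of class `simpls_fit`: `coef` (p x ncomp_eff matrix, one
#'   column per component count), `intercept`, `ncomp`, `xmeans`, `ymean`.
#' @export
simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  ncomp <- min(ncomp, p, n - 1L)
  if (ncomp < 1L) stop("too few samples/variables for PLS")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  s <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp); Q <- numeric(ncomp); V <- matrix(0, p, ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12 * max(1, sqrt(sum(Xc^2)))) break   # rank exhausted
    t <- t / nt; r <- r / nt
    pl <- crossprod(Xc, t)
    q <- sum(yc * t)
    v <- pl
    if (a > 0L) v <- v - V[, seq_len(a), drop = FALSE] %*%
        crossprod(V[, seq_len(a), drop = FALSE], pl)
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    a <- a + 1L
    R[, a] <- r; Q[a] <- q; V[, a] <- v
  }
  if (a == 0L) stop("degenerate predictors: no PLS component could be extracted")
  R <- R[, seq_len(a), drop = FALSE]; Q <- Q[seq_len(a)]
  coef <- sapply(seq_len(a), function(k)
    R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)])
  coef <- matrix(coef, nrow = p)
  intercept <- ym - as.numeric(xm %*% coef)
  structure(list(coef = coef, intercept = intercept, ncomp = a,
                 xmeans = xm, ymean = ym),
            class = "simpls_fit")
}

#' Predict from a SIMPLS fit
#' @param object A [simpls_fit()].
#' @param newdata Numeric matrix, samples in rows.
#' @param ncomp Component count to use (default: all extracted).
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.simpls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  as.numeric(as.matrix(newdata) %*% object$coef[, ncomp] +
               object$intercept[ncomp])
}

# cross-validated RMSE of a 0/1 response for a variable subset, with the
# component count chosen per fold-averaged minimum; fold ids are supplied so
# every subset is judged on the identical partition.
pls_rmsecv <- function(X, y, fold_id, max_ncomp) {
  nf <- max(fold_id)
  ncomp_cap <- min(max_ncomp, ncol(X))
  sse <- numeric(ncomp_cap)
  used <- ncomp_cap
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    fit <- simpls_fit(X[tr, , drop = FALSE], y[tr], ncomp_cap)
    used <- min(used, fit$ncomp)
    pred <- as.matrix(X[!tr, , drop = FALSE] %*% fit$coef) +
      rep(fit$intercept, each = sum(!tr))
    err <- (pred - y[!tr])^2
    sse[seq_len(fit$ncomp)] <- sse[seq_len(fit$ncomp)] + colSums(err)
    if (fit$ncomp < ncomp_cap)   # reuse the largest available model beyond rank
      sse[(fit$ncomp + 1):ncomp_cap] <- sse[(fit$ncomp + 1):ncomp_cap] +
        sum(err[, fit$ncomp])
  }
  rmse <- sqrt(sse / length(y))
  list(rmsecv = min(rmse[seq_len(used)]),
       ncomp = which.min(rmse[seq_len(used)]))
}
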