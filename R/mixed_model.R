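#' REML variance components for the animal model
#'
#' Fits `y1 ~ N(0, W11 sigma2_g + I sigma2_e)` for phenotypes pre-corrected
#' for fixed effects (no mean is fitted, so the restricted likelihood
#' coincides with the ordinary one). `W11` is eigendecomposed once; the
#' total variance is profiled out in closed form and the restricted
#' log-likelihood is maximized over `h2` with a bracketed scalar optimizer.
#'
#' @param y1 phenotype vector of the reference population (finite values).
#' @param W11 symmetric relationship matrix of the reference population.
#' @param h2_bounds search interval for the heritability.
#' @param tol convergence tolerance on h2.
#' @param n_grid number of points of the returned profile grid.
#' @param eig optional precomputed `eigen(W11, symmetric = TRUE)`; pass it
#'   when calling repeatedly with the same `W11` (e.g. Monte-Carlo
#'   replicates) so the matrix is factorized once.
#' @return An object of class `reml_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `loglik`, and a `profile` data frame (h2, restricted log-likelihood).
#' @export
estimate_reml <- function(y1, W11 = NULL, h2_bounds = c(1e-4, 1 - 1e-4),
                          tol = 1e-8, n_grid = 50, eig = NULL) {
  if (!all(is.finite(y1))) stop("non-finite phenotypes")
  n <- length(y1)
  if (is.null(eig)) {
    if (is.null(W11)) stop("supply W11 or its eigendecomposition")
    stopifnot(is.matrix(W11), nrow(W11) == n)
    eig <- eigen(W11, symmetric = TRUE)
  }
  lam <- pmax(eig$values, 0)
  if (max(abs(lam - 1)) < 1e-8)
    warning("W11 is numerically indistinguishable from the identity; ",
            "h2 is weakly identified (flat profile)")
  yt2 <- drop(crossprod(eig$vectors, y1))^2
  ll <- function(h2) {
    v <- h2 * lam + (1 - h2)
    s2 <- mean(yt2 / v)
    -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  }
  opt <- stats::optimize(ll, h2_bounds, maximum = TRUE, tol = tol)
  h2 <- opt$maximum
  v <- h2 * lam + (1 - h2)
  s2 <- mean(yt2 / v)
  grid <- seq(h2_bounds[1], h2_bounds[2], length.out = n_grid)
  structure(list(sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2,
                 loglik = opt$objective,
                 profile = data.frame(h2 = grid, loglik = vapply(grid, ll, 0))),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.4f\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}

#' Variance components from known values
#'
#' @param sigma2_g additive genetic variance (>= 0).
#' @param sigma2_e residual variance (> 0).
#' @return A `reml_fit`-compatible list (no profile).
#' @export
variance_components <- function(sigma2_g, sigma2_e) {
  stopifnot(sigma2_g >= 0, sigma2_e > 0)
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = sigma2_g / (sigma2_g + sigma2_e),
                 loglik = NA_real_, profile = NULL),
            class = "reml_fit")
}

#' BLUP breeding values and predicted breeding values
#'
#' Direct transcription of the analytical mixed-model solutions for
#' pre-corrected phenotypes:
#' `g1_hat = W11 (W11 sigma2_g + I sigma2_e)^-1 y1 sigma2_g` for the
#' reference population, and
#' `g2_tilde = W21 (W11 sigma2_g + I sigma2_e)^-1 y1 sigma2_g` for the
#' target population. A single Cholesky factorization of the coefficient
#' matrix serves both.
#'
#' @param y1 reference phenotypes (length n1).
#' @param W11 n1 x n1 reference relationship block.
#' @param W21 n2 x n1 target-by-reference relationship block.
#' @param vc variance components ([estimate_reml()] or
#'   [variance_components()]).
#' @return List with `g_hat_ref` (length n1) and `g_tilde_target`
#'   (length n2), named when the blocks carry dimnames.
#' @export
solve_blup <- function(y1, W11, W21, vc) {
  stopifnot(inherits(vc, "reml_fit"), length(y1) == nrow(W11),
            ncol(W21) == nrow(W11))
  C <- W11 * vc$sigma2_g
  diag(C) <- diag(C) + vc$sigma2_e
  ch <- tryCatch(chol(C), error = function(e)
    stop("coefficient matrix not positive definite; condition number ~ ",
         format(kappa(C), digits = 3)))
  sol <- backsolve(ch, forwardsolve(t(ch), y1))
  g1 <- drop(W11 %*% sol) * vc$sigma2_g
  g2 <- drop(W21 %*% sol) * vc$sigma2_g
  names(g1) <- rownames(W11); names(g2) <- rownames(W21)
  list(g_hat_ref = g1, g_tilde_target = g2)
}

## Eigen-space BLUP used by the study/IGC loops: with W11 = Q L Q' cached,
## g1_hat = Q diag(L s2g / (L s2g + s2e)) Q'y1 and
## g2_tilde = (W21 Q) diag(s2g / (L s2g + s2e)) Q'y1.
## Equivalence with solve_blup is asserted in the test suite.
.blup_eig <- function(yt, eig, B21, s2g, s2e) {
  lam <- pmax(eig$values, 0)
  w <- yt / (lam * s2g + s2e)
  list(g_hat_ref = drop(eig$vectors %*% (lam * s2g * w)),
       g_tilde_target = if (is.null(B21)) NULL else drop(B21 %*% (s2g * w)))
}
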