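#' Fisher Z-transformation of a correlation
#'
#' `Z = log((1 + R) / (1 - R))`, approximately normal with variance
#' `4 / (n - 3)` for a realized correlation on n pairs (twice the usual
#' atanh convention, matching the variance used throughout this package).
#'
#' @param R correlation(s), strictly inside (-1, 1).
#' @return Z value(s).
#' @export
fisher_z <- function(R) {
  if (any(abs(R) >= 1)) stop("|R| must be < 1")
  log((1 + R) / (1 - R))
}

#' Inverse Fisher Z-transformation
#' @param Z Z value(s).
#' @return Correlation(s) `(exp(Z) - 1) / (exp(Z) + 1)`.
#' @export
inv_fisher_z <- function(Z) (exp(Z) - 1) / (exp(Z) + 1)

#' Accuracy ceiling of the reference population
#'
#' The accuracy entering the erosion expectation is capped at the
#' theoretical ceiling: `rho = min(cor(g1_hat, y1), sqrt(h2))`, floored at
#' zero (a negative reference accuracy carries no predictive signal).
#'
#' @param cor_ref realized correlation `cor(g1_hat, y1)` in (-1, 1).
#' @param h2 heritability in `[0, 1]`.
#' @return The capped accuracy rho.
#' @export
rho_cap <- function(cor_ref, h2) {
  stopifnot(abs(cor_ref) < 1, h2 >= 0, h2 <= 1)
  v <- min(cor_ref, sqrt(h2))
  if (v < 0) {
    warning("negative reference accuracy floored at 0")
    v <- 0
  }
  v
}

#' Expected accuracy of predicted breeding values under erosion
#'
#' The central quantity of the package: assuming the Z-transformed accuracy
#' is shrunk linearly by the index of genetic correlation r,
#' `E(Z | erosion) = r log((1 + rho) / (1 - rho))`, back-transforming gives
#' `E(R | erosion) = ((1 + rho)^r - (1 - rho)^r) /
#'                  ((1 + rho)^r + (1 - rho)^r)`.
#' It equals `rho` at r = 1 (no erosion) and 0 at r = 0 (disconnected
#' populations), and is monotone increasing in both arguments.
#'
#' @param rho reference-population accuracy in `[0, 1)` (see [rho_cap()]).
#' @param r index of genetic correlation in `[0, 1]`.
#' @return Expected accuracy; vectorized over both arguments.
#' @export
expected_R_erosion <- function(rho, r) {
  if (any(rho < 0 | rho >= 1)) stop("rho must be in [0, 1)")
  if (any(r < 0 | r > 1)) stop("r must be in [0, 1]")
  up <- (1 + rho)^r
  dn <- (1 - rho)^r
  (up - dn) / (up + dn)
}

#' Confidence interval for a realized correlation
#'
#' Normal interval on the Fisher Z scale with `SE(Z) = 2 / sqrt(n - 3)`,
#' back-transformed. With related individuals the nominal variance is
#' optimistic; the interval is a convention, not an exact guarantee.
#'
#' @param R realized correlation, |R| < 1.
#' @param n number of pairs behind R (> 3).
#' @param alpha two-sided error rate (default 0.05).
#' @return Named vector `c(low, high)`.
#' @export
correlation_ci <- function(R, n, alpha = 0.05) {
  if (n <= 3) stop("n must exceed 3")
  z <- fisher_z(R)
  se <- 2 / sqrt(n - 3)
  q <- stats::qnorm(1 - alpha / 2)
  c(low = inv_fisher_z(z - q * se), high = inv_fisher_z(z + q * se))
}

#' Mean GBLUP reliability of the target population
#'
#' The mixed-model-equations reference value
#' `E(R | GBLUP) = sqrt(h2_hat) / n2 *
#'    sum_i sqrt([W21 W11^-1 (W11 - (LHS sigma2_g)^-1) W11^-1 W12]_ii)`,
#' with `LHS = I / sigma2_e + W11^-1 / sigma2_g`, the left-hand side of the
#' mixed-model equations for the no-fixed-effect animal model
#' (phenotypes pre-corrected). Diagonal terms that come out (numerically)
#' negative are floored at zero before the square root; the number of
#' floored terms is attached as attribute `n_floored`.
#'
#' @param W11,W12,W21 relationship blocks (`W12 = t(W21)`).
#' @param vc variance components.
#' @param h2_hat heritability estimate (defaults to `vc$h2`).
#' @return Scalar expected accuracy, with attribute `n_floored`.
#' @export
expected_R_gblup <- function(W11, W12, W21, vc, h2_hat = NULL) {
  if (is.null(h2_hat)) h2_hat <- vc$h2
  n2 <- nrow(W21)
  W11_inv <- .solve_jitter(W11)
  LHS <- diag(nrow(W11)) / vc$sigma2_e + W11_inv / vc$sigma2_g
  inner <- W11 - .solve_jitter(LHS * vc$sigma2_g)
  B <- W21 %*% W11_inv
  d <- rowSums((B %*% inner) * B)
  n_floored <- sum(d < 0)
  if (n_floored) warning(n_floored, " negative diagonal term(s) floored at 0")
  out <- sqrt(h2_hat) / n2 * sum(sqrt(pmax(d, 0)))
  attr(out, "n_floored") <- n_floored
  out
}

#' GBLUP index of weighted between-population relationships
#'
#' `r_GBLUP = 1 / n2 * sum_i sqrt([W21 W11^-1 W12]_ii)`, the average
#' weighted relationship of each target individual to the reference
#' population; used as a comparator for the IGC.
#'
#' @param W11 reference block; @param W21 target-by-reference block.
#' @return Scalar.
#' @export
r_gblup <- function(W11, W21) {
  B <- W21 %*% .solve_jitter(W11)
  d <- rowSums(B * W21)
  mean(sqrt(pmax(d, 0)))
}

## inverse through Cholesky with the package-wide jitter policy
.solve_jitter <- function(W, label = "matrix") {
  ch <- .chol_jitter(W, label)
  chol2inv(ch)
}
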