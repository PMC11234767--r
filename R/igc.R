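#' Quadratic least-squares fit of paired singular values
#'
#' Ordinary least squares for `d_T = a + b d_2 + c d_2^2`.
#'
#' @param d_T response singular values.
#' @param d_2 regressor singular values (same length, not all equal).
#' @return Named coefficients `c(a, b, c)` with attribute `r_squared`.
#' @export
quad_fit <- function(d_T, d_2) {
  if (length(d_T) != length(d_2)) stop("d_T and d_2 must have equal length")
  if (length(d_2) < 3L) stop("need at least 3 points for a quadratic fit")
  if (stats::var(d_2) == 0) stop("d_2 values are all equal; fit unidentifiable")
  X <- cbind(1, d_2, d_2^2)
  qx <- qr(X)
  if (qx$rank < 3L) stop("rank-deficient quadratic design")
  beta <- qr.coef(qx, d_T)
  names(beta) <- c("a", "b", "c")
  fitted <- drop(X %*% beta)
  ss_res <- sum((d_T - fitted)^2)
  ss_tot <- sum((d_T - mean(d_T))^2)
  attr(beta, "r_squared") <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  beta
}

.igc_result <- function(r_raw, method, coefficients, n_points, fit_r2,
                        diagnostics = NULL) {
  clipped <- r_raw < -1e-8 || r_raw > 1 + 1e-8   # float fuzz is not erosion
  if (clipped) warning("raw IGC ", format(r_raw, digits = 4),
                       " outside [0, 1]; clipped")
  structure(list(r = min(max(r_raw, 0), 1), method = method,
                 coefficients = coefficients, n_points = n_points,
                 fit_r2 = fit_r2, clipped = clipped,
                 diagnostics = diagnostics),
            class = "igc_result")
}

#' @export
print.igc_result <- function(x, ...) {
  cat(sprintf("IGC (%s): r = %.4f over %d points%s\n", x$method, x$r,
              x$n_points, if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

#' Index of genetic correlation from genotype SVDs
#'
#' Compares the contributions of the SNPs to the variation of the reference
#' (M1) and target (M2) centred-and-scaled genotype matrices. With
#' `M = U D V'` for each population, the kernel matrix
#' `T = sqrt(n2 / n1) V2' V1 D1` carries, for any trait, the linear map
#' from reference phenotypes to target predictions; its singular values
#' `d_T` are regressed on the target singular values `d_2` with a quadratic
#' term, `d_Ti = a + b d_2i + c d_2i^2`, and the index is `r = a + b + c`,
#' clipped into [0, 1] if numerically outside.
#'
#' Components are retained by the standard numerical-rank rule
#' (`d > max(dim) * eps * d_max`, per matrix) before forming `T`: centring
#' forces at least one exactly-zero singular value whose null-space
#' right-vectors are arbitrary and would otherwise contaminate `T`.
#'
#' @param M1 reference `scaled_geno` (or plain matrix), n1 x m.
#' @param M2 target `scaled_geno` (or plain matrix) over the same variants
#'   in the same order, n2 x m.
#' @return An `igc_result` with the fitted coefficients and paired singular
#'   values in `diagnostics`.
#' @export
igc_svd <- function(M1, M2) {
  v1 <- if (inherits(M1, "scaled_geno")) M1$values else as.matrix(M1)
  v2 <- if (inherits(M2, "scaled_geno")) M2$values else as.matrix(M2)
  if (ncol(v1) != ncol(v2))
    stop("M1 and M2 must cover the same variants")
  if (!is.null(colnames(v1)) && !is.null(colnames(v2)) &&
      !identical(colnames(v1), colnames(v2)))
    stop("M1 and M2 variant sets (or order) differ")
  n1 <- nrow(v1); n2 <- nrow(v2)
  s1 <- svd(v1, nu = 0)
  s2 <- svd(v2, nu = 0)
  k1 <- sum(s1$d > max(dim(v1)) * .Machine$double.eps * s1$d[1])
  k2 <- sum(s2$d > max(dim(v2)) * .Machine$double.eps * s2$d[1])
  k <- min(k1, k2)
  if (k < 3L) stop("fewer than 3 retained components; quadratic fit unidentifiable")
  T_ <- sqrt(n2 / n1) *
    crossprod(s2$v[, seq_len(k2), drop = FALSE], s1$v[, seq_len(k1), drop = FALSE]) *
    rep(s1$d[seq_len(k1)], each = k2)
  d_T <- svd(T_, nu = 0, nv = 0)$d[seq_len(k)]
  d_2 <- s2$d[seq_len(k)]
  beta <- quad_fit(d_T, d_2)
  .igc_result(sum(beta), "svd", beta, k, attr(beta, "r_squared"),
              diagnostics = data.frame(d_T = d_T, d_2 = d_2))
}

#' Index of genetic correlation from simulated phenotypes
#'
#' The estimator that needs no genotype SVD and works for any relationship
#' matrix: for each heritability in `h2_grid` (and replicate) a phenotype
#' is simulated -- from the genotypes when supplied, else from `W` -- the
#' breeding values and predictions are solved with the *true* simulation
#' variances (`sigma2_g = h2 * sigma2_y`), the reference accuracy
#' `rho = min(cor(g1_hat, y1), sqrt(h2))` (capped at its theoretical
#' ceiling, which is known exactly here since h2 is the simulation truth)
#' and the target accuracy `R = cor(g2_tilde, y2)` are Fisher
#' Z-transformed, and the through-origin regression slope
#' `r = sum(Z_rho Z_R) / sum(Z_rho^2)` is the index. Without the cap the
#' slope is biased downward whenever the reference fit is optimistic
#' (`cor(g1_hat, y1) > sqrt(h2)`, common when the effective genomic
#' dimension is not far below n1); the raw correlations and the
#' with-intercept (covariance / variance) slope are kept in the
#' diagnostics.
#'
#' @param W relationship matrix over reference + target ids.
#' @param split a [population_partition()].
#' @param h2_grid heritabilities to scan (default 0.1 ... 0.9).
#' @param sigma2_y phenotypic variance of the simulated traits.
#' @param reps_per_h2 phenotype replicates per heritability.
#' @param seed optional integer seed.
#' @param geno optional [geno_matrix()] covering the same ids; when given,
#'   breeding values are simulated from SNP effects.
#' @param n_qtl number of causal variants per simulated trait when `geno`
#'   is used (default: all variants).
#' @return An `igc_result`; `diagnostics` holds the per-trait (h2, rho, R)
#'   table and the cov/var slope.
#' @export
igc_simphen <- function(W, split, h2_grid = seq(0.1, 0.9, by = 0.1),
                        sigma2_y = 100, reps_per_h2 = 1, seed = NULL,
                        geno = NULL, n_qtl = NULL) {
  stopifnot(inherits(split, "partition"))
  if (length(h2_grid) < 3L || any(h2_grid <= 0 | h2_grid >= 1))
    stop("h2_grid must hold at least 3 values strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  blocks <- partition_W(W, split)
  eig <- eigen(blocks$W11, symmetric = TRUE)
  B21 <- blocks$W21 %*% eig$vectors
  ref <- split$reference; tar <- split$target
  rows <- list()
  for (h2 in h2_grid) for (rep in seq_len(reps_per_h2)) {
    trait <- if (is.null(geno))
      simulate_trait_from_W(W, h2, sigma2_y)
    else
      simulate_trait(geno, trait_config(h2, sigma2_y, n_qtl = n_qtl))
    y1 <- trait$y[ref]; y2 <- trait$y[tar]
    s2g <- h2 * sigma2_y; s2e <- (1 - h2) * sigma2_y
    bv <- .blup_eig(drop(crossprod(eig$vectors, y1)), eig, B21, s2g, s2e)
    rho_raw <- stats::cor(bv$g_hat_ref, y1)
    rows[[length(rows) + 1L]] <-
      data.frame(h2 = h2, rep = rep, rho_raw = rho_raw,
                 rho = min(rho_raw, sqrt(h2)),
                 R = stats::cor(bv$g_tilde_target, y2))
  }
  d <- do.call(rbind, rows)
  ok <- is.finite(d$rho) & is.finite(d$R) & abs(d$rho) < 1 & abs(d$R) < 1
  if (any(!ok))
    warning(sum(!ok), " point(s) with undefined or unit correlation dropped")
  d <- d[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("fewer than 3 usable (rho, R) points")
  z_rho <- fisher_z(d$rho); z_R <- fisher_z(d$R)
  slope <- sum(z_rho * z_R) / sum(z_rho^2)
  .igc_result(slope, "simphen", c(slope = slope), nrow(d),
              stats::cor(z_rho, z_R)^2,
              diagnostics = list(points = d,
                                 slope_cov_var = stats::cov(z_R, z_rho) /
                                   stats::var(z_rho)))
}
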