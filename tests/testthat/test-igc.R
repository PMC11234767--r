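test_that("quadratic fit recovers exact linear, quadratic and oracle cases", {
  d2 <- c(5, 4, 3, 2, 1)
  expect_equal(unname(quad_fit(d2, d2)), c(0, 1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(quad_fit(d2^2, d2)), c(0, 0, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  # normal-equations oracle on a noisy 5-point fixture
  set.seed(60)
  dT <- 0.3 + 0.7 * d2 - 0.05 * d2^2 + rnorm(5, 0, 0.01)
  X <- cbind(1, d2, d2^2)
  beta_ne <- solve(t(X) %*% X, t(X) %*% dT)
  expect_equal(unname(quad_fit(dT, d2)), unname(drop(beta_ne)),
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(quad_fit(1:2, 1:2), "at least 3")
  expect_error(quad_fit(c(1, 2, 3), c(2, 2, 2)), "unidentifiable")
})

test_that("SVD index is exactly 1 on itself and 0 on orthogonal variant spaces", {
  set.seed(61)
  for (s in 1:3) {
    dos <- matrix(rbinom(20 * 100, 2, 0.5), 20, 100,
                  dimnames = list(paste0("s", 1:20), paste0("v", 1:100)))
    keep <- apply(dos, 2, function(x) length(unique(x)) > 1)
    M <- center_scale(dos[, keep, drop = FALSE])
    res <- igc_svd(M, M)
    expect_equal(res$r, 1, tolerance = 1e-8)
    expect_equal(unname(res$coefficients), c(0, 1, 0), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }

  # populations spanning orthogonal variant subspaces: V2'V1 = 0
  Z1 <- cbind(matrix(rnorm(10 * 30), 10, 30), matrix(0, 10, 30))
  Z2 <- cbind(matrix(0, 10, 30), matrix(rnorm(10 * 30), 10, 30))
  res0 <- igc_svd(Z1, Z2)
  expect_equal(res0$r, 0)
  expect_equal(unname(res0$coefficients), c(0, 0, 0), ignore_attr = TRUE)
})

test_that("SVD index matches an independent brute-force implementation", {
  # 10 individuals split 5 + 5: own-frequency centring removes one rank from
  # each group, leaving 4 retained components -- enough for the quadratic
  set.seed(62)
  dos <- matrix(rbinom(10 * 40, 2, runif(40, 0.2, 0.8)[rep(1:40, each = 10)]),
                10, 40, dimnames = list(paste0("s", 1:10), paste0("v", 1:40)))
  g1i <- 1:5; g2i <- 6:10
  keep <- apply(dos[g1i, ], 2, function(x) length(unique(x)) > 1) &
    apply(dos[g2i, ], 2, function(x) length(unique(x)) > 1)
  dos <- dos[, keep]
  M1 <- center_scale(dos[g1i, ])
  M2 <- center_scale(dos[g2i, ])

  # brute force with explicit steps, no shared code
  brute_igc <- function(X1, X2) {
    s1 <- svd(X1); s2 <- svd(X2)
    tol1 <- max(dim(X1)) * .Machine$double.eps * max(s1$d)
    tol2 <- max(dim(X2)) * .Machine$double.eps * max(s2$d)
    i1 <- which(s1$d > tol1); i2 <- which(s2$d > tol2)
    k <- min(length(i1), length(i2))
    Tm <- matrix(0, length(i2), length(i1))
    for (a in seq_along(i2)) for (b in seq_along(i1))
      Tm[a, b] <- sqrt(nrow(X2) / nrow(X1)) *
        sum(s2$v[, i2[a]] * s1$v[, i1[b]]) * s1$d[i1[b]]
    dT <- svd(Tm)$d[1:k]
    d2 <- s2$d[i2][1:k]
    X <- cbind(1, d2, d2^2)
    beta <- solve(t(X) %*% X, t(X) %*% dT)
    min(max(sum(beta), 0), 1)
  }
  # this toy's raw index is slightly negative, so both paths clip to 0
  expect_warning(r_pkg <- igc_svd(M1, M2)$r, "clipped")
  expect_equal(r_pkg, brute_igc(M1$values, M2$values), tolerance = 1e-10)

  # permutation invariance: reordering individuals changes nothing
  perm <- c(3, 5, 1, 4, 2)
  M1p <- center_scale(dos[g1i[perm], ])
  expect_equal(suppressWarnings(igc_svd(M1p, M2)$r), r_pkg, tolerance = 1e-8)

  expect_error(igc_svd(M1, center_scale(dos[g2i, 1:10])), "variant")
})

test_that("simulated-phenotype index separates identical from unrelated targets", {
  W <- random_W(60, m = 120, seed = 63, ids = sprintf("r%02d", 1:60))

  # target duplicating the reference block (strong relationships)
  ids <- rownames(W)
  Wdup <- rbind(cbind(W, W), cbind(W, W + diag(1e-4, 60)))
  dimnames(Wdup) <- list(c(ids, sub("r", "t", ids)), c(ids, sub("r", "t", ids)))
  split <- population_partition(ids, sub("r", "t", ids))
  r_dup <- suppressWarnings(igc_simphen(Wdup, split, reps_per_h2 = 3,
                                        seed = 64)$r)

  # essentially unrelated target: W21 ~ 0
  set.seed(66)
  Wfar <- diag(120) * 1.0
  dimnames(Wfar) <- dimnames(Wdup)
  Wfar[1:60, 1:60] <- W
  cross <- matrix(runif(3600, -1e-4, 1e-4), 60, 60)
  Wfar[1:60, 61:120] <- cross
  Wfar[61:120, 1:60] <- t(cross)
  r_far <- igc_simphen(Wfar, split, reps_per_h2 = 3, seed = 64)$r

  # a duplicated target tops any genuinely distinct one; residual noise in
  # fresh target phenotypes keeps the index below 1 even here
  expect_gt(r_dup, 0.6)
  expect_lt(r_far, 0.15)
  expect_gt(r_dup, r_far + 0.5)

  # determinism under a fixed seed
  expect_equal(suppressWarnings(igc_simphen(Wdup, split, seed = 65)$r),
               suppressWarnings(igc_simphen(Wdup, split, seed = 65)$r))
})

test_that("simulated-phenotype index is stable across seeds", {
  pop <- small_population()
  ref <- pop$founders$geno
  tar <- pop$gen2$geno
  dos <- rbind(ref$dosages, tar$dosages)
  comb <- geno_matrix(dos, ref$chrom, ref$pos_cM)
  G <- build_G(center_scale(comb))
  split <- population_partition(sample_ids(ref), sample_ids(tar))
  rs <- vapply(1:20, function(s)
    igc_simphen(G, split, seed = s, geno = comb, n_qtl = 100)$r, 0)
  expect_lt(sd(rs), 0.05)
  expect_true(all(rs >= 0 & rs <= 1))
})
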