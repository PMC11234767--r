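test_that("founder simulation respects frequencies, LD decay limits and seeds", {
  model <- ld_model(n_snps = 200, n_chromosomes = 2, ld_decay = 5,
                    freq_range = c(0.3, 0.7))
  pop <- simulate_founders(model, 500, seed = 1)
  g <- pop$geno
  expect_equal(dim(g$dosages), c(500L, 200L))
  expect_true(all(g$dosages %in% 0:2))
  p <- allele_freqs(g)
  expect_true(all(p > 0.15 & p < 0.85))   # near the sampled range

  # determinism
  pop2 <- simulate_founders(model, 500, seed = 1)
  expect_identical(pop$geno$haplotypes, pop2$geno$haplotypes)

  # ld_decay -> 0: adjacent loci essentially independent
  tiny <- simulate_founders(ld_model(n_snps = 200, n_chromosomes = 1,
                                     ld_decay = 1e-6), 400, seed = 2)$geno
  adj_cor <- sapply(seq_len(199), function(j)
    suppressWarnings(cor(tiny$haplotypes[, j], tiny$haplotypes[, j + 1])))
  expect_lt(mean(abs(adj_cor), na.rm = TRUE), 0.06)

  # ld_decay -> Inf at p = 0.5: adjacent loci near-perfectly correlated
  big <- simulate_founders(ld_model(n_snps = 50, n_chromosomes = 1,
                                    ld_decay = 1e6,
                                    freq_range = c(0.5 - 1e-9, 0.5 + 1e-9)),
                           400, seed = 3)$geno
  adj_cor <- sapply(seq_len(49), function(j)
    cor(big$haplotypes[, j], big$haplotypes[, j + 1]))
  expect_gt(mean(adj_cor), 0.97)
})

test_that("r2 between close loci exceeds r2 between distant loci", {
  g <- simulate_founders(ld_model(n_snps = 200, n_chromosomes = 1,
                                  ld_decay = 5), 500, seed = 4)$geno
  hap <- g$haplotypes
  r2_at <- function(lo, hi) {
    vals <- c()
    for (j in seq(1, 199, by = 3)) {
      d <- abs(g$pos_cM - g$pos_cM[j])
      k <- which(d > lo & d < hi)
      if (length(k) && sd(hap[, j]) > 0 && sd(hap[, k[1]]) > 0)
        vals <- c(vals, cor(hap[, j], hap[, k[1]])^2)
    }
    mean(vals)
  }
  expect_gt(r2_at(0.5, 1.5), r2_at(15, 25))
})

test_that("gametes are parental mosaics with correct transmission", {
  pop <- small_population()$founders

  # map_length = 0 impossible (positions need room), so emulate the
  # zero-recombination limit with a one-crossover-per-100cM genome and
  # check the construction identity instead
  off <- advance_generation(pop, 150, seed = 7)
  hap <- off$geno$haplotypes
  expect_true(all(off$geno$dosages ==
    hap[seq(1, nrow(hap), 2), ] + hap[seq(2, nrow(hap), 2), ]))
  expect_equal(max(off$ped$generation), 1L)
  expect_equal(sum(off$ped$generation == 1L), 150L)
  expect_true(all(table(off$ped$sex[off$ped$generation == 1L]) == 75))

  # two fixed parents: mean offspring dosage ~ mid-parent dosage
  two <- pop
  keep <- c(two$ped$id[two$ped$sex == "M"][1], two$ped$id[two$ped$sex == "F"][1])
  two$geno <- subset_samples(two$geno, keep)
  two$ped <- two$ped[two$ped$id %in% keep, ]
  kids <- advance_generation(two, 800, seed = 8)
  midparent <- colMeans(two$geno$dosages)
  expect_lt(max(abs(colMeans(kids$geno$dosages) - midparent)), 0.25)

  # unphased parents are refused
  nohap <- list(geno = geno_matrix(pop$geno$dosages, pop$geno$chrom,
                                   pop$geno$pos_cM), ped = pop$ped)
  expect_error(advance_generation(nohap, 5), "haplotypes")
})

test_that("allele frequencies drift without direction across generations", {
  pop <- small_population()
  p0 <- allele_freqs(pop$founders$geno)
  p2 <- allele_freqs(pop$gen2$geno)
  expect_lt(abs(mean(p2 - p0)), 0.01)   # no systematic change
})

test_that("trait simulation calibrates to the requested heritability", {
  g <- small_population()$founders$geno
  expect_error(trait_config(h2 = 0), "strictly inside")
  expect_error(trait_config(h2 = 1), "strictly inside")

  set.seed(20)
  ratios <- replicate(300, {
    tr <- simulate_trait(g, trait_config(0.4, 100, n_qtl = 80))
    var(tr$g_true) / var(tr$y)
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.4), 3 * se)

  tr <- simulate_trait(g, trait_config(0.4, 100, n_qtl = 50), seed = 5)
  expect_equal(tr$y, tr$g_true + tr$epsilon)
  tr2 <- simulate_trait(g, trait_config(0.4, 100, n_qtl = 50), seed = 5)
  expect_identical(tr$y, tr2$y)

  # monomorphic causal variants are excluded (all-monomorphic errors)
  dos <- g$dosages
  dos[, 1] <- 0L
  gm <- geno_matrix(dos, g$chrom, g$pos_cM)
  expect_warning(simulate_trait(gm, trait_config(0.4, qtl_ids =
    colnames(dos)[1:3]), seed = 1), "monomorphic")
  expect_error(suppressWarnings(simulate_trait(gm, trait_config(0.4,
    qtl_ids = colnames(dos)[1]), seed = 1)), "monomorphic")
})

test_that("trait simulation from W reproduces the requested covariance", {
  # identity W: i.i.d. breeding values with variance h2 * sigma2_y
  W <- diag(400)
  dimnames(W) <- list(sprintf("i%03d", 1:400), sprintf("i%03d", 1:400))
  set.seed(30)
  v <- replicate(100, var(simulate_trait_from_W(W, 0.5, 100)$g_true))
  expect_lt(abs(mean(v) - 50), 3 * sd(v) / 10)

  # parent-offspring covariance recovered: W = [[1, .5], [.5, 1]]
  W2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("p", "o"), c("p", "o")))
  set.seed(31)
  gs <- replicate(4000, simulate_trait_from_W(W2, 0.8, 100)$g_true)
  expect_lt(abs(cor(gs[1, ], gs[2, ]) - 0.5), 0.05)

  # determinism
  expect_identical(simulate_trait_from_W(W2, 0.5, 100, seed = 9)$y,
                   simulate_trait_from_W(W2, 0.5, 100, seed = 9)$y)
})
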