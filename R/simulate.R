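#' LD model for founder haplotypes
#'
#' Describes the generative model used by [simulate_founders()]: a
#' latent-Gaussian (copula) construction in which adjacent loci on a
#' chromosome share a latent first-order autoregressive correlation
#' `exp(-d / ld_decay)` for map distance `d` (cM), thresholded at the
#' normal quantile of each locus' allele frequency. It is a simple, seedable
#' stand-in for cattle-like LD, not a population-genetic model: `ld_decay`
#' tunes how fast r-squared decays with distance.
#'
#' @param n_snps total number of SNPs, split evenly across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param map_length chromosome map length in centimorgans.
#' @param ld_decay correlation-decay length in centimorgans of the latent
#'   AR process; small values give near-independent loci.
#' @param freq_range closed interval within (0, 1) from which founder
#'   allele frequencies are drawn uniformly.
#'
#' @return An object of class `ld_model`.
#' @export
ld_model <- function(n_snps = 2000, n_chromosomes = 10, map_length = 100,
                     ld_decay = 5, freq_range = c(0.05, 0.95)) {
  stopifnot(n_chromosomes >= 1, n_snps >= n_chromosomes,
            map_length > 0, ld_decay > 0)
  if (length(freq_range) != 2L || freq_range[1] <= 0 || freq_range[2] >= 1 ||
      freq_range[1] > freq_range[2])
    stop("freq_range must be an interval inside (0, 1)")
  if (n_snps %/% n_chromosomes < 2L)
    stop("fewer than 2 SNPs per chromosome; increase n_snps")
  structure(list(n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 map_length = map_length, ld_decay = ld_decay,
                 freq_range = freq_range),
            class = "ld_model")
}

#' Simulate founder genotypes in LD
#'
#' Draws `2 n` founder haplotypes per the latent-Gaussian AR construction of
#' [ld_model()]: within each chromosome the latent Gaussian at locus j is
#' `z_j = a_j z_{j-1} + sqrt(1 - a_j^2) e_j` with
#' `a_j = exp(-(pos_j - pos_{j-1}) / ld_decay)`, and the allele is 1 when
#' `z_j < qnorm(p_j)`, so each locus has allele frequency `p_j` while
#' adjacent loci are correlated. Map positions are uniform on the
#' chromosome; frequencies are uniform on `freq_range`.
#'
#' @param model an [ld_model()].
#' @param n number of founder individuals (>= 2).
#' @param seed optional integer seed.
#' @param id_prefix prefix for sample identifiers.
#' @return A list with elements `geno` (a phased [geno_matrix()]) and `ped`
#'   (a founder pedigree data frame with columns id, sire, dam, sex,
#'   generation; sexes assigned 50/50 at random).
#' @export
simulate_founders <- function(model, n, seed = NULL, id_prefix = "G0") {
  stopifnot(inherits(model, "ld_model"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  per_chr <- diff(round(seq(0, model$n_snps, length.out = model$n_chromosomes + 1)))
  if (any(per_chr < 2L)) stop("fewer than 2 SNPs on a chromosome")
  chrom <- rep(seq_len(model$n_chromosomes), per_chr)
  pos <- unlist(lapply(per_chr, function(k) sort(stats::runif(k, 0, model$map_length))))
  p <- stats::runif(model$n_snps, model$freq_range[1], model$freq_range[2])

  hap <- matrix(0L, 2L * n, model$n_snps)
  off <- 0L
  for (ch in seq_len(model$n_chromosomes)) {
    k <- per_chr[ch]
    a <- exp(-diff(pos[off + seq_len(k)]) / model$ld_decay)
    z <- matrix(0, 2L * n, k)
    z[, 1L] <- stats::rnorm(2L * n)
    for (j in seq_len(k - 1L))
      z[, j + 1L] <- a[j] * z[, j] + sqrt(1 - a[j]^2) * stats::rnorm(2L * n)
    thr <- stats::qnorm(p[off + seq_len(k)])
    hap[, off + seq_len(k)] <- (z < rep(thr, each = 2L * n)) + 0L
    off <- off + k
  }

  ids <- sprintf("%s_%04d", id_prefix, seq_len(n))
  dimnames(hap) <- list(paste0(rep(ids, each = 2L), c("_h1", "_h2")),
                        sprintf("snp%05d", seq_len(model$n_snps)))
  dos <- hap[seq(1L, 2L * n, 2L), , drop = FALSE] + hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  rownames(dos) <- ids
  geno <- geno_matrix(dos, chrom, pos, hap)
  ped <- data.frame(id = ids, sire = "0", dam = "0",
                    sex = sample(rep(c("M", "F"), length.out = n)),
                    generation = 0L, stringsAsFactors = FALSE)
  list(geno = geno, ped = ped)
}

## one gamete from a phased parent: per chromosome, Poisson(map_length/100)
## crossovers at uniform positions, no interference, random start haplotype
.make_gamete <- function(h1, h2, chrom, pos, chr_index, map_length) {
  g <- integer(length(h1))
  for (ch in seq_along(chr_index)) {
    idx <- chr_index[[ch]]
    nco <- stats::rpois(1L, map_length / 100)
    start <- sample.int(2L, 1L)
    if (nco == 0L) {
      g[idx] <- if (start == 1L) h1[idx] else h2[idx]
    } else {
      bp <- sort(stats::runif(nco, 0, map_length))
      phase <- (start + findInterval(pos[idx], bp)) %% 2L
      g[idx] <- ifelse(phase == 1L, h1[idx], h2[idx])
    }
  }
  g
}

#' Advance one generation by random mating
#'
#' Each offspring receives one recombinant gamete from a random sire and one
#' from a random dam, both drawn (with replacement) from the most recent
#' generation in `pop$ped`. Crossover counts per chromosome are
#' Poisson(map_length / 100) with uniform positions and no interference;
#' offspring sexes are assigned 50/50; there is no selection, migration or
#' mutation.
#'
#' @param pop a list with `geno` (phased [geno_matrix()]) and `ped` as
#'   returned by [simulate_founders()] or by this function.
#' @param n_offspring number of offspring to produce.
#' @param seed optional integer seed.
#' @return A list with `geno` (the offspring generation, phased) and `ped`
#'   (the parental pedigree with the offspring records appended).
#' @export
advance_generation <- function(pop, n_offspring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno <- pop$geno; ped <- pop$ped
  if (is.null(geno$haplotypes))
    stop("parental haplotypes are required for mating; simulate or phase genotypes first")
  gen <- max(ped$generation)
  cur <- ped[ped$generation == gen & ped$id %in% sample_ids(geno), ]
  sires <- cur$id[cur$sex == "M"]; dams <- cur$id[cur$sex == "F"]
  if (!length(sires) || !length(dams))
    stop("random mating requires at least one male and one female parent")

  map_length <- max(tapply(geno$pos_cM, geno$chrom, max))
  chr_index <- split(seq_along(geno$chrom), geno$chrom)
  hidx <- function(id) 2L * match(id, sample_ids(geno)) - 1L

  m <- ncol(geno$dosages)
  hap <- matrix(0L, 2L * n_offspring, m)
  sire_of <- sample(sires, n_offspring, replace = TRUE)
  dam_of <- sample(dams, n_offspring, replace = TRUE)
  for (i in seq_len(n_offspring)) {
    si <- hidx(sire_of[i]); di <- hidx(dam_of[i])
    hap[2L * i - 1L, ] <- .make_gamete(geno$haplotypes[si, ], geno$haplotypes[si + 1L, ],
                                       geno$chrom, geno$pos_cM, chr_index, map_length)
    hap[2L * i, ] <- .make_gamete(geno$haplotypes[di, ], geno$haplotypes[di + 1L, ],
                                  geno$chrom, geno$pos_cM, chr_index, map_length)
  }
  ids <- sprintf("G%d_%04d", gen + 1L, seq_len(n_offspring))
  dimnames(hap) <- list(paste0(rep(ids, each = 2L), c("_h1", "_h2")), variant_ids(geno))
  dos <- hap[seq(1L, 2L * n_offspring, 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n_offspring, 2L), , drop = FALSE]
  rownames(dos) <- ids
  off_geno <- geno_matrix(dos, geno$chrom, geno$pos_cM, hap)
  off_ped <- data.frame(id = ids, sire = sire_of, dam = dam_of,
                        sex = sample(rep(c("M", "F"), length.out = n_offspring)),
                        generation = gen + 1L, stringsAsFactors = FALSE)
  list(geno = off_geno, ped = rbind(ped, off_ped))
}

#' Trait simulation settings
#'
#' @param h2 heritability, strictly inside (0, 1).
#' @param sigma2_y phenotypic variance (default 100).
#' @param n_qtl number of causal variants drawn uniformly without
#'   replacement, ignored when `qtl_ids` is given.
#' @param qtl_ids optional explicit causal-variant identifiers.
#' @return An object of class `trait_config`.
#' @export
trait_config <- function(h2, sigma2_y = 100, n_qtl = NULL, qtl_ids = NULL) {
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1)
    stop("h2 must be strictly inside (0, 1)")
  stopifnot(sigma2_y > 0)
  structure(list(h2 = h2, sigma2_y = sigma2_y, n_qtl = n_qtl,
                 qtl_ids = qtl_ids), class = "trait_config")
}

#' Simulate an additive trait from genotypes
#'
#' Allele-substitution effects are drawn as
#' `alpha ~ N(0, h2 * sigma2_y / sum(2 p (1 - p)))` over the causal
#' variants (observed frequencies), breeding values are `g = M alpha` with
#' `M` the centred (not scaled) causal dosage block, residuals are
#' i.i.d. `N(0, (1 - h2) * sigma2_y)` and `y = g + epsilon`.
#'
#' @param geno a [geno_matrix()] covering all individuals to phenotype.
#' @param cfg a [trait_config()].
#' @param seed optional integer seed.
#' @return An object of class `sim_trait`: named vectors `y`, `g_true`,
#'   `epsilon`, per-QTL `alpha`, the causal ids, and the settings used.
#' @export
simulate_trait <- function(geno, cfg, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(cfg, "trait_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- ncol(geno$dosages)
  qtl <- cfg$qtl_ids
  if (is.null(qtl)) {
    n_qtl <- if (is.null(cfg$n_qtl)) m else cfg$n_qtl
    if (n_qtl > m) stop("n_qtl exceeds the number of variants")
    qtl <- sample(variant_ids(geno), n_qtl)
  } else if (!all(qtl %in% variant_ids(geno)))
    stop("unknown qtl_ids")
  p <- allele_freqs(geno)[qtl]
  mono <- p <= 0 | p >= 1
  if (all(mono)) stop("all causal variants are monomorphic")
  if (any(mono)) {
    warning(sum(mono), " monomorphic causal variant(s) excluded")
    qtl <- qtl[!mono]; p <- p[!mono]
  }
  sum2pq <- sum(2 * p * (1 - p))
  alpha <- stats::rnorm(length(qtl), 0, sqrt(cfg$h2 * cfg$sigma2_y / sum2pq))
  names(alpha) <- qtl
  Mc <- sweep(geno$dosages[, qtl, drop = FALSE], 2L, 2 * p)
  g <- drop(Mc %*% alpha)
  eps <- stats::rnorm(nrow(Mc), 0, sqrt((1 - cfg$h2) * cfg$sigma2_y))
  y <- g + eps
  names(g) <- names(eps) <- names(y) <- sample_ids(geno)
  structure(list(y = y, g_true = g, epsilon = eps, alpha = alpha,
                 qtl_ids = qtl, h2 = cfg$h2, sigma2_y = cfg$sigma2_y),
            class = "sim_trait")
}

## Cholesky with escalating diagonal jitter: delta = 1e-8 * mean(diag),
## times 10 per retry, at most 3 retries.
.chol_jitter <- function(W, label = "W") {
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  delta <- 1e-8 * mean(diag(W))
  for (k in 0:3) {
    ch <- tryCatch(chol(W + diag(delta * 10^k, nrow(W))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  stop(label, " could not be factorized even after jitter; condition number ~ ",
       format(kappa(W), digits = 3))
}

#' Simulate an additive trait from a relationship matrix
#'
#' Draws `g ~ N(0, W h2 sigma2_y)` through a (jittered, if needed) Cholesky
#' factor of `W`, then `y = g + epsilon` with i.i.d. residuals of variance
#' `(1 - h2) sigma2_y`. Useful when genotypes are unavailable (pedigree-only
#' A, or H).
#'
#' @param W symmetric relationship matrix with sample ids as dimnames.
#' @param h2 heritability in (0, 1).
#' @param sigma2_y phenotypic variance.
#' @param seed optional integer seed.
#' @return A `sim_trait` (with `alpha = NULL`).
#' @export
simulate_trait_from_W <- function(W, h2, sigma2_y = 100, seed = NULL) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (max(abs(W - t(W))) > 1e-8 * max(abs(W))) stop("W must be symmetric")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be strictly inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  ch <- .chol_jitter(W)
  g <- drop(crossprod(ch, stats::rnorm(nrow(W)))) * sqrt(h2 * sigma2_y)
  eps <- stats::rnorm(nrow(W), 0, sqrt((1 - h2) * sigma2_y))
  y <- g + eps
  names(g) <- names(eps) <- names(y) <- rownames(W)
  structure(list(y = y, g_true = g, epsilon = eps, alpha = NULL,
                 qtl_ids = NULL, h2 = h2, sigma2_y = sigma2_y),
            class = "sim_trait")
}
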