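#' Centre and scale a genotype matrix
#'
#' Produces `M = (dosages - 2p) * (sum_j 2 p_j (1 - p_j))^(-1/2)`, the
#' centred and scaled SNP matrix whose cross-product is the genomic
#' relationship matrix (VanRaden's first method). The frequencies default to
#' the observed ones; supplying frequencies from another population (or the
#' combined set) is how between-population frequency differences enter, or
#' are removed from, downstream comparisons.
#'
#' @param geno a [geno_matrix()] or a plain dosage matrix with dimnames.
#' @param freqs optional per-variant allele frequencies in (0, 1), in
#'   variant order.
#' @return An object of class `scaled_geno` with elements `values` (the
#'   n x m matrix M), `freqs` and `scale_factor`.
#' @export
center_scale <- function(geno, freqs = NULL) {
  dos <- if (inherits(geno, "geno_matrix")) geno$dosages else as.matrix(geno)
  if (is.null(freqs)) freqs <- colMeans(dos) / 2
  if (length(freqs) != ncol(dos))
    stop("freqs must have one entry per variant")
  bad <- which(freqs <= 0 | freqs >= 1)
  if (length(bad))
    stop("allele frequency outside (0, 1) for variant(s): ",
         paste(utils::head(colnames(dos)[bad], 5L), collapse = ", "),
         "; drop monomorphic variants first")
  sf <- 1 / sqrt(sum(2 * freqs * (1 - freqs)))
  M <- sweep(dos, 2L, 2 * freqs) * sf
  structure(list(values = M, freqs = freqs, scale_factor = sf),
            class = "scaled_geno")
}

#' Genomic relationship matrix
#'
#' `G = M M'` from the centred and scaled genotypes of [center_scale()].
#'
#' @param M a `scaled_geno` object.
#' @return Symmetric n x n matrix with sample ids as dimnames and
#'   attribute `kind = "G"`.
#' @export
build_G <- function(M) {
  stopifnot(inherits(M, "scaled_geno"))
  if (nrow(M$values) < 2L) stop("need at least 2 individuals")
  G <- tcrossprod(M$values)
  attr(G, "kind") <- "G"
  G
}

## Prune a pedigree so ancestors more than max_depth generations above any
## requested id become unknown founders.
.prune_pedigree <- function(ped, ids, max_depth) {
  depth <- stats::setNames(rep(Inf, nrow(ped)), ped$id)
  depth[ids] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(ped))) {
      d <- depth[ped$id[k]] + 1
      for (par in c(ped$sire[k], ped$dam[k])) {
        if (par != "0" && par %in% ped$id && d < depth[par]) {
          depth[par] <- d; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  keep <- ped$id[depth[ped$id] <= max_depth]
  out <- ped[ped$id %in% keep, , drop = FALSE]
  out$sire[!(out$sire %in% keep)] <- "0"
  out$dam[!(out$dam %in% keep)] <- "0"
  out
}

#' Pedigree (numerator) relationship matrix
#'
#' Tabular-method additive relationships. Ancestors more than `max_depth`
#' generations above the requested individuals are treated as unknown
#' founders, i.e. the pedigree is traced back at most `max_depth`
#' generations (default 3).
#'
#' @param ped pedigree data frame with columns id, sire, dam ("0" =
#'   unknown), already acyclic; see [read_pedigree()].
#' @param ids individuals to report (default: everyone); all must appear in
#'   the pedigree.
#' @param max_depth generations traced back from `ids`.
#' @return Symmetric relationship matrix over `ids`, attribute `kind = "A"`.
#' @export
build_A <- function(ped, ids = NULL, max_depth = 3) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (is.null(ids)) ids <- ped$id
  miss <- setdiff(ids, ped$id)
  if (length(miss)) stop("id(s) absent from pedigree: ", paste(miss, collapse = ", "))
  ped <- .prune_pedigree(ped, ids, max_depth)
  ped <- .topo_sort_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)   # NA for unknown
  di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) + (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- A[i, j] <- aij
    }
  }
  A <- A[ids, ids, drop = FALSE]
  attr(A, "kind") <- "A"
  A
}

#' Single-step relationship matrix
#'
#' Combines the pedigree matrix `A` with a genomic matrix `G` on the
#' genotyped subset via the standard block formula: with g = genotyped and
#' u = ungenotyped,
#' `H_gg = G*`, `H_ug = A_ug A_gg^-1 G*`,
#' `H_uu = A_uu + A_ug A_gg^-1 (G* - A_gg) A_gg^-1 A_gu`, where
#' `G* = blend_beta * G + (1 - blend_beta) * A_gg`.
#'
#' @param A pedigree relationship matrix (dimnames = ids).
#' @param G genomic relationship matrix over the genotyped ids.
#' @param genotyped_ids ids (subset of A's ids) present in `G`.
#' @param blend_beta weight of G in the blended `G*` (default 0.95).
#' @return Symmetric matrix over A's ids, attribute `kind = "H"`.
#' @export
build_H <- function(A, G, genotyped_ids, blend_beta = 0.95) {
  ids <- rownames(A)
  if (!all(genotyped_ids %in% ids)) stop("genotyped_ids must be a subset of A's ids")
  if (length(genotyped_ids) == 0L) {
    H <- A; attr(H, "kind") <- "H"; return(H)
  }
  if (!all(genotyped_ids %in% rownames(G))) stop("G must be indexed by genotyped_ids")
  g <- genotyped_ids
  u <- setdiff(ids, g)
  Agg <- A[g, g, drop = FALSE]
  Gs <- blend_beta * G[g, g, drop = FALSE] + (1 - blend_beta) * Agg
  H <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  H[g, g] <- Gs
  if (length(u)) {
    Agg_inv <- tryCatch(solve(Agg), error = function(e)
      stop("A_gg is singular (condition number ~ ", format(kappa(Agg), digits = 3), ")"))
    P <- A[u, g, drop = FALSE] %*% Agg_inv         # A_ug A_gg^-1
    H[u, g] <- P %*% Gs
    H[g, u] <- t(H[u, g])
    H[u, u] <- A[u, u, drop = FALSE] + P %*% (Gs - Agg) %*% t(P)
  }
  H <- (H + t(H)) / 2
  attr(H, "kind") <- "H"
  H
}

#' Reference/target split of a relationship matrix
#'
#' @param reference ids of the phenotyped reference population.
#' @param target ids of the non-phenotyped target population.
#' @return An object of class `partition`.
#' @export
population_partition <- function(reference, target) {
  reference <- as.character(reference); target <- as.character(target)
  if (!length(reference) || !length(target))
    stop("reference and target must both be non-empty")
  if (length(intersect(reference, target)))
    stop("reference and target ids overlap: ",
         paste(utils::head(intersect(reference, target), 5L), collapse = ", "))
  structure(list(reference = reference, target = target), class = "partition")
}

#' Partition W into reference/target blocks
#'
#' Extracts `W11` (reference x reference), `W12`, `W21 = t(W12)` and `W22`
#' by id, regardless of the storage order of `W`.
#'
#' @param W symmetric relationship matrix with ids as dimnames.
#' @param split a [population_partition()].
#' @return List with elements `W11`, `W12`, `W21`, `W22`.
#' @export
partition_W <- function(W, split) {
  stopifnot(inherits(split, "partition"))
  ids <- rownames(W)
  miss <- setdiff(c(split$reference, split$target), ids)
  if (length(miss)) stop("partition id(s) absent from W: ", paste(miss, collapse = ", "))
  r <- split$reference; t2 <- split$target
  list(W11 = W[r, r, drop = FALSE], W12 = W[r, t2, drop = FALSE],
       W21 = W[t2, r, drop = FALSE], W22 = W[t2, t2, drop = FALSE])
}
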