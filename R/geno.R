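#' SNP genotype container
#'
#' Bundles a samples-by-variants dosage matrix with the genetic map and,
#' optionally, the underlying phased haplotypes. Dosages count copies of the
#' alternative allele, so every entry is 0, 1 or 2 and, when haplotypes are
#' present, each dosage equals the sum of the two haplotype alleles.
#'
#' @param dosages integer matrix, samples in rows, variants in columns; both
#'   dimensions must be named (sample ids, variant ids).
#' @param chrom integer vector, chromosome index per variant.
#' @param pos_cM numeric vector, map position in centimorgans per variant;
#'   strictly increasing within each chromosome.
#' @param haplotypes optional 0/1 integer matrix with two rows per sample
#'   (rows `<id>_h1`, `<id>_h2`, in sample order).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, chrom, pos_cM, haplotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosages must carry sample ids (rownames) and variant ids (colnames)")
  m <- ncol(dosages)
  if (length(chrom) != m || length(pos_cM) != m)
    stop("chrom and pos_cM must have one entry per variant")
  if (anyNA(dosages))
    stop("missing dosages are not allowed; the model requires complete data")
  if (!all(dosages %in% 0:2))
    stop("dosages must be 0, 1 or 2")
  for (ch in unique(chrom)) {
    p <- pos_cM[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("pos_cM must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    if (nrow(haplotypes) != 2L * nrow(dosages) || ncol(haplotypes) != m)
      stop("haplotypes must have two rows per sample and one column per variant")
    if (!all(haplotypes %in% 0:1)) stop("haplotype alleles must be 0/1")
    dos <- haplotypes[seq(1L, nrow(haplotypes), 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), 2L), , drop = FALSE]
    if (any(dos != dosages))
      stop("dosages are inconsistent with the haplotypes")
  }
  structure(list(dosages = dosages, chrom = as.integer(chrom),
                 pos_cM = as.numeric(pos_cM), haplotypes = haplotypes),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages), "variants;",
      length(unique(x$chrom)), "chromosome(s);",
      if (is.null(x$haplotypes)) "unphased\n" else "phased\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Sample and variant identifiers of a genotype matrix
#' @param geno a [geno_matrix()].
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(geno) rownames(geno$dosages)

#' @rdname sample_ids
#' @export
variant_ids <- function(geno) colnames(geno$dosages)

#' Observed alternative-allele frequencies
#'
#' @param geno a [geno_matrix()].
#' @return Named numeric vector of per-variant allele frequencies
#'   (mean dosage / 2).
#' @export
allele_freqs <- function(geno) colMeans(geno$dosages) / 2

#' Subset a genotype matrix by sample ids
#'
#' @param geno a [geno_matrix()].
#' @param ids sample identifiers to keep, in the requested order.
#' @return A [geno_matrix()] restricted to `ids`.
#' @export
subset_samples <- function(geno, ids) {
  miss <- setdiff(ids, sample_ids(geno))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  hap <- NULL
  if (!is.null(geno$haplotypes)) {
    idx <- match(ids, sample_ids(geno))
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- geno$haplotypes[rows, , drop = FALSE]
  }
  geno_matrix(geno$dosages[ids, , drop = FALSE], geno$chrom, geno$pos_cM, hap)
}
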