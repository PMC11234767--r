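## Kahn topological sort: parents before offspring; reports any cycle.
.topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  parents <- cbind(idx[ped$sire], idx[ped$dam])   # NA = unknown/outside
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[i, ]) if (!is.na(p))
    children[[p]] <- c(children[[p]], i)
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n)
    stop("pedigree contains a cycle involving: ",
         paste(ped$id[setdiff(seq_len(n), order)], collapse = ", "))
  ped[order, , drop = FALSE]
}

#' Read a pedigree CSV
#'
#' Expects columns `id,sire,dam` (plus optional `sex`, `generation`).
#' Unknown parents may be written as `0`, `NA` or an empty field and are
#' normalized to `"0"`. Records are returned topologically ordered (parents
#' first); a cycle, including an individual listed as its own ancestor, is
#' an error naming the individuals involved.
#'
#' @param path CSV file path.
#' @return Ordered pedigree data frame with columns id, sire, dam, sex,
#'   generation.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree file must have columns id, sire, dam")
  for (col in c("sire", "dam"))
    ped[[col]][is.na(ped[[col]]) | ped[[col]] %in% c("", "NA")] <- "0"
  if (anyDuplicated(ped$id))
    stop("duplicate id(s): ", paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  ped <- .topo_sort_pedigree(ped)
  if (is.null(ped$sex)) ped$sex <- NA_character_
  if (is.null(ped$generation)) {
    gen <- stats::setNames(integer(nrow(ped)), ped$id)
    for (i in seq_len(nrow(ped))) {
      pg <- gen[c(ped$sire[i], ped$dam[i])]
      gen[ped$id[i]] <- if (all(is.na(pg))) 0L else max(pg, na.rm = TRUE) + 1L
    }
    ped$generation <- unname(gen[ped$id])
  } else ped$generation <- as.integer(ped$generation)
  rownames(ped) <- NULL
  ped
}

#' Write a pedigree CSV
#' @param ped pedigree data frame.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(ped[, intersect(c("id", "sire", "dam", "sex", "generation"),
                                   names(ped))], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pre-corrected phenotypes
#'
#' CSV with columns `id,value`; values must be numeric and complete (the
#' model equations assume complete records, so missing or non-numeric
#' values are an error, not imputed) and ids unique.
#'
#' @param path CSV file path.
#' @return Named numeric vector.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "value") %in% names(d)))
    stop("phenotype file must have columns id, value")
  if (anyDuplicated(d$id))
    stop("duplicate phenotype id(s): ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  v <- suppressWarnings(as.numeric(d$value))
  bad <- which(is.na(v))
  if (length(bad))
    stop("non-numeric phenotype value in row(s): ", paste(bad, collapse = ", "),
         " (id ", paste(d$id[bad], collapse = ", "), ")")
  stats::setNames(v, d$id)
}

#' Write phenotypes (and optionally true breeding values)
#' @param trait a `sim_trait` or a named numeric vector.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(trait, path) {
  if (inherits(trait, "sim_trait"))
    d <- data.frame(id = names(trait$y), y = unname(trait$y),
                    g_true = unname(trait$g_true))
  else d <- data.frame(id = names(trait), value = unname(trait))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference/target partition file
#'
#' CSV with columns `id,role`, role in {reference, target}.
#' @param path CSV file path.
#' @return A [population_partition()].
#' @export
read_partition <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "role") %in% names(d)))
    stop("partition file must have columns id, role")
  if (!all(d$role %in% c("reference", "target")))
    stop("role must be 'reference' or 'target'")
  population_partition(d$id[d$role == "reference"], d$id[d$role == "target"])
}

#' Write a partition file
#' @param split a [population_partition()].
#' @param path output CSV path.
#' @export
write_partition <- function(split, path) {
  d <- data.frame(id = c(split$reference, split$target),
                  role = rep(c("reference", "target"),
                             c(length(split$reference), length(split$target))))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as a dosage TSV (plus map TSV)
#'
#' The dosage table has samples in rows (first column `id`) and a header of
#' variant ids; the companion `<path>.map` TSV stores variant id,
#' chromosome and map position (cM).
#'
#' @param geno a [geno_matrix()].
#' @param path output TSV path.
#' @export
write_dosage <- function(geno, path) {
  d <- data.frame(id = sample_ids(geno), geno$dosages, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  map <- data.frame(variant = variant_ids(geno), chrom = geno$chrom,
                    pos_cM = geno$pos_cM)
  utils::write.table(map, paste0(path, ".map"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as VCF
#'
#' Minimal VCF v4.2 with a GT field; phased (`|`) when haplotypes are
#' present, otherwise unphased dosage-consistent genotypes. Map positions
#' in centimorgans are preserved in the INFO field (`CM=`); the integer POS
#' column is the cM position scaled by 1000 (made strictly increasing).
#'
#' @param geno a [geno_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf <- function(geno, path) {
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Map position in cM\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               sprintf("##contig=<ID=%d>", unique(geno$chrom)),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids(geno)), collapse = "\t")), con)
  pos <- integer(m)
  for (ch in unique(geno$chrom)) {
    i <- which(geno$chrom == ch)
    p <- as.integer(round(geno$pos_cM[i] * 1000)) + 1L
    for (j in seq_along(p)[-1L]) if (p[j] <= p[j - 1L]) p[j] <- p[j - 1L] + 1L
    pos[i] <- p
  }
  if (is.null(geno$haplotypes)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[geno$dosages + 1L], n, m)
  } else {
    h1 <- geno$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- geno$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, m)
  }
  lines <- paste(geno$chrom, pos, variant_ids(geno), "A", "B", ".", "PASS",
                 sprintf("CM=%.6g", geno$pos_cM), "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF parsing is delegated to the vcfR package. Only biallelic sites with
#' complete genotype calls are accepted: a multiallelic record or a missing
#' call is an error naming the site (the downstream matrices require
#' complete data; nothing is imputed). Map positions are taken from a
#' `CM=` INFO key when present, else `POS / 1000`; for a dosage TSV they
#' come from the companion `<path>.map` written by [write_dosage()], or
#' default to the variant index on one chromosome.
#'
#' @param path input file path.
#' @param format `"vcf"` or `"dosage"`.
#' @return A [geno_matrix()] (phased when the VCF is fully phased).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dosage") {
    d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
    dos <- as.matrix(d[, -1L, drop = FALSE])
    rownames(dos) <- d[[1L]]
    storage.mode(dos) <- "integer"
    mapf <- paste0(path, ".map")
    if (file.exists(mapf)) {
      map <- utils::read.table(mapf, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      map <- map[match(colnames(dos), map$variant), ]
      return(geno_matrix(dos, map$chrom, map$pos_cM))
    }
    return(geno_matrix(dos, rep(1L, ncol(dos)), seq_len(ncol(dos))))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multiallelic site(s) rejected: ",
         paste(utils::head(fix[multi, "ID"], 5L), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (anyNA(gt) || any(grepl("\\.", gt)))
    stop("missing genotype call(s); the method requires complete data")
  phased <- all(grepl("|", gt, fixed = TRUE))
  m <- nrow(gt); n <- ncol(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), m, n)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), m, n)
  dos <- matrix(a1 + a2, m, n, dimnames = dimnames(gt))
  info <- fix[, "INFO"]
  cm <- suppressWarnings(as.numeric(sub(".*CM=([-0-9.eE+]+).*", "\\1", info)))
  if (anyNA(cm)) cm <- as.numeric(fix[, "POS"]) / 1000
  hap <- NULL
  if (phased) {
    hap <- matrix(0L, 2L * n, m)
    hap[seq(1L, 2L * n, 2L), ] <- t(a1)
    hap[seq(2L, 2L * n, 2L), ] <- t(a2)
    rownames(hap) <- paste0(rep(colnames(gt), each = 2L), c("_h1", "_h2"))
    colnames(hap) <- rownames(gt)
  }
  geno_matrix(t(dos), as.integer(fix[, "CHROM"]), cm, hap)
}

#' Write a relationship matrix as TSV
#' @param W symmetric matrix with ids as dimnames.
#' @param path output path.
#' @export
write_relmat <- function(W, path) {
  d <- data.frame(id = rownames(W), W, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relationship matrix TSV written by [write_relmat()]
#' @param path input path.
#' @return Symmetric matrix with ids as dimnames.
#' @export
read_relmat <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  W <- as.matrix(d[, -1L, drop = FALSE])
  rownames(W) <- d[[1L]]
  W
}
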