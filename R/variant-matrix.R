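#' Construct a variant matrix
#'
#' A `variant_matrix` holds the biallelic-SNP view of one contig: 1-based
#' positions, a variants x samples matrix of alternate-allele dosages
#' (0/1/2, `NA` = missing), and, when every retained genotype is phased, a
#' variants x 2*samples binary haplotype matrix whose column pairs
#' `(2i - 1, 2i)` belong to sample `i`.
#'
#' @param contig Contig (chromosome) identifier, length-1 character.
#' @param positions Integer vector of 1-based, strictly increasing positions.
#' @param genotypes Integer matrix, `length(positions)` rows, one column per
#'   sample; values in `{0, 1, 2, NA}`.
#' @param sample_ids Character vector of sample identifiers (column names).
#' @param haplotypes Optional binary matrix with `2 * n_samples` columns;
#'   column pairs must sum to the non-missing dosages in `genotypes`.
#' @param quality Optional numeric per-variant quality scores (VCF QUAL).
#' @param biallelic Logical per-variant flag: `TRUE` when the record is a
#'   biallelic SNP. Multi-allelic or indel records read from a VCF are kept
#'   but flagged `FALSE` so [filter_variants()] can drop them.
#'
#' @return An object of class `variant_matrix`.
#' @seealso [read_vcf()], [filter_variants()]
#' @export
variant_matrix <- function(contig, positions, genotypes, sample_ids,
                           haplotypes = NULL, quality = NULL,
                           biallelic = NULL) {
  positions <- as.integer(positions)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(positions)) {
    stop("genotypes must have one row per position", call. = FALSE)
  }
  if (ncol(genotypes) != length(sample_ids)) {
    stop("genotypes must have one column per sample", call. = FALSE)
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing within a contig",
         call. = FALSE)
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(quality)) quality <- rep(NA_real_, length(positions))
  if (is.null(biallelic)) biallelic <- rep(TRUE, length(positions))
  colnames(genotypes) <- sample_ids
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    if (ncol(haplotypes) != 2L * length(sample_ids) ||
        nrow(haplotypes) != length(positions)) {
      stop("haplotypes must be n_variants x 2*n_samples", call. = FALSE)
    }
    dos <- haplotypes[, seq(1L, ncol(haplotypes), by = 2L), drop = FALSE] +
      haplotypes[, seq(2L, ncol(haplotypes), by = 2L), drop = FALSE]
    ok <- is.na(genotypes) | dos == genotypes
    if (!all(ok)) {
      stop("haplotype column pairs must sum to the genotype dosage",
           call. = FALSE)
    }
  }
  structure(
    list(contig = as.character(contig)[1], positions = positions,
         genotypes = genotypes, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         quality = as.numeric(quality), biallelic = as.logical(biallelic)),
    class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: contig %s, %d variants x %d samples (%s)\n",
              x$contig, length(x$positions), length(x$sample_ids),
              if (is.null(x$haplotypes)) "unphased" else "phased"))
  if (length(x$positions)) {
    cat(sprintf("  positions %d..%d; %d biallelic SNPs\n",
                min(x$positions), max(x$positions), sum(x$biallelic)))
  }
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) dim(x$genotypes)

#' Number of variants in a variant matrix
#'
#' @param vm A [variant_matrix()].
#' @return Integer count of variant records.
#' @export
n_variants <- function(vm) length(vm$positions)

#' Subset a variant matrix by variant index
#'
#' @param vm A [variant_matrix()].
#' @param idx Integer or logical index over variants (rows).
#' @return A `variant_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(vm, idx) {
  variant_matrix(vm$contig, vm$positions[idx],
                 vm$genotypes[idx, , drop = FALSE], vm$sample_ids,
                 haplotypes = if (!is.null(vm$haplotypes))
                   vm$haplotypes[idx, , drop = FALSE],
                 quality = vm$quality[idx], biallelic = vm$biallelic[idx])
}

#' Extract the genotype columns of a set of samples
#'
#' @param vm A [variant_matrix()].
#' @param samples Character vector of sample ids.
#' @return Integer dosage matrix (variants x samples).
#' @export
genotypes_of <- function(vm, samples) {
  miss <- setdiff(samples, vm$sample_ids)
  if (length(miss)) {
    stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  vm$genotypes[, samples, drop = FALSE]
}

#' Extract the haplotype columns of a set of samples
#'
#' @inheritParams genotypes_of
#' @return Binary haplotype matrix (variants x 2*length(samples)).
#' @export
haplotypes_of <- function(vm, samples) {
  if (is.null(vm$haplotypes)) {
    stop("variant matrix is not phased; haplotypes unavailable", call. = FALSE)
  }
  idx <- match(samples, vm$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample(s): ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  vm$haplotypes[, cols, drop = FALSE]
}
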