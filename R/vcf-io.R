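#' Read a VCF file into per-contig variant matrices
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and returns one [variant_matrix()]
#' per contig, in file order. Genotypes are coded as alternate-allele dosage
#' 0/1/2 with `NA` for missing; calls carrying an allele index above 1
#' (multi-allelic records) are set `NA` and the record is flagged
#' non-biallelic so [filter_variants()] removes it. Haplotypes are populated
#' only when every retained genotype call is phased (`|` separator).
#'
#' @param path Path to a VCF file (plain text or bgzip).
#' @param samples Optional character vector restricting the sample columns;
#'   an unknown sample id is an error.
#'
#' @return Named list of `variant_matrix`, one per contig.
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) {
    samples <- all_samples
  } else {
    miss <- setdiff(samples, all_samples)
    if (length(miss)) {
      stop("sample(s) not in VCF: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, samples, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, samples))

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  biallelic <- !grepl(",", alt, fixed = TRUE) & !is.na(alt) & alt != "." &
    nchar(ref) == 1L & nchar(alt) == 1L

  parsed <- parse_gt_matrix(gt)

  out <- list()
  for (ctg in unique(chrom)) {
    i <- which(chrom == ctg)
    i <- i[order(pos[i])]
    haps <- NULL
    gsub_block <- parsed$dosage[i, , drop = FALSE]
    if (parsed$all_phased) {
      haps <- parsed$haps[i, , drop = FALSE]
    }
    out[[ctg]] <- variant_matrix(
      contig = ctg, positions = pos[i], genotypes = gsub_block,
      sample_ids = samples, haplotypes = haps, quality = qual[i],
      biallelic = biallelic[i])
  }
  out
}

# GT strings -> dosage matrix, haplotype matrix, phase flag.
# Allele indices > 1 (multi-allelic calls) become NA dosages.
parse_gt_matrix <- function(gt) {
  nr <- nrow(gt); nc <- ncol(gt)
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  bad_format <- !is.na(gt) & !(sep %in% c("/", "|") &
                                 a1 %in% c("0", "1", "2", "3", ".") &
                                 a2 %in% c("0", "1", "2", "3", "."))
  if (any(bad_format)) {
    k <- which(bad_format)[1]
    stop(sprintf("malformed GT field '%s' at record %d, sample %d",
                 gt[k], (k - 1L) %% nr + 1L, (k - 1L) %/% nr + 1L),
         call. = FALSE)
  }
  num1 <- suppressWarnings(as.integer(a1))
  num2 <- suppressWarnings(as.integer(a2))
  dosage <- num1 + num2
  dosage[is.na(gt) | is.na(num1) | is.na(num2)] <- NA_integer_
  dosage[!is.na(num1) & num1 > 1L] <- NA_integer_
  dosage[!is.na(num2) & num2 > 1L] <- NA_integer_
  dim(dosage) <- c(nr, nc)
  all_phased <- all(is.na(gt) | sep == "|") && !anyNA(dosage)
  haps <- NULL
  if (all_phased) {
    haps <- matrix(0L, nr, 2L * nc)
    haps[, seq(1L, 2L * nc, by = 2L)] <- num1
    haps[, seq(2L, 2L * nc, by = 2L)] <- num2
  }
  list(dosage = dosage, haps = haps, all_phased = all_phased)
}

#' Write a variant matrix as a plain-text VCF 4.2 file
#'
#' Emits GT-only records; phased (`|`) when the matrix carries haplotypes,
#' unphased (`/`) otherwise with heterozygotes written `0/1`.
#'
#' @param vm A [variant_matrix()].
#' @param path Output path.
#' @param contig_length Optional contig length for the `##contig` header line.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vm, path, contig_length = NULL) {
  n <- n_variants(vm)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_length)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", vm$contig,
                          as.integer(contig_length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", vm$sample_ids),
                      collapse = "\t"))
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  if (!is.null(vm$haplotypes)) {
    h1 <- vm$haplotypes[, seq(1L, ncol(vm$haplotypes), 2L), drop = FALSE]
    h2 <- vm$haplotypes[, seq(2L, ncol(vm$haplotypes), 2L), drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), n, length(vm$sample_ids))
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[vm$genotypes + 1L], n,
                 length(vm$sample_ids))
    gt[is.na(vm$genotypes)] <- "./."
  }
  qual <- ifelse(is.na(vm$quality), ".",
                 formatC(vm$quality, format = "fg"))
  rows <- paste(vm$contig, vm$positions, ".", "A", "T", qual, "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
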