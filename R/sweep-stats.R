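#' Per-SNP major/minor allele counts within one population
#'
#' Counts are taken over non-missing genotypes only; no imputation. At each
#' SNP the more frequent allele in the population is labelled major (ties
#' resolved towards the reference allele).
#'
#' @param vm A [variant_matrix()].
#' @param samples Character vector of sample ids forming the population.
#' @return Data frame with columns `n_major`, `n_minor` (one row per SNP).
#' @export
allele_counts <- function(vm, samples) {
  g <- genotypes_of(vm, samples)
  n_alt <- rowSums(g, na.rm = TRUE)
  n_tot <- 2L * rowSums(!is.na(g))
  n_ref <- n_tot - n_alt
  data.frame(n_major = pmax(n_ref, n_alt), n_minor = pmin(n_ref, n_alt))
}

#' Pooled heterozygosity (Hp) of one window
#'
#' `Hp = 2 * sum(nMAJ) * sum(nMIN) / (sum(nMAJ) + sum(nMIN))^2`, where the
#' sums run over the major and minor allele counts of every SNP in the
#' window. The statistic lies in \[0, 0.5\]; values near 0 indicate loss of
#' diversity, the signature of a sweep.
#'
#' @param n_major,n_minor Per-SNP major/minor allele counts of the window's
#'   SNPs (equal length numeric vectors).
#' @return Hp, or `NA` for an empty window or zero total counts.
#' @export
pooled_heterozygosity <- function(n_major, n_minor) {
  s_maj <- sum(n_major)
  s_min <- sum(n_minor)
  tot <- s_maj + s_min
  if (length(n_major) == 0L || tot == 0) return(NA_real_)
  2 * s_maj * s_min / tot^2
}

#' Per-SNP Weir-Cockerham FST between two populations
#'
#' The two-population Weir & Cockerham (1984) variance-components estimator
#' `theta = a / (a + b + c)` without an inbreeding term, computed per SNP
#' from non-missing diploid genotypes. Sites monomorphic across both
#' populations, or with fewer than two non-missing alleles in either
#' population, return `NA`. Estimates can be slightly negative; they never
#' exceed 1.
#'
#' @param vm A [variant_matrix()].
#' @param samples_a,samples_b Sample ids of the two populations.
#' @param estimator `"wc"` (Weir-Cockerham, default) or `"hudson"`
#'   (Hudson's estimator from allele frequencies and sample sizes).
#' @return Numeric vector of per-SNP FST estimates.
#' @export
snp_fst <- function(vm, samples_a, samples_b,
                    estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ga <- genotypes_of(vm, samples_a)
  gb <- genotypes_of(vm, samples_b)
  na_ <- rowSums(!is.na(ga))          # diploid sample sizes per SNP
  nb_ <- rowSums(!is.na(gb))
  pa <- rowSums(ga, na.rm = TRUE) / (2 * na_)
  pb <- rowSums(gb, na.rm = TRUE) / (2 * nb_)
  if (estimator == "hudson") {
    num <- (pa - pb)^2 -
      pa * (1 - pa) / (na_ * 2 - 1) - pb * (1 - pb) / (nb_ * 2 - 1)
    den <- pa * (1 - pb) + pb * (1 - pa)
    out <- num / den
  } else {
    ha <- rowMeans(ga == 1L, na.rm = TRUE)  # observed het fractions
    hb <- rowMeans(gb == 1L, na.rm = TRUE)
    comp <- wc_components(na_, nb_, pa, pb, ha, hb)
    out <- comp$a / (comp$a + comp$b + comp$c)
  }
  undefined <- na_ < 1 | nb_ < 1 | (na_ == 1 & nb_ == 1) |
    (pmin(pa, pb) == 0 & pmax(pa, pb) == 0) |
    (pmin(pa, pb) == 1 & pmax(pa, pb) == 1)
  out[undefined] <- NA_real_
  out
}

# Weir & Cockerham (1984) variance components for two populations,
# vectorised over SNPs. n: diploid counts, p: alt frequencies, h: observed
# heterozygote fractions.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Average per-SNP FST over a window
#'
#' The window statistic is the arithmetic mean of the defined per-SNP
#' estimates (average-of-ratios); undefined SNPs are excluded.
#'
#' @param fst_values Numeric vector of per-SNP FST values (with `NA`s).
#' @param snp_idx Integer indices of the window's SNPs.
#' @param min_snps Minimum number of defined per-SNP values; windows below
#'   it return `NA`.
#' @param method `"mean"` (average of per-SNP ratios, default). Reserved
#'   for a ratio-of-sums variant via [fst_track()].
#' @return Mean FST, or `NA`.
#' @export
window_fst <- function(fst_values, snp_idx, min_snps = 1,
                       method = "mean") {
  v <- fst_values[snp_idx]
  v <- v[!is.na(v)]
  if (length(v) < min_snps) return(NA_real_)
  mean(v)
}

#' Per-site components of nucleotide diversity
#'
#' Unbiased per-site heterozygosity `2 * p * (1 - p) * n / (n - 1)` with
#' `n` the non-missing allele count; sites with `n < 2` contribute `NA`.
#'
#' @param vm A [variant_matrix()].
#' @param samples Sample ids of the population.
#' @return Numeric vector, one value per SNP.
#' @export
pi_site <- function(vm, samples) {
  g <- genotypes_of(vm, samples)
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / n
  out <- 2 * p * (1 - p) * n / (n - 1)
  out[n < 2] <- NA_real_
  out
}

#' Nucleotide diversity (theta-pi) of one window
#'
#' Mean pairwise difference per bp: the per-site unbiased heterozygosities
#' of the window's SNPs are summed and divided by the window length in bp.
#' Monomorphic sites contribute zero, so only segregating sites need to be
#' present in the variant matrix.
#'
#' @param site_pi Per-site values from [pi_site()].
#' @param snp_idx Integer indices of the window's SNPs.
#' @param window_length Window length in bp.
#' @param min_snps Minimum number of SNPs with defined values;
#'   windows below it return `NA` (an empty genome region is a legitimate
#'   zero only when the window has enough genotyped SNPs to say so).
#' @return Theta-pi per bp, or `NA`.
#' @export
window_pi <- function(site_pi, snp_idx, window_length, min_snps = 1) {
  v <- site_pi[snp_idx]
  v <- v[!is.na(v)]
  if (length(v) < min_snps) return(NA_real_)
  sum(v) / window_length
}

#' Log2 ratio of two theta-pi tracks
#'
#' @param pi_num,pi_den Per-window theta-pi values on the same window
#'   universe (numerator and denominator populations).
#' @param pseudocount Added to both numerator and denominator before the
#'   ratio; the default 0 leaves zero-denominator windows `NA` rather than
#'   producing infinities.
#' @return Per-window `log2(pi_num / pi_den)`; `NA` where either input is
#'   missing or the (pseudocounted) denominator is zero.
#' @export
pi_ratio_log2 <- function(pi_num, pi_den, pseudocount = 0) {
  if (length(pi_num) != length(pi_den)) {
    stop("theta-pi tracks are on different window universes", call. = FALSE)
  }
  num <- pi_num + pseudocount
  den <- pi_den + pseudocount
  out <- log2(num / den)
  out[is.na(pi_num) | is.na(pi_den) | den == 0 | !is.finite(out)] <- NA_real_
  out
}

#' Genome-wide Z-transformation
#'
#' Standardises a per-window statistic to mean 0, standard deviation 1 over
#' all non-missing windows jointly, using the population (divide-by-N)
#' standard deviation. Missing windows propagate as `NA`.
#'
#' @param x Numeric vector of per-window values.
#' @param track Optional track name used in error messages.
#' @return Z values, same length as `x`.
#' @export
z_transform <- function(x, track = "statistic") {
  ok <- !is.na(x)
  if (sum(ok) < 2L) {
    stop("Z-transform of '", track, "': fewer than 2 non-missing windows",
         call. = FALSE)
  }
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  if (s == 0) {
    stop("Z-transform of '", track, "': zero spread", call. = FALSE)
  }
  (x - m) / s
}
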