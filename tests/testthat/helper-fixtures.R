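# Fixture builders and independent brute-force oracles used across tests.

# --- builders ---------------------------------------------------------------

# random phased variant matrix: n_snp sites x n_sample diploids
random_vm <- function(seed, n_snp = 50, n_sample = 10, contig = "chr1",
                      L = 100000) {
  set.seed(seed)
  positions <- sort(sample.int(L, n_snp))
  haps <- matrix(rbinom(n_snp * 2 * n_sample, 1,
                        rep(runif(n_snp, 0.05, 0.95), 2 * n_sample)),
                 n_snp, 2 * n_sample)
  h1 <- haps[, seq(1, 2 * n_sample, 2), drop = FALSE]
  h2 <- haps[, seq(2, 2 * n_sample, 2), drop = FALSE]
  variant_matrix(contig, positions, h1 + h2,
                 sample_ids = paste0("s", seq_len(n_sample)),
                 haplotypes = haps, quality = rep(60, n_snp))
}

write_vcf_text <- function(path, chrom, pos, ref, alt, qual, gt) {
  # gt: character matrix, variants x samples
  samples <- paste0("s", seq_len(ncol(gt)))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".",
            "GT", gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, rows), path)
  path
}

# --- oracles ----------------------------------------------------------------

# Weir-Cockerham FST through the two-level ANOVA sums of squares on
# per-allele-copy indicator variables (independent of the closed-form
# variance-components route in the package).
fst_anova_oracle <- function(ga, gb) {
  vapply(seq_len(nrow(ga)), function(k) {
    pops <- list(ga[k, ], gb[k, ])
    pops <- lapply(pops, function(g) g[!is.na(g)])
    n <- vapply(pops, length, integer(1))
    if (any(n < 1) || all(n == 1)) return(NA_real_)
    p <- vapply(pops, function(g) mean(g) / 2, numeric(1))
    if (all(p == 0) || all(p == 1)) return(NA_real_)
    r <- 2
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    # sums of squares: among populations, among individuals within
    # populations, within individuals (allele copies)
    ssp <- sum(2 * n * (p - pbar)^2)
    ssi <- 0; ssg <- 0
    for (i in 1:2) {
      for (g in pops[[i]]) {
        xbar <- g / 2
        ssi <- ssi + 2 * (xbar - p[i])^2
        # copies are xbar +/- (0 or 1/2): het -> copies 0,1
        if (g == 1) ssg <- ssg + 2 * 0.25
      }
    }
    msp <- ssp / (r - 1)
    msi <- ssi / (sum(n) - r)
    msg <- ssg / sum(n)
    s2_g <- msg
    s2_i <- (msi - msg) / 2
    s2_p <- (msp - msi) / (2 * nc)
    s2_p / (s2_p + s2_i + s2_g)
  }, numeric(1))
}

# theta-pi from explicit haplotype pairs
pi_pairwise_oracle <- function(haps, window_length) {
  n <- ncol(haps)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + sum(haps[, i] != haps[, j])
    }
  }
  tot / choose(n, 2) / window_length
}

# EHH by explicit pairwise identity over the span core..j
ehh_pairwise_oracle <- function(haps, positions, core, side,
                                cutoff = 0.05, max_gap = 200000) {
  n <- ncol(haps)
  idx_all <- if (side == "downstream") seq(core, nrow(haps))
  else seq(core, 1)
  pair_identical <- function(span) {
    cnt <- 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (all(haps[span, i] == haps[span, j])) cnt <- cnt + 1
      }
    }
    cnt / choose(n, 2)
  }
  dist <- numeric(0); vals <- numeric(0)
  prev_pos <- positions[core]
  for (m in seq_along(idx_all)) {
    j <- idx_all[m]
    if (abs(positions[j] - prev_pos) > max_gap) break
    prev_pos <- positions[j]
    span <- idx_all[seq_len(m)]
    e <- pair_identical(span)
    if (m > 1 && e < cutoff) break
    dist <- c(dist, abs(positions[j] - positions[core]))
    vals <- c(vals, e)
    if (m == 1 && e < cutoff) break
    if (e == 0) break
  }
  list(distance = dist, ehh = vals)
}

# r^2 from explicit two-locus haplotype counts
r2_count_oracle <- function(hi, hj) {
  pA <- mean(hi); pB <- mean(hj)
  pAB <- mean(hi == 1 & hj == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# random additive tree -> distance matrix (via ape) for NJ consistency
random_additive_tree <- function(seed, n_taxa) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.1, 2))
  list(tree = tr, d = cophenetic(tr))
}
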