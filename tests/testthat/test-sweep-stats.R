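test_that("pooled heterozygosity matches the hand-computed formula", {
  # two SNPs (8,2) and (9,1): 2*17*3/20^2
  expect_equal(pooled_heterozygosity(c(8, 9), c(2, 1)), 0.255)
  # all fixed -> 0
  expect_equal(pooled_heterozygosity(c(10, 10), c(0, 0)), 0)
  # equal sums -> the 0.5 maximum
  expect_equal(pooled_heterozygosity(c(6, 4), c(4, 6)), 0.5)
  # empty window -> NA, not zero
  expect_true(is.na(pooled_heterozygosity(numeric(0), numeric(0))))
  expect_true(is.na(pooled_heterozygosity(c(0, 0), c(0, 0))))
})

test_that("Hp is invariant to major/minor labelling and stays in [0, 0.5]", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:50, 1)
    maj <- sample(0:20, n, replace = TRUE)
    mnr <- pmin(maj, sample(0:20, n, replace = TRUE))
    if (sum(maj + mnr) == 0) next
    hp <- pooled_heterozygosity(maj, mnr)
    expect_gte(hp, 0); expect_lte(hp, 0.5)
    # swap labels at random SNPs: formula uses the two sums, so any swap
    # that preserves the sums leaves Hp unchanged; full swap always does
    expect_equal(pooled_heterozygosity(mnr, maj), hp)
  }
})

test_that("Weir-Cockerham FST reproduces fixed differences and the ANOVA oracle", {
  # popA fixed ref, popB fixed alt -> FST 1
  vm <- variant_matrix("c", 1L, matrix(c(0L, 0L, 2L, 2L), 1, 4),
                       paste0("s", 1:4))
  expect_equal(snp_fst(vm, c("s1", "s2"), c("s3", "s4")), 1)

  # identical intermediate frequencies -> small non-positive estimate,
  # exactly the ANOVA-oracle value
  set.seed(1)
  g <- cbind(matrix(rbinom(50 * 10, 2, 0.5), 50, 10),
             matrix(rbinom(50 * 10, 2, 0.5), 50, 10))
  vm2 <- variant_matrix("c", seq_len(50), g, paste0("s", 1:20))
  a_ids <- paste0("s", 1:10); b_ids <- paste0("s", 11:20)
  est <- snp_fst(vm2, a_ids, b_ids)
  oracle <- fst_anova_oracle(g[, 1:10], g[, 11:20])
  expect_equal(est, oracle, tolerance = 1e-12)

  # diverged frequencies p1=0.2, p2=0.8, n=10 diploids each
  set.seed(2)
  g3 <- cbind(matrix(rbinom(100 * 10, 2, 0.2), 100, 10),
              matrix(rbinom(100 * 10, 2, 0.8), 100, 10))
  vm3 <- variant_matrix("c", seq_len(100), g3, paste0("s", 1:20))
  expect_equal(snp_fst(vm3, a_ids, b_ids),
               fst_anova_oracle(g3[, 1:10], g3[, 11:20]),
               tolerance = 1e-12)
  expect_true(all(snp_fst(vm3, a_ids, b_ids) <= 1, na.rm = TRUE))
})

test_that("FST is invariant to sample order within populations", {
  vm <- random_vm(3, n_snp = 40, n_sample = 12)
  a_ids <- paste0("s", 1:6); b_ids <- paste0("s", 7:12)
  est <- snp_fst(vm, a_ids, b_ids)
  expect_equal(snp_fst(vm, sample(a_ids), sample(b_ids)), est)
})

test_that("random splits of a pooled population centre FST on zero", {
  set.seed(42)
  g <- matrix(rbinom(30 * 20, 2, runif(30, 0.2, 0.8)), 30, 20)
  vm <- variant_matrix("c", seq_len(30), g, paste0("s", 1:20))
  means <- replicate(1000, {
    idx <- sample(20, 10)
    mean(snp_fst(vm, paste0("s", idx), paste0("s", setdiff(1:20, idx))),
         na.rm = TRUE)
  })
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 1e-3)
})

test_that("monomorphic and undersized sites are undefined", {
  vm <- variant_matrix("c", c(1L, 2L),
                       matrix(c(0L, 2L, 0L, 2L, 0L, 2L, 0L, 2L), 2, 4),
                       paste0("s", 1:4))
  # site 1: all 0 in both pops -> undefined
  g <- vm$genotypes; g[1, ] <- 0L; g[2, ] <- c(0L, 1L, 2L, 1L)
  vm2 <- variant_matrix("c", c(1L, 2L), g, paste0("s", 1:4))
  est <- snp_fst(vm2, c("s1", "s2"), c("s3", "s4"))
  expect_true(is.na(est[1]))
  expect_false(is.na(est[2]))
})

test_that("window FST averages defined per-SNP values", {
  expect_equal(window_fst(c(0.1, 0.3), 1:2), 0.2)
  expect_equal(window_fst(c(0.4, NA), 1:2), 0.4)
  expect_equal(window_fst(c(1, 1, 1), 1:3), 1)
  expect_true(is.na(window_fst(c(NA, NA), 1:2)))
  expect_true(is.na(window_fst(c(0.5, NA), 1:2, min_snps = 2)))
})

test_that("theta-pi equals the pairwise-difference oracle", {
  # one site, 4 haplotypes, counts 2/2, length 1 bp
  haps <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  vm <- variant_matrix("c", 1L, matrix(c(2L, 0L), 1, 2), c("a", "b"),
                       haplotypes = haps)
  sp <- pi_site(vm, c("a", "b"))
  expect_equal(sp, 2 * 0.25 * 4 / 3)
  expect_equal(window_pi(sp, 1L, 1), pi_pairwise_oracle(haps, 1))
  expect_equal(window_pi(sp, 1L, 1), 4 / 6)

  # random phased fixtures: genotype-based estimator equals the
  # haplotype-pair oracle exactly (counts are identical)
  for (seed in 1:5) {
    vm2 <- random_vm(seed, n_snp = 30, n_sample = 8, L = 5000)
    sp2 <- pi_site(vm2, vm2$sample_ids)
    expect_equal(window_pi(sp2, seq_len(30), 5000),
                 pi_pairwise_oracle(vm2$haplotypes, 5000),
                 tolerance = 1e-12)
  }
})

test_that("theta-pi normalises per bp and is zero when monomorphic", {
  vm <- random_vm(9, n_snp = 20, n_sample = 6, L = 10000)
  sp <- pi_site(vm, vm$sample_ids)
  expect_equal(window_pi(sp, 1:20, 20000),
               window_pi(sp, 1:20, 10000) / 2)
  expect_equal(window_pi(sp, integer(0), 1000, min_snps = 0), 0)
})

test_that("log2 pi ratios handle boundaries and zero denominators", {
  expect_equal(pi_ratio_log2(4, 1), 2)
  expect_equal(pi_ratio_log2(0.3, 0.3), 0)
  expect_true(is.na(pi_ratio_log2(0.5, 0)))
  expect_true(is.na(pi_ratio_log2(NA, 1)))
  expect_false(is.infinite(pi_ratio_log2(0.5, 0)))   # never +-Inf
  expect_error(pi_ratio_log2(1:3, 1:2), "different window universes")
})

test_that("Z-transform standardises with the population sd", {
  z <- z_transform(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  x <- rnorm(50)
  z2 <- z_transform(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z2 - mean(z2))^2)), 1, tolerance = 1e-12)
  # affine invariance
  expect_equal(z_transform(3 * x + 7), z2, tolerance = 1e-9)
  # missing propagates, excluded from the moments
  x[5] <- NA
  expect_true(is.na(z_transform(x)[5]))
  expect_error(z_transform(rep(1, 5)), "zero spread")
  expect_error(z_transform(c(1, NA)), "fewer than 2")
})

test_that("candidate selection is strict and skips missing windows", {
  w <- data.frame(contig = "c", start = seq(0L, 150000L, 50000L),
                  end = seq(100000L, 250000L, 50000L))
  tr <- scan_track(w, raw = c(0.69, 0.7, 0.71, NA), stat = "XPEHH",
                   z = c(-4.5, -4.0, 3.9, 4.2))
  up <- select_candidates(tr, 0.7, "greater", on = "raw")
  expect_equal(up$start, 100000L)          # 0.7 fails strict >
  dn <- select_candidates(tr, -4, "less", on = "z")
  expect_equal(dn$start, 0L)               # -4.0 fails strict <
  # NA windows are never selected even with extreme z
  tr2 <- scan_track(w, raw = rep(NA_real_, 4), stat = "Hp")
  expect_equal(nrow(select_candidates(tr2, 0, "less", on = "raw")), 0L)
})

test_that("evidence combination counts distinct supporting methods", {
  w <- function(starts, m) data.frame(contig = "c", start = starts,
                                      end = starts + 100000L,
                                      value = 0, method = m)
  out <- combine_evidence(list(w(c(0L, 50000L), "Hp"),
                               w(c(50000L, 100000L), "Fst")),
                          min_methods = 2)
  expect_equal(out$start, 50000L)
  expect_equal(out$n_methods, 2L)

  four <- lapply(c("Hp", "Fst", "XPEHH", "pi_ratio"),
                 function(m) w(0L, m))
  all4 <- combine_evidence(four, min_methods = 2)
  expect_equal(all4$n_methods, 4L)
  expect_equal(all4$methods, "Fst,Hp,XPEHH,pi_ratio")

  uni <- combine_evidence(list(w(0L, "a"), w(50000L, "b")),
                          min_methods = 1)
  expect_equal(sort(uni$start), c(0L, 50000L))
  expect_error(combine_evidence(list(w(0L, "a")), min_methods = 0),
               "min_methods")
  # duplicate rows from the same method count once
  dup <- combine_evidence(list(w(c(0L, 0L), "a"), w(50000L, "b")),
                          min_methods = 2)
  expect_equal(nrow(dup), 0L)
})
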