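test_that("allele-sharing distances hit their boundary cases", {
  g <- matrix(c(0L, 0L, 2L, 1L,
                0L, 0L, 2L, 1L), 2, 4, byrow = FALSE)
  # s1 and s2 identical; s3 opposite homozygote; s4 one het at both sites
  vm <- variant_matrix("c", c(1L, 2L),
                       cbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(1L, 0L)),
                       paste0("s", 1:4))
  d <- pairwise_distance(vm)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 1)
  # dosage pair (0,1) at one of two sites: per-site d = 0.5 and 0
  expect_equal(d["s1", "s4"], 0.25)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("single-site (0,1) distance is 0.5 per the allele-sharing rule", {
  vm <- variant_matrix("c", 1L, matrix(c(0L, 1L), 1, 2), c("a", "b"))
  expect_equal(pairwise_distance(vm)["a", "b"], 0.5)
})

test_that("a pair with no shared non-missing sites is an error", {
  g <- matrix(c(0L, NA, NA, 2L), 2, 2)
  vm <- variant_matrix("c", c(1L, 2L), g, c("a", "b"))
  expect_error(pairwise_distance(vm), "share no non-missing")
})

test_that("neighbour joining recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  path <- cophenetic(tr)[rownames(d), colnames(d)]
  expect_equal(path, d, tolerance = 1e-9)
  # topology: AB vs CD split
  expect_equal(as.numeric(ape::dist.topo(
    tr, ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")))),
    0)
})

test_that("three taxa solve the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")], d,
               tolerance = 1e-9)
  # closed form: la = (dab + dac - dbc)/2 = 1
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(la, 1)
})

test_that("star-like equidistant matrices still reproduce distances", {
  d <- matrix(2, 5, 5); diag(d) <- 0
  dimnames(d) <- list(paste0("t", 1:5), paste0("t", 1:5))
  tr <- neighbor_joining(d)
  expect_equal(unname(cophenetic(tr)[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-9)
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighbor_joining(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(d3), "symmetric")
  d4 <- matrix(0, 3, 3); d4[1, 2] <- d4[2, 1] <- -1
  expect_error(neighbor_joining(d4), "negative")
})

test_that("NJ agrees with the ape reference implementation", {
  for (seed in 1:10) {
    rt <- random_additive_tree(seed, sample(5:9, 1))
    ours <- neighbor_joining(rt$d)
    apes <- ape::nj(rt$d)
    expect_equal(as.numeric(ape::dist.topo(ours, apes)), 0)
    expect_equal(as.numeric(ape::dist.topo(ours, rt$tree)), 0)
  }
})

test_that("Patterson PCA separates structure and matches the svd oracle", {
  # duplicated samples get identical coordinates
  vm <- random_vm(5, n_snp = 100, n_sample = 6)
  g <- vm$genotypes; g[, 6] <- g[, 5]
  vm2 <- variant_matrix("c", vm$positions, g, vm$sample_ids)
  p <- pca_patterson(vm2)
  lead <- which(p$eigenvalues > 1e-8 * p$eigenvalues[1])
  expect_equal(p$scores[5, lead], p$scores[6, lead], tolerance = 1e-8)

  # two internally identical groups: PC1 separates, later eigenvalues ~ 0
  g3 <- cbind(matrix(0L, 40, 4), matrix(2L, 40, 4))
  g3[1:20, 1:4] <- 2L; g3[1:20, 5:8] <- 0L
  vm3 <- variant_matrix("c", seq_len(40), g3, paste0("s", 1:8))
  p3 <- pca_patterson(vm3)
  expect_true(all(p3$scores[1:4, 1] * p3$scores[5:8, 1] < 0))
  expect_true(sign(p3$scores[1, 1]) != sign(p3$scores[5, 1]))
  expect_lt(p3$eigenvalues[2] / p3$eigenvalues[1], 1e-10)

  # dense-eigendecomposition oracle on a random 20 x 200 fixture
  vm4 <- random_vm(8, n_snp = 200, n_sample = 20)
  p4 <- pca_patterson(vm4)
  gg <- vm4$genotypes
  pf <- rowMeans(gg) / 2
  keep <- pf > 0 & pf < 1
  m <- (gg[keep, ] - 2 * pf[keep]) / sqrt(pf[keep] * (1 - pf[keep]))
  sv <- svd(t(m) / sqrt(nrow(m)))
  expect_equal(p4$eigenvalues[1], sv$d[1]^2, tolerance = 1e-8)
  expect_equal(abs(sum(p4$vectors[, 1] * sv$u[, 1])), 1, tolerance = 1e-8)
  # orthogonality of coordinates
  gram <- crossprod(p4$vectors[, 1:5])
  expect_equal(unname(gram), diag(5), tolerance = 1e-8)
})

test_that("LD r2 matches haplotype-count expectations", {
  mk <- function(h) {
    # h: 2-row haplotype matrix (sites x haplotypes)
    n <- ncol(h) / 2
    geno <- h[, seq(1, ncol(h), 2)] + h[, seq(2, ncol(h), 2)]
    variant_matrix("c", c(100L, 200L), geno, paste0("s", seq_len(n)),
                   haplotypes = h)
  }
  # AB,AB,ab,ab -> r2 = 1
  h1 <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
  r <- ld_r2(mk(h1), maf_min = 0, bin_bp = 1000)
  expect_equal(r$mean_r2, 1)
  # AB,Ab,aB,ab -> D = 0 (max_het lifted: a 2-sample all-het site is
  # legitimate in this contrived fixture)
  h2 <- rbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_equal(ld_r2(mk(h2), maf_min = 0, max_het = 1)$mean_r2, 0)
  # AB,AB,AB,ab: counting oracle
  h3 <- rbind(c(1L, 1L, 1L, 0L), c(1L, 1L, 1L, 0L))
  expect_equal(ld_r2(mk(h3), maf_min = 0)$mean_r2,
               r2_count_oracle(h3[1, ], h3[2, ]))
  expect_equal(ld_r2(mk(h3), maf_min = 0)$mean_r2, 1)
})

test_that("dosage-based r2 equals haplotype r2 for homozygous data", {
  set.seed(3)
  n <- 12
  a <- rbinom(n, 1, 0.5)
  b <- ifelse(runif(n) < 0.7, a, rbinom(n, 1, 0.5))
  haps <- rbind(rep(a, each = 2), rep(b, each = 2))
  geno <- 2L * rbind(a, b)
  vm <- variant_matrix("c", c(10L, 500L), geno, paste0("s", 1:n),
                       haplotypes = haps)
  hap_r2 <- ld_r2(vm, maf_min = 0, use_haplotypes = TRUE)$mean_r2
  dos_r2 <- ld_r2(vm, maf_min = 0, use_haplotypes = FALSE)$mean_r2
  expect_equal(hap_r2, dos_r2, tolerance = 1e-12)
})

test_that("LD filters respect MAF, heterozygosity and missingness", {
  set.seed(4)
  vm <- random_vm(4, n_snp = 40, n_sample = 10, L = 50000)
  # strict MAF: a site at exactly the threshold is excluded
  af <- rowMeans(vm$genotypes) / 2
  maf <- pmin(af, 1 - af)
  curve <- ld_r2(vm, maf_min = max(maf))
  expect_equal(nrow(curve), 0L)
  # pair counting is complete over the SNPs passing the site filters
  curve0 <- ld_r2(vm, maf_min = 0, max_dist = 1e6, bin_bp = 1e6)
  het <- rowMeans(vm$genotypes == 1L)
  n_keep <- sum(maf > 0 & het <= 0.9)
  expect_equal(sum(curve0$n_pairs), choose(n_keep, 2))
})

test_that("PHYLIP distance files round-trip through the written format", {
  vm <- random_vm(6, n_snp = 30, n_sample = 5)
  d <- pairwise_distance(vm)
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(d, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 5L)
  expect_length(lines, 6L)
})
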