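test_that("VCF genotypes are read as alternate-allele dosage", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(f, chrom = rep("chr1", 3), pos = c(100, 200, 300),
                 ref = rep("A", 3), alt = rep("T", 3), qual = rep(50, 3),
                 gt = matrix(c("0/0", "0/1", "1/1",
                               "0/1", "0/0", "1/1"), 3, 2))
  vms <- read_vcf(f)
  expect_length(vms, 1)
  vm <- vms[["chr1"]]
  expect_equal(vm$positions, c(100L, 200L, 300L))
  expect_equal(unname(vm$genotypes[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(vm$genotypes[, 2]), c(1L, 0L, 2L))
  expect_null(vm$haplotypes)   # unphased input
})

test_that("phased VCF yields haplotypes whose column pairs sum to dosage", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(f, chrom = rep("chr1", 3), pos = c(100, 200, 300),
                 ref = rep("A", 3), alt = rep("T", 3), qual = rep(50, 3),
                 gt = matrix(c("0|1", "1|0", "1|1",
                               "0|0", "0|1", "1|0"), 3, 2))
  vm <- read_vcf(f)[[1]]
  expect_false(is.null(vm$haplotypes))
  dos <- vm$haplotypes[, c(1, 3)] + vm$haplotypes[, c(2, 4)]
  expect_equal(unname(dos), unname(vm$genotypes))
  expect_equal(vm$haplotypes[1, ], c(0L, 1L, 0L, 0L))
})

test_that("multi-allelic records are carried but dropped by the filter", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(f, chrom = rep("chr1", 3), pos = c(100, 200, 300),
                 ref = rep("A", 3), alt = c("T", "T,G", "C"),
                 qual = rep(50, 3),
                 gt = matrix(c("0/0", "0/2", "1/1",
                               "0/1", "1/2", "0/0"), 3, 2))
  vm <- read_vcf(f)[[1]]
  expect_equal(n_variants(vm), 3L)
  expect_equal(vm$biallelic, c(TRUE, FALSE, TRUE))
  out <- filter_variants(vm, filter_spec(min_call_rate = 0,
                                         min_quality = 0,
                                         adjacency_bp = 0))
  expect_equal(out$positions, c(100L, 300L))
})

test_that("unknown samples and malformed genotypes are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(f, chrom = "chr1", pos = 100, ref = "A", alt = "T",
                 qual = 50, gt = matrix(c("0/0", "0/1"), 1, 2))
  expect_error(read_vcf(f, samples = c("s1", "nope")), "nope")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_text(f2, chrom = "chr1", pos = 100, ref = "A", alt = "T",
                 qual = 50, gt = matrix(c("0x1", "0/1"), 1, 2))
  expect_error(read_vcf(f2), "malformed GT")
})

test_that("adjacency filter removes both members of a close pair", {
  vm <- variant_matrix("chr1", c(100L, 103L, 500L),
                       matrix(c(0L, 1L, 2L, 1L, 1L, 0L), 3, 2),
                       c("a", "b"), quality = rep(60, 3))
  out <- filter_variants(vm, filter_spec(adjacency_bp = 5,
                                         min_call_rate = 0))
  expect_equal(out$positions, 500L)
  # transitive runs: 100,103,106 all removed
  vm3 <- variant_matrix("chr1", c(100L, 103L, 106L, 500L),
                        matrix(1L, 4, 2), c("a", "b"),
                        quality = rep(60, 4))
  expect_equal(filter_variants(vm3, filter_spec(adjacency_bp = 5,
                                                min_call_rate = 0))$positions,
               500L)
  # adjacency 0 disables the rule
  expect_equal(filter_variants(vm, filter_spec(adjacency_bp = 0,
                                               min_call_rate = 0))$positions,
               vm$positions)
  # "first" mode keeps the first member of each run
  expect_equal(filter_variants(vm3, filter_spec(adjacency_bp = 5,
                                                min_call_rate = 0,
                                                adjacency_mode = "first"))$positions,
               c(100L, 106L, 500L))
})

test_that("call-rate and quality thresholds are strict", {
  g <- matrix(0L, 2, 10)
  g[1, 1] <- NA   # call rate exactly 0.9 at site 1
  vm <- variant_matrix("chr1", c(100L, 200L), g, paste0("s", 1:10),
                       quality = c(60, 30))  # site 2 QUAL exactly 30
  out <- filter_variants(vm, filter_spec(min_call_rate = 0.9,
                                         min_quality = 30,
                                         adjacency_bp = 0))
  expect_equal(n_variants(out), 0L)   # 0.9 is not > 0.9; 30 is not > 30
})

test_that("filtering is idempotent and yields a position subsequence", {
  for (seed in 1:5) {
    vm <- random_vm(seed, n_snp = 60, n_sample = 8)
    set.seed(seed)
    vm$quality <- sample(c(10, 60), 60, replace = TRUE)
    spec <- filter_spec(adjacency_bp = 500, min_call_rate = 0.5)
    once <- filter_variants(vm, spec)
    twice <- filter_variants(once, spec)
    expect_identical(once$positions, twice$positions)
    expect_identical(once$genotypes, twice$genotypes)
    expect_true(all(once$positions %in% vm$positions))
    expect_false(is.unsorted(once$positions, strictly = TRUE))
  }
})

test_that("VCF round-trip preserves positions, dosages and phase", {
  vm <- random_vm(11, n_snp = 30, n_sample = 6)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vm, f, contig_length = 100000)
  back <- read_vcf(f)[[1]]
  expect_identical(back$positions, vm$positions)
  expect_identical(unname(back$genotypes), unname(vm$genotypes))
  expect_identical(unname(back$haplotypes), unname(vm$haplotypes))
})

test_that("population maps resolve lookups and reject conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tMEAT", "s2\tMEAT", "s3\tWOOL"), f)
  pm <- read_population_map(f)
  expect_equal(attr(pm, "populations"), c("MEAT", "WOOL"))
  expect_equal(pop_samples(pm, "MEAT"), c("s1", "s2"))
  expect_equal(pop_samples(pm, "WOOL"), "s3")
  expect_error(pop_samples(pm, "OTHER"), "not present")
  expect_error(population_map(c(s1 = "MEAT", s1 = "WOOL")),
               "more than one population")
})

test_that("GFF3 genes convert to 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "src", "gene", "1001", "2000", ".", "+", ".",
                     "ID=gene1", sep = "\t"),
               paste("chr1", "src", "mRNA", "1001", "1500", ".", "+", ".",
                     "ID=tx1;Parent=gene1", sep = "\t")), f)
  gs <- read_genes(f)
  expect_equal(nrow(gs), 1L)    # mRNA feature ignored
  expect_equal(gs$start, 1000)
  expect_equal(gs$end, 2000)
  expect_equal(gs$gene_id, "gene1")
})

test_that("BED round-trip of windows preserves intervals", {
  w <- data.frame(contig = "chr1", start = c(0L, 50000L, 100000L, 150000L),
                  end = c(100000L, 150000L, 200000L, 250000L))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(w, f, score = 1:4)
  back <- read_bed(f)
  expect_equal(back$start, w$start)
  expect_equal(back$end, w$end)
  expect_equal(back$score, 1:4)
  gs <- read_genes(f)
  expect_equal(gs$start, w$start)
})
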