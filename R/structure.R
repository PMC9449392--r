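#' Pairwise allele-sharing genetic distances
#'
#' `d(i, j) = 1 - IBS(i, j)`, where IBS is the mean, over sites non-missing
#' in both samples, of the shared allele fraction `(2 - |g_i - g_j|) / 2`
#' given dosages. Identical samples have distance 0; opposite homozygotes
#' at every site have distance 1.
#'
#' @param vm A [variant_matrix()] (or list of them, concatenated).
#' @return A symmetric `dist`-convertible matrix with sample ids as
#'   dimnames.
#' @export
pairwise_distance <- function(vm) {
  vms <- if (inherits(vm, "variant_matrix")) list(vm) else vm
  g <- do.call(rbind, lapply(vms, `[[`, "genotypes"))
  ids <- vms[[1]]$sample_ids
  n <- length(ids)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    gi <- g[, i]
    for (j in seq.int(i + 1L, n)) {
      diffs <- abs(gi - g[, j])
      ok <- !is.na(diffs)
      if (!any(ok)) {
        stop("samples ", ids[i], " and ", ids[j],
             " share no non-missing sites", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(diffs[ok]) / 2
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining with the standard Q-criterion. Ties in the
#' Q matrix are broken by the lowest index pair; a negative branch length
#' is clamped to zero with the deficit moved to its sister branch so the
#' pair's path length is preserved. On an additive distance matrix the
#' tree's path-length distances reproduce the input exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and non-negative
#'   entries; dimnames supply taxon labels.
#' @return An unrooted `phylo` tree (\pkg{ape}).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(d < 0)) stop("distance matrix has negative entries",
                       call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node carries its Newick subtree string
  newick <- labels
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  while (length(newick) > 3L) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    # lowest-index tie break: column-major which.min scans i fastest, so
    # pick the minimum explicitly over the upper triangle in (i, j) order
    min_q <- min(q)
    hit <- which(q - min_q <= 0, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(li),
                      newick[j], fmt(lj))
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    newick <- c(newick[keep], merged)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(lens[1]),
                 newick[2], fmt(lens[2]), newick[3], fmt(lens[3]))
  ape::read.tree(text = txt)
}

#' Write a distance matrix in PHYLIP format
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(formatC(rownames(d)[i], width = -10),
                     paste(formatC(d[i, ], digits = 6, format = "f"),
                           collapse = " ")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Patterson-normalised principal component analysis
#'
#' The dosage matrix is column-centred by `2 * p_hat` and scaled by
#' `sqrt(p_hat * (1 - p_hat))` with `p_hat` the sample allele frequency,
#' the normalisation of EIGENSOFT/smartpca. Missing dosages are
#' mean-imputed per SNP before normalisation; monomorphic SNPs are
#' dropped. Eigenvalues are those of the sample-by-sample covariance
#' `M M' / n_snps`; sample coordinates (`scores`) are the eigenvectors
#' scaled by the square root of their eigenvalue, so Euclidean distances
#' between samples approximate Mahalanobis distances in SNP space.
#'
#' @param vm A [variant_matrix()] (or list of them).
#' @param n_pc Number of components to return (default all).
#' @return An object of class `patterson_pca`: list with `eigenvalues`
#'   (non-increasing), `scores` (samples x PCs), `vectors` (unit
#'   eigenvectors) and `n_snps_used`.
#' @export
pca_patterson <- function(vm, n_pc = NULL) {
  vms <- if (inherits(vm, "variant_matrix")) list(vm) else vm
  g <- do.call(rbind, lapply(vms, `[[`, "genotypes"))
  ids <- vms[[1]]$sample_ids
  if (length(ids) < 2L) stop("need at least 2 samples", call. = FALSE)
  all_missing <- rowSums(!is.na(g)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) with all genotypes missing dropped")
    g <- g[!all_missing, , drop = FALSE]
  }
  p <- rowMeans(g, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  g <- g[keep, , drop = FALSE]
  p <- p[keep]
  if (!nrow(g)) stop("no polymorphic SNPs for PCA", call. = FALSE)
  m <- g
  for (k in which(rowSums(is.na(m)) > 0L)) {
    m[k, is.na(m[k, ])] <- 2 * p[k]
  }
  m <- (m - 2 * p) / sqrt(p * (1 - p))
  cov <- crossprod(m) / nrow(m)           # samples x samples
  eig <- eigen(cov, symmetric = TRUE)
  if (is.null(n_pc)) n_pc <- length(ids)
  n_pc <- min(n_pc, length(ids))
  lam <- pmax(eig$values[seq_len(n_pc)], 0)
  vec <- eig$vectors[, seq_len(n_pc), drop = FALSE]
  rownames(vec) <- ids
  colnames(vec) <- paste0("PC", seq_len(n_pc))
  scores <- sweep(vec, 2L, sqrt(lam), `*`)
  structure(list(eigenvalues = lam, scores = scores, vectors = vec,
                 n_snps_used = nrow(m)),
            class = "patterson_pca")
}

#' @export
print.patterson_pca <- function(x, ...) {
  cat(sprintf("patterson_pca: %d samples, %d SNPs used\n",
              nrow(x$scores), x$n_snps_used))
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  k <- min(5L, length(pct))
  cat("  top eigenvalues (% variance):",
      paste(sprintf("%.1f", pct[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Linkage-disequilibrium decay curve
#'
#' For every SNP pair within `max_dist` bp (after per-SNP filters: minor
#' allele frequency strictly above `maf_min`, heterozygote fraction at
#' most `max_het`, missing fraction at most `max_miss`), `r^2` is computed
#' from haplotype frequencies when the matrix is phased
#' (`r^2 = D^2 / (pA qA pB qB)`), otherwise as the squared Pearson
#' correlation of dosages. Pairs are averaged in distance bins.
#'
#' @param vm A phased or unphased [variant_matrix()].
#' @param samples Optional sample subset (e.g. one population).
#' @param maf_min Minimum minor allele frequency, strict (default 0.05).
#' @param max_dist Maximum pair distance in bp (default 1e6).
#' @param max_het Maximum per-SNP heterozygote fraction (default 0.9).
#' @param max_miss Maximum per-SNP missing fraction (default 0.1).
#' @param bin_bp Distance bin width in bp (default 1000).
#' @param use_haplotypes Force haplotype- (`TRUE`) or dosage-based
#'   (`FALSE`) r2; default uses haplotypes when available.
#' @return An `ld_decay` data frame: `bin_start`, `bin_end`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_r2 <- function(vm, samples = NULL, maf_min = 0.05, max_dist = 1e6,
                  max_het = 0.9, max_miss = 0.1, bin_bp = 1000,
                  use_haplotypes = NULL) {
  if (is.null(samples)) samples <- vm$sample_ids
  g <- genotypes_of(vm, samples)
  if (is.null(use_haplotypes)) use_haplotypes <- !is.null(vm$haplotypes)
  h <- if (use_haplotypes) haplotypes_of(vm, samples) else NULL
  n <- ncol(g)
  af <- rowMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  het <- rowMeans(g == 1L, na.rm = TRUE)
  miss <- rowMeans(is.na(g))
  keep <- which(maf > maf_min & het <= max_het & miss <= max_miss &
                  !is.na(af))
  pos <- vm$positions
  nbin <- ceiling(max_dist / bin_bp)
  sum_r2 <- numeric(nbin)
  n_pair <- integer(nbin)
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    js <- keep[-seq_len(ii)]
    js <- js[pos[js] - pos[i] <= max_dist & pos[js] > pos[i]]
    if (!length(js)) next
    if (use_haplotypes) {
      hi <- h[i, ]
      pA <- mean(hi)
      hj <- h[js, , drop = FALSE]
      pB <- rowMeans(hj)
      pAB <- as.vector(hj %*% hi) / length(hi)
      D <- pAB - pA * pB
      r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    } else {
      gi <- g[i, ]
      r2 <- apply(g[js, , drop = FALSE], 1L, function(gj)
        suppressWarnings(stats::cor(gi, gj,
                                    use = "pairwise.complete.obs")))^2
    }
    bins <- pmin(pmax(ceiling((pos[js] - pos[i]) / bin_bp), 1L), nbin)
    ok <- !is.na(r2)
    for (b in unique(bins[ok])) {
      sel <- ok & bins == b
      sum_r2[b] <- sum_r2[b] + sum(r2[sel])
      n_pair[b] <- n_pair[b] + sum(sel)
    }
  }
  out <- data.frame(bin_start = (seq_len(nbin) - 1L) * bin_bp,
                    bin_end = seq_len(nbin) * bin_bp,
                    mean_r2 = ifelse(n_pair > 0, sum_r2 / n_pair, NA_real_),
                    n_pairs = n_pair)
  out <- out[out$n_pairs > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ld_decay", "data.frame")
  out
}
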