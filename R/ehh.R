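#' Extended haplotype homozygosity from a core SNP
#'
#' `EHH(x) = sum_h C(c_h, 2) / C(n, 2)`: the probability that two randomly
#' drawn haplotypes are identical over the interval from the core SNP out
#' to distance `x`. By default the curve is computed over all `n`
#' haplotypes, so its value at distance 0 is the homozygosity of the core
#' site itself; restricted to the carriers of one core allele
#' (`core_allele`), it starts at 1. The curve is evaluated at every SNP
#' moving away from the core and stops when it drops below `cutoff` or a
#' gap larger than `max_gap` bp separates consecutive SNPs.
#'
#' @param haps Binary haplotype matrix, variants x haplotypes (phased).
#' @param positions 1-based positions matching the rows of `haps`.
#' @param core Row index of the core SNP.
#' @param side `"downstream"` extends towards larger positions,
#'   `"upstream"` towards smaller.
#' @param cutoff Truncation threshold on EHH (default 0.05).
#' @param max_gap Maximum tolerated gap between consecutive SNPs in bp
#'   (default 200000).
#' @param core_allele Optional 0/1; restricts the computation to carriers
#'   of that core allele.
#' @return An `ehh_curve`: list with `distance` (bp from core, starting at
#'   0) and `ehh` (values in \[0, 1\], non-increasing).
#' @export
ehh <- function(haps, positions, core,
                side = c("downstream", "upstream"),
                cutoff = 0.05, max_gap = 200000, core_allele = NULL) {
  side <- match.arg(side)
  if (is.null(haps)) stop("phased haplotypes required for EHH",
                          call. = FALSE)
  if (anyNA(haps)) stop("haplotype matrix must not contain missing calls",
                        call. = FALSE)
  if (core < 1L || core > nrow(haps)) stop("core SNP index out of range",
                                           call. = FALSE)
  if (!is.null(core_allele)) {
    haps <- haps[, haps[core, ] == core_allele, drop = FALSE]
  }
  ht <- t(haps)   # haplotypes in rows: contiguous column access per SNP
  cv <- ehh_engine(ht, positions, core,
                   step_dir = if (side == "downstream") 1L else -1L,
                   cutoff = cutoff, max_gap = max_gap,
                   core_allele = core_allele)
  structure(c(cv, list(core = core, side = side)), class = "ehh_curve")
}

# ht: haplotypes x sites; thin wrapper over the compiled incremental
# prefix-grouping engine.
ehh_engine <- function(ht, positions, core, step_dir, cutoff, max_gap,
                       core_allele = NULL) {
  if (nrow(ht) < 2L) stop("EHH needs at least 2 haplotypes", call. = FALSE)
  storage.mode(ht) <- "integer"
  .ehh_curve_cpp(ht, as.integer(positions), as.integer(core),
                 as.integer(step_dir), cutoff, max_gap,
                 per_allele = !is.null(core_allele))
}

#' Integrated haplotype homozygosity (iHH)
#'
#' Trapezoidal integral of the EHH curve against physical distance, summed
#' over the upstream and downstream sides. A side whose curve has a single
#' point (core at the contig edge, or immediate truncation) contributes 0.
#'
#' @param curve_down,curve_up `ehh_curve`s for the two sides (either may be
#'   `NULL`).
#' @return iHH in bp x EHH units (non-negative scalar).
#' @export
ihh_from_curves <- function(curve_down, curve_up = NULL) {
  area <- function(cv) {
    if (is.null(cv) || length(cv$distance) < 2L) return(0)
    d <- cv$distance
    e <- cv$ehh
    sum(diff(d) * (e[-length(e)] + e[-1]) / 2)
  }
  area(curve_down) + area(curve_up)
}

#' iHH at a core SNP (both directions)
#'
#' @inheritParams ehh
#' @return iHH scalar; see [ihh_from_curves()].
#' @export
ihh <- function(haps, positions, core, cutoff = 0.05, max_gap = 200000,
                core_allele = NULL) {
  ihh_from_curves(
    ehh(haps, positions, core, "downstream", cutoff, max_gap, core_allele),
    ehh(haps, positions, core, "upstream", cutoff, max_gap, core_allele))
}

#' Cross-population EHH statistic at one core SNP
#'
#' `XP-EHH = ln(iHH_A / iHH_B)` over the identical SNP set in the two
#' populations. Positive values indicate longer shared haplotypes (slower
#' EHH decay) in population A, the signature of a recent sweep there.
#' Swapping the populations negates the value exactly.
#'
#' @param haps_a,haps_b Binary haplotype matrices of populations A and B
#'   over the same SNPs.
#' @param positions Shared 1-based SNP positions.
#' @param core Core SNP index.
#' @inheritParams ehh
#' @return `ln(iHH_A / iHH_B)`, or `NA` when either iHH is 0.
#' @export
xpehh <- function(haps_a, haps_b, positions, core, cutoff = 0.05,
                  max_gap = 200000) {
  ia <- ihh(haps_a, positions, core, cutoff, max_gap)
  ib <- ihh(haps_b, positions, core, cutoff, max_gap)
  if (ia == 0 || ib == 0) return(NA_real_)
  log(ia / ib)
}

#' Per-SNP XP-EHH over all cores of a variant matrix
#'
#' @param vm A phased [variant_matrix()].
#' @param samples_a,samples_b Sample ids of populations A and B.
#' @param cores Integer indices of core SNPs (default: every SNP).
#' @inheritParams ehh
#' @return Numeric vector of XP-EHH values aligned with `cores`.
#' @export
xpehh_scan <- function(vm, samples_a, samples_b, cores = NULL,
                       cutoff = 0.05, max_gap = 200000) {
  ha_t <- t(haplotypes_of(vm, samples_a))
  hb_t <- t(haplotypes_of(vm, samples_b))
  storage.mode(ha_t) <- "integer"
  storage.mode(hb_t) <- "integer"
  pos <- as.integer(vm$positions)
  ia <- .ihh_all_cpp(ha_t, pos, cutoff, max_gap)
  ib <- .ihh_all_cpp(hb_t, pos, cutoff, max_gap)
  out <- ifelse(ia == 0 | ib == 0, NA_real_, log(ia / ib))
  if (is.null(cores)) out else out[cores]
}

#' Window-averaged XP-EHH track
#'
#' Arithmetic mean of the defined per-core-SNP XP-EHH values in each
#' window; windows with fewer than `min_snps` defined values are missing.
#'
#' @param xpehh_values Per-SNP XP-EHH values aligned with the variant
#'   matrix used to build `windows`.
#' @param windows Windows with `snp_idx` from [assign_snps()].
#' @param min_snps Minimum defined values per window (default 10).
#' @param comparison Track metadata label.
#' @return A [scan_track()] named `"XPEHH"`.
#' @export
xpehh_track <- function(xpehh_values, windows, min_snps = 10,
                        comparison = "A vs B") {
  raw <- vapply(windows$snp_idx, function(idx) {
    v <- xpehh_values[idx]
    v <- v[!is.na(v)]
    if (length(v) < min_snps) return(NA_real_)
    mean(v)
  }, numeric(1))
  scan_track(windows, raw, "XPEHH", comparison)
}
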