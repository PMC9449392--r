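#' Variant filter specification
#'
#' Bundles the site-level filters applied before any scan statistic:
#' biallelic SNPs only, per-site call rate strictly above `min_call_rate`,
#' QUAL strictly above `min_quality`, and removal of adjacent SNPs closer
#' than `adjacency_bp` (a guard against clusters of calling errors around
#' misalignments and indels).
#'
#' @param min_call_rate Fraction in \[0, 1\]; a site is kept when its
#'   non-missing fraction is strictly greater. Default 0.9.
#' @param min_quality Sites are kept when QUAL is strictly greater.
#'   Default 30. Sites with missing QUAL are kept.
#' @param adjacency_bp Minimum spacing in bp; consecutive SNPs separated by
#'   less than this are removed. Default 5. `0` disables the rule.
#' @param biallelic_only Drop records not flagged as biallelic SNPs.
#' @param adjacency_mode `"both"` removes every member of a run of
#'   too-close SNPs (applied transitively); `"first"` keeps the first SNP of
#'   each run and drops the rest.
#'
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_call_rate = 0.9, min_quality = 30,
                        adjacency_bp = 5, biallelic_only = TRUE,
                        adjacency_mode = c("both", "first")) {
  adjacency_mode <- match.arg(adjacency_mode)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, adjacency_bp >= 0)
  structure(list(min_call_rate = min_call_rate, min_quality = min_quality,
                 adjacency_bp = adjacency_bp, biallelic_only = biallelic_only,
                 adjacency_mode = adjacency_mode),
            class = "filter_spec")
}

#' Apply site filters to a variant matrix
#'
#' Filters run in two stages: first the per-site filters (biallelic SNP,
#' call rate, quality), then the adjacency rule on the surviving positions.
#' With `adjacency_mode = "both"` (the default) every SNP belonging to a
#' run of consecutive SNPs spaced `< adjacency_bp` apart is removed, so a
#' pair 3 bp apart loses both members.
#'
#' @param vm A [variant_matrix()].
#' @param spec A [filter_spec()].
#' @return A filtered `variant_matrix`; possibly with zero variants.
#' @export
filter_variants <- function(vm, spec = filter_spec()) {
  stopifnot(inherits(vm, "variant_matrix"), inherits(spec, "filter_spec"))
  keep <- rep(TRUE, n_variants(vm))
  if (spec$biallelic_only) keep <- keep & vm$biallelic
  if (spec$min_call_rate > 0) {
    call_rate <- rowMeans(!is.na(vm$genotypes))
    keep <- keep & call_rate > spec$min_call_rate
  }
  keep <- keep & (is.na(vm$quality) | vm$quality > spec$min_quality)
  pos <- vm$positions[keep]
  if (spec$adjacency_bp > 0 && length(pos) > 1L) {
    d <- diff(pos)
    close_pair <- d < spec$adjacency_bp
    if (spec$adjacency_mode == "both") {
      drop <- c(close_pair, FALSE) | c(FALSE, close_pair)
    } else {
      # keep the first SNP of each run: drop a SNP when it is too close to
      # the previous *kept* SNP
      drop <- logical(length(pos))
      last_kept <- pos[1]
      for (i in seq_along(pos)[-1]) {
        if (pos[i] - last_kept < spec$adjacency_bp) drop[i] <- TRUE
        else last_kept <- pos[i]
      }
    }
    pos <- pos[!drop]
  }
  subset_variants(vm, which(keep)[match(pos, vm$positions[keep])])
}
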