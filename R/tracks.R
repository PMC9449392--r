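#' Construct a scan track
#'
#' A `scan_track` attaches one statistic to the window universe: the raw
#' per-window value, its genome-wide Z-transform (when at least two windows
#' are defined and the spread is non-zero), and metadata naming the
#' statistic and the populations compared.
#'
#' @param windows A `scan_windows` data frame (with `n_snps` if available).
#' @param raw Numeric per-window values (`NA` = undefined window).
#' @param stat Statistic name (e.g. `"Hp"`, `"Fst"`).
#' @param comparison Label of the populations involved, e.g. `"HYB"` or
#'   `"HYB vs P1"`.
#' @param z Optional precomputed Z values; computed with [z_transform()]
#'   when `NULL` and possible.
#' @return A `scan_track` data frame with columns `contig`, `start`, `end`,
#'   `n_snps`, `raw`, `z`.
#' @export
scan_track <- function(windows, raw, stat, comparison = "", z = NULL) {
  stopifnot(length(raw) == nrow(windows))
  if (is.null(z)) {
    z <- tryCatch(z_transform(raw, track = stat),
                  error = function(e) rep(NA_real_, length(raw)))
  }
  out <- data.frame(contig = windows$contig, start = windows$start,
                    end = windows$end,
                    n_snps = if (!is.null(windows$n_snps)) windows$n_snps
                    else NA_integer_,
                    raw = raw, z = z, stringsAsFactors = FALSE)
  attr(out, "stat") <- stat
  attr(out, "comparison") <- comparison
  class(out) <- c("scan_track", "data.frame")
  out
}

#' Pooled-heterozygosity track over windows
#'
#' @param vm A [variant_matrix()] (filtered, biallelic SNPs).
#' @param windows Windows with `snp_idx` from [assign_snps()].
#' @param samples Sample ids of the focal population.
#' @param min_snps Windows with fewer SNPs are set missing (default 10).
#' @param population Label used in the track metadata.
#' @return A [scan_track()] named `"Hp"`.
#' @export
hp_track <- function(vm, windows, samples, min_snps = 10,
                     population = "pop") {
  ac <- allele_counts(vm, samples)
  raw <- vapply(windows$snp_idx, function(idx) {
    idx <- idx[ac$n_major[idx] + ac$n_minor[idx] > 0]
    if (length(idx) < min_snps) return(NA_real_)
    pooled_heterozygosity(ac$n_major[idx], ac$n_minor[idx])
  }, numeric(1))
  scan_track(windows, raw, "Hp", population)
}

#' Window-averaged FST track
#'
#' @inheritParams hp_track
#' @param samples_a,samples_b Sample ids of the two populations.
#' @param estimator Passed to [snp_fst()].
#' @param method `"mean"` averages per-SNP estimates (default);
#'   `"ratio_of_sums"` sums the Weir-Cockerham `a` components over the
#'   window and divides by the summed `a + b + c`.
#' @param comparison Label for the track metadata.
#' @return A [scan_track()] named `"Fst"`.
#' @export
fst_track <- function(vm, windows, samples_a, samples_b, min_snps = 10,
                      estimator = "wc", method = c("mean", "ratio_of_sums"),
                      comparison = "A vs B") {
  method <- match.arg(method)
  if (method == "mean") {
    per_snp <- snp_fst(vm, samples_a, samples_b, estimator = estimator)
    raw <- vapply(windows$snp_idx, function(idx)
      window_fst(per_snp, idx, min_snps = min_snps), numeric(1))
  } else {
    ga <- genotypes_of(vm, samples_a)
    gb <- genotypes_of(vm, samples_b)
    na_ <- rowSums(!is.na(ga)); nb_ <- rowSums(!is.na(gb))
    pa <- rowSums(ga, na.rm = TRUE) / (2 * na_)
    pb <- rowSums(gb, na.rm = TRUE) / (2 * nb_)
    comp <- wc_components(na_, nb_, pa, pb,
                          rowMeans(ga == 1L, na.rm = TRUE),
                          rowMeans(gb == 1L, na.rm = TRUE))
    ok <- !(na_ < 1 | nb_ < 1 | (pa == pb & pa %in% c(0, 1)))
    raw <- vapply(windows$snp_idx, function(idx) {
      idx <- idx[ok[idx]]
      if (length(idx) < min_snps) return(NA_real_)
      sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$c[idx])
    }, numeric(1))
  }
  scan_track(windows, raw, "Fst", comparison)
}

#' Nucleotide-diversity track
#'
#' @inheritParams hp_track
#' @return A [scan_track()] named `"pi"` with per-bp theta-pi values.
#' @export
pi_track <- function(vm, windows, samples, min_snps = 10,
                     population = "pop") {
  sp <- pi_site(vm, samples)
  raw <- vapply(seq_len(nrow(windows)), function(i)
    window_pi(sp, windows$snp_idx[[i]],
              windows$end[i] - windows$start[i], min_snps = min_snps),
    numeric(1))
  scan_track(windows, raw, "pi", population)
}

#' Log2 theta-pi-ratio track from two diversity tracks
#'
#' @param track_num,track_den [pi_track()]s for numerator and denominator
#'   populations, on the identical window universe.
#' @param pseudocount Passed to [pi_ratio_log2()].
#' @return A [scan_track()] named `"pi_ratio"`. No Z column is meaningful
#'   for thresholding; the raw log2 ratio is used.
#' @export
pi_ratio_track <- function(track_num, track_den, pseudocount = 0) {
  if (nrow(track_num) != nrow(track_den) ||
      any(track_num$start != track_den$start) ||
      any(track_num$contig != track_den$contig)) {
    stop("theta-pi tracks are on different window universes", call. = FALSE)
  }
  raw <- pi_ratio_log2(track_num$raw, track_den$raw,
                       pseudocount = pseudocount)
  scan_track(track_num[, c("contig", "start", "end", "n_snps")], raw,
             "pi_ratio",
             paste(attr(track_num, "comparison"), "/",
                   attr(track_den, "comparison")))
}

#' @export
print.scan_track <- function(x, ...) {
  cat(sprintf("scan_track %s (%s): %d windows, %d defined\n",
              attr(x, "stat"), attr(x, "comparison"), nrow(x),
              sum(!is.na(x$raw))))
  invisible(x)
}

#' Extract candidate windows beyond a threshold
#'
#' Windows are selected when the chosen column lies strictly beyond the
#' threshold in the stated direction; missing windows are never selected.
#'
#' @param track A [scan_track()].
#' @param threshold Numeric cut-off.
#' @param direction `"greater"` selects values `> threshold`, `"less"`
#'   selects values `< threshold`.
#' @param on `"z"` applies the threshold to the Z column, `"raw"` to the
#'   raw statistic.
#' @param method Method label recorded as provenance; defaults to the
#'   track's statistic name and comparison.
#' @return A `candidate_set` data frame (`contig`, `start`, `end`, `value`,
#'   `method`).
#' @export
select_candidates <- function(track, threshold,
                              direction = c("greater", "less"),
                              on = c("z", "raw"), method = NULL) {
  direction <- match.arg(direction)
  on <- match.arg(on)
  v <- track[[on]]
  hit <- !is.na(v) & if (direction == "greater") v > threshold
  else v < threshold
  if (is.null(method)) {
    method <- paste0(attr(track, "stat"),
                     if (nzchar(attr(track, "comparison")))
                       paste0("[", attr(track, "comparison"), "]"))
  }
  out <- data.frame(contig = track$contig[hit], start = track$start[hit],
                    end = track$end[hit], value = v[hit],
                    method = rep_len(method, sum(hit)),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "direction") <- direction
  attr(out, "on") <- on
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Combine candidate sets across statistics
#'
#' A window (identified by contig and start) enters the combined set when
#' at least `min_methods` distinct methods selected it; windows flagged by
#' several statistics carry the strongest evidence of selection.
#'
#' @param sets List of `candidate_set` data frames over the same window
#'   universe.
#' @param min_methods Minimum number of supporting methods (default 2).
#'   `1` yields the union, `length(sets)` the intersection.
#' @return A `candidate_set` with a `methods` column listing supporters
#'   (comma-separated) and `n_methods` counts.
#' @export
combine_evidence <- function(sets, min_methods = 2) {
  if (min_methods < 1) stop("min_methods must be >= 1", call. = FALSE)
  all_rows <- do.call(rbind, lapply(sets, function(s)
    s[, c("contig", "start", "end", "method"), drop = FALSE]))
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), methods = character(0),
                      n_methods = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("candidate_set", "data.frame")
    return(out)
  }
  key <- paste0(all_rows$contig, ":", all_rows$start)
  split_methods <- split(all_rows$method, key)
  n_methods <- vapply(split_methods, function(m) length(unique(m)),
                      integer(1))
  first <- all_rows[!duplicated(key), , drop = FALSE]
  first <- first[match(names(split_methods), paste0(first$contig, ":",
                                                    first$start)), ]
  keep <- n_methods >= min_methods
  out <- data.frame(contig = first$contig[keep], start = first$start[keep],
                    end = first$end[keep],
                    methods = vapply(split_methods[keep], function(m)
                      paste(sort(unique(m)), collapse = ","), character(1)),
                    n_methods = n_methods[keep], stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}
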