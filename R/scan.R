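#' Genome scan for selection signatures
#'
#' Runs the four window-based selection statistics on one contig and
#' combines their evidence. For the focal population the scan computes
#' pooled heterozygosity Hp; against each reference population it computes
#' window-averaged Weir-Cockerham FST, the log2 ratio of nucleotide
#' diversities (focal over reference), and, when the input is phased,
#' window-averaged XP-EHH (focal first, so positive values mean longer
#' haplotypes in the focal population). Hp and FST are Z-transformed
#' genome-wide; candidate windows lie strictly beyond the thresholds, and
#' windows flagged by at least `min_methods` distinct statistics form the
#' combined candidate set.
#'
#' With `threshold_mode = "fixed"` the printed-cut-off convention is used:
#' `Z(Hp) < thresholds$hp_z`, `Z(FST) > thresholds$fst_z`,
#' `XP-EHH > thresholds$xpehh` and `log2 pi-ratio > thresholds$pi_ratio`
#' (or `<` its negative with `ratio_tail = "lower"`). With
#' `"quantile"` each statistic's cut-off is the empirical genome-wide
#' quantile (`quantile_probs`) of its own track, the appropriate tail per
#' statistic — the right choice for small simulated genomes where
#' +/-4 SD outliers may not exist.
#'
#' @param vm A filtered [variant_matrix()] (phased for XP-EHH).
#' @param popmap A [population_map()] covering `vm`'s samples.
#' @param focal Focal population label (the one scanned for sweeps).
#' @param refs Character vector of reference population labels.
#' @param window_size,step Window size and slide in bp (default 100 kb,
#'   half-step).
#' @param contig_length Contig length in bp; defaults to the largest SNP
#'   position.
#' @param min_snps Windows with fewer usable SNPs are set missing
#'   (default 10).
#' @param thresholds Named list of fixed cut-offs: `hp_z` (-4), `fst_z`
#'   (4), `xpehh` (0.7), `pi_ratio` (2).
#' @param threshold_mode `"fixed"` or `"quantile"`.
#' @param quantile_probs Lower/upper tail probabilities for
#'   `threshold_mode = "quantile"` (default 0.01 / 0.99).
#' @param ratio_tail Which tail of the log2 pi-ratio flags candidates:
#'   `"upper"` (high focal diversity, the printed convention) or
#'   `"lower"` (diversity loss in the focal population, the sweep-in-focal
#'   direction).
#' @param min_methods Minimum number of distinct statistics supporting a
#'   combined candidate window (default 2).
#' @param xpehh_cutoff,xpehh_max_gap EHH truncation parameters, see
#'   [ehh()].
#' @param compute_xpehh Set `FALSE` to skip the haplotype statistic even
#'   on phased input.
#' @return An object of class `selection_scan` with elements `tracks`
#'   (named list of [scan_track()]s), `candidates` (per-statistic
#'   `candidate_set`s, comparisons merged per statistic), `combined`
#'   (multi-evidence `candidate_set`), `windows`, and `params`.
#' @export
selection_scan <- function(vm, popmap, focal, refs,
                           window_size = 100000, step = window_size / 2,
                           contig_length = NULL, min_snps = 10,
                           thresholds = list(hp_z = -4, fst_z = 4,
                                             xpehh = 0.7, pi_ratio = 2),
                           threshold_mode = c("fixed", "quantile"),
                           quantile_probs = c(lower = 0.01, upper = 0.99),
                           ratio_tail = c("upper", "lower"),
                           min_methods = 2,
                           xpehh_cutoff = 0.05, xpehh_max_gap = 200000,
                           compute_xpehh = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  ratio_tail <- match.arg(ratio_tail)
  for (p in c(focal, refs)) {
    if (!p %in% attr(popmap, "populations")) {
      stop("population '", p, "' not present in the population map",
           call. = FALSE)
    }
  }
  if (is.null(contig_length)) contig_length <- max(vm$positions)
  windows <- assign_snps(
    make_windows(contig_length, size = window_size, step = step,
                 contig = vm$contig), vm)
  focal_samples <- pop_samples(popmap, focal)
  do_xpehh <- compute_xpehh && !is.null(vm$haplotypes)

  tracks <- list()
  tracks[[paste0("Hp[", focal, "]")]] <-
    hp_track(vm, windows, focal_samples, min_snps, population = focal)
  pi_focal <- pi_track(vm, windows, focal_samples, min_snps,
                       population = focal)
  tracks[[paste0("pi[", focal, "]")]] <- pi_focal
  for (r in refs) {
    rs <- pop_samples(popmap, r)
    cmp <- paste(focal, "vs", r)
    tracks[[paste0("Fst[", cmp, "]")]] <-
      fst_track(vm, windows, focal_samples, rs, min_snps,
                comparison = cmp)
    pi_ref <- pi_track(vm, windows, rs, min_snps, population = r)
    tracks[[paste0("pi[", r, "]")]] <- pi_ref
    tracks[[paste0("pi_ratio[", cmp, "]")]] <-
      pi_ratio_track(pi_focal, pi_ref)
    if (do_xpehh) {
      xp <- xpehh_scan(vm, focal_samples, rs, cutoff = xpehh_cutoff,
                       max_gap = xpehh_max_gap)
      tracks[[paste0("XPEHH[", cmp, "]")]] <-
        xpehh_track(xp, windows, min_snps, comparison = cmp)
    }
  }

  pick <- function(stat) tracks[vapply(tracks, function(t)
    attr(t, "stat") == stat, logical(1))]
  sel <- function(stat, fixed, direction, on, prob) {
    trs <- pick(stat)
    # quantile thresholds are taken over the pooled values of all
    # comparisons of one statistic: one genome-wide cut-off per method
    thr <- if (threshold_mode == "fixed") fixed
    else stats::quantile(unlist(lapply(trs, `[[`, on)), prob,
                         na.rm = TRUE, names = FALSE)
    per <- lapply(trs, function(tr)
      select_candidates(tr, thr, direction = direction, on = on,
                        method = stat))
    do.call(rbind, per)
  }
  lowq <- quantile_probs[["lower"]]; upq <- quantile_probs[["upper"]]
  cand <- list(
    Hp = sel("Hp", thresholds$hp_z, "less", "z", lowq),
    Fst = sel("Fst", thresholds$fst_z, "greater", "z", upq),
    pi_ratio = if (ratio_tail == "upper")
      sel("pi_ratio", thresholds$pi_ratio, "greater", "raw", upq)
    else sel("pi_ratio", -thresholds$pi_ratio, "less", "raw", lowq))
  if (do_xpehh) {
    cand$XPEHH <- sel("XPEHH", thresholds$xpehh, "greater", "raw", upq)
  }
  cand <- lapply(cand, function(x) {
    class(x) <- c("candidate_set", "data.frame"); x
  })
  combined <- combine_evidence(cand, min_methods = min_methods)

  structure(list(
    tracks = tracks, candidates = cand, combined = combined,
    windows = windows,
    params = list(focal = focal, refs = refs, window_size = window_size,
                  step = step, contig_length = contig_length,
                  min_snps = min_snps, thresholds = thresholds,
                  threshold_mode = threshold_mode,
                  quantile_probs = quantile_probs,
                  ratio_tail = ratio_tail, min_methods = min_methods,
                  xpehh_cutoff = xpehh_cutoff,
                  xpehh_max_gap = xpehh_max_gap,
                  xpehh_computed = do_xpehh)),
    class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  p <- x$params
  cat(sprintf("selection_scan: focal %s vs %s; %d windows of %g kb (step %g kb)\n",
              p$focal, paste(p$refs, collapse = ", "), nrow(x$windows),
              p$window_size / 1000, p$step / 1000))
  cat(sprintf("  thresholds: %s mode; min_methods = %d\n",
              p$threshold_mode, p$min_methods))
  for (m in names(x$candidates)) {
    cat(sprintf("  %-9s %3d candidate window(s)\n", m,
                nrow(x$candidates[[m]])))
  }
  cat(sprintf("  combined (>=%d methods): %d window(s)\n", p$min_methods,
              nrow(x$combined)))
  invisible(x)
}

#' @export
summary.selection_scan <- function(object, ...) {
  print(object)
  cat("\ntracks:\n")
  for (nm in names(object$tracks)) {
    tr <- object$tracks[[nm]]
    def <- !is.na(tr$raw)
    cat(sprintf("  %-22s defined %3d/%3d  raw [%.4g, %.4g]\n", nm,
                sum(def), nrow(tr),
                if (any(def)) min(tr$raw[def]) else NA,
                if (any(def)) max(tr$raw[def]) else NA))
  }
  invisible(object)
}

#' @export
as.data.frame.selection_scan <- function(x, ...) {
  out <- x$windows[, c("contig", "start", "end", "n_snps")]
  for (nm in names(x$tracks)) {
    out[[paste0(nm, ".raw")]] <- x$tracks[[nm]]$raw
    out[[paste0(nm, ".z")]] <- x$tracks[[nm]]$z
  }
  out
}

#' Manhattan-style plot of a selection scan
#'
#' One panel per statistic type (Hp and FST on the Z scale, XP-EHH and
#' log2 pi-ratio raw), with the windows of the combined candidate set
#' highlighted.
#'
#' @param x A `selection_scan`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.selection_scan <- function(x, ...) {
  stats_shown <- intersect(c("Hp", "Fst", "XPEHH", "pi_ratio"),
                           unique(vapply(x$tracks, attr, "", "stat")))
  old <- graphics::par(mfrow = c(length(stats_shown), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  comb_key <- paste0(x$combined$contig, ":", x$combined$start)
  for (st in stats_shown) {
    trs <- x$tracks[vapply(x$tracks, function(t) attr(t, "stat") == st,
                           logical(1))]
    on <- if (st %in% c("Hp", "Fst")) "z" else "raw"
    ylab <- if (on == "z") paste0("Z(", st, ")") else st
    first <- TRUE
    for (tr in trs) {
      mid <- (tr$start + tr$end) / 2 / 1e6
      hit <- paste0(tr$contig, ":", tr$start) %in% comb_key
      if (first) {
        graphics::plot(mid, tr[[on]], type = "p", pch = 20,
                       col = ifelse(hit, "red", "grey40"),
                       xlab = "", ylab = ylab, main = st, ...)
        first <- FALSE
      } else {
        graphics::points(mid, tr[[on]], pch = 20,
                         col = ifelse(hit, "red", "grey40"))
      }
    }
  }
  invisible(x)
}

#' Did a scan recover a simulated sweep?
#'
#' A sweep counts as recovered when any window of the scan's combined
#' (multi-evidence) candidate set overlaps the simulator's recorded sweep
#' interval — the tract over which carriers share the origin haplotype.
#'
#' @param scan A `selection_scan`.
#' @param truth The `truth` element of a [wf_simulate()] result.
#' @return Logical.
#' @export
sweep_detected <- function(scan, truth) {
  if (is.null(truth)) return(FALSE)
  any(scan$combined$start <= truth$interval[2] &
        scan$combined$end > truth$interval[1])
}

#' Write scan outputs and a run manifest
#'
#' Emits one TSV per track (`contig, start, end, n_snps, raw, z, pass`),
#' a BED6 of the combined candidate windows, and a JSON manifest capturing
#' the parameters, input checksums, seed and output paths; re-running with
#' identical inputs reproduces the statistic files byte for byte. Every
#' file starts with comment lines stating the thresholds and the XP-EHH
#' sign convention in force.
#'
#' @param scan A `selection_scan`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest (optional).
#' @param inputs Character vector of input file paths to checksum into the
#'   manifest (optional).
#' @return Invisibly, the manifest as a list.
#' @export
write_scan_outputs <- function(scan, dir, seed = NULL, inputs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- scan$params
  hdr <- c(
    sprintf("# sweepscan %s", as.character(utils::packageVersion("sweepscan"))),
    sprintf("# focal=%s refs=%s window=%g step=%g min_snps=%d min_methods=%d",
            p$focal, paste(p$refs, collapse = ","), p$window_size, p$step,
            p$min_snps, p$min_methods),
    sprintf("# threshold_mode=%s hp_z=%g fst_z=%g xpehh=%g pi_ratio=%g ratio_tail=%s",
            p$threshold_mode, p$thresholds$hp_z, p$thresholds$fst_z,
            p$thresholds$xpehh, p$thresholds$pi_ratio, p$ratio_tail),
    "# convention: positive XP-EHH = longer haplotypes in the focal population")
  paths <- character(0)
  comb_key <- paste0(scan$combined$contig, ":", scan$combined$start)
  for (nm in names(scan$tracks)) {
    tr <- scan$tracks[[nm]]
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv"))
    con <- file(fn, "w")
    writeLines(hdr, con)
    df <- data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                     n_snps = tr$n_snps,
                     raw = formatC(tr$raw, digits = 10, format = "g"),
                     z = formatC(tr$z, digits = 10, format = "g"),
                     pass = paste0(tr$contig, ":", tr$start) %in% comb_key)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    paths <- c(paths, fn)
  }
  bed <- file.path(dir, "combined_candidates.bed")
  write_bed(scan$combined, bed, score = scan$combined$n_methods)
  paths <- c(paths, bed)
  manifest <- list(
    tool = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    params = p[setdiff(names(p), "quantile_probs")],
    quantile_probs = as.list(p$quantile_probs),
    seed = seed,
    inputs = if (!is.null(inputs))
      as.list(tools::md5sum(inputs)) else NULL,
    outputs = paths)
  mf <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), mf)
  invisible(manifest)
}
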