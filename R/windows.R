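#' Generate half-step sliding windows over a contig
#'
#' Windows start at `0, step, 2*step, ...` (0-based half-open) and have
#' width `size` except for trailing windows truncated at the contig end.
#' Every window containing at least one bp is emitted, so the union of the
#' windows is exactly `[0, contig_length)`; truncated windows carry
#' `partial = TRUE` so downstream statistics can treat them separately.
#' The defaults are the 100-kb window with half-step (50-kb) sliding used
#' throughout the scan.
#'
#' @param contig_length Contig length in bp.
#' @param size Window size in bp (default 100000).
#' @param step Slide in bp (default `size / 2`).
#' @param contig Contig identifier attached to each window.
#' @return A `scan_windows` data frame with columns `contig`, `start`,
#'   `end`, `partial`.
#' @export
make_windows <- function(contig_length, size = 100000, step = size / 2,
                         contig = "1") {
  if (size <= 0 || step <= 0) stop("size and step must be positive",
                                   call. = FALSE)
  if (step > size) stop("step must not exceed size", call. = FALSE)
  if (contig_length <= 0) stop("contig_length must be positive",
                               call. = FALSE)
  starts <- seq(0L, by = as.integer(step),
                length.out = ceiling(contig_length / step))
  starts <- starts[starts < contig_length]
  ends <- pmin(starts + as.integer(size), as.integer(contig_length))
  out <- data.frame(contig = contig, start = as.integer(starts),
                    end = as.integer(ends),
                    partial = (ends - starts) < size,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_windows", "data.frame")
  out
}

#' Assign SNPs of a variant matrix to windows
#'
#' A SNP at 1-based position `p` belongs to window `[start, end)` when
#' `start <= p - 1 < end`. With half-step sliding every interior SNP falls
#' in exactly two windows.
#'
#' @param windows A `scan_windows` data frame from [make_windows()].
#' @param vm A [variant_matrix()] on the same contig.
#' @return `windows` with a list column `snp_idx` of integer indices into
#'   `vm$positions`, plus an `n_snps` count column.
#' @export
assign_snps <- function(windows, vm) {
  if (nrow(windows) && !all(windows$contig == vm$contig)) {
    stop("windows and variant matrix are on different contigs",
         call. = FALSE)
  }
  pos0 <- vm$positions - 1L
  idx <- lapply(seq_len(nrow(windows)), function(i) {
    # positions sorted: locate [start, end) by binary search
    lo <- findInterval(windows$start[i] - 0.5, pos0) + 1L
    hi <- findInterval(windows$end[i] - 0.5, pos0)
    if (hi < lo) integer(0) else seq.int(lo, hi)
  })
  windows$snp_idx <- idx
  windows$n_snps <- lengths(idx)
  windows
}

window_id <- function(windows) paste0(windows$contig, ":", windows$start)
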