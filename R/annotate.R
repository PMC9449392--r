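#' Map candidate windows to genes with a flanking margin
#'
#' Each candidate window is extended by `flank` bp on both sides (clipped
#' at 0) and a gene is reported when its interval overlaps the extended
#' window by at least 1 bp (half-open interval intersection; strand is
#' ignored, the flank rule being symmetric). Genes hit by several windows
#' are reported once with their supporting windows and methods merged.
#'
#' @param candidates A `candidate_set` (e.g. from [combine_evidence()]),
#'   with 0-based half-open `start`/`end` and, optionally, a `methods` or
#'   `method` column.
#' @param genes A `gene_set` from [read_genes()].
#' @param flank Flank size in bp applied to windows (default 50000).
#' @return A `candidate_gene_report` data frame: `gene_id`, `contig`,
#'   `start`, `end`, `n_windows`, `windows`, `methods`.
#' @export
genes_in_windows <- function(candidates, genes, flank = 50000) {
  known <- unique(candidates$contig)
  unknown <- !(genes$contig %in% known)
  if (any(unknown) && nrow(candidates)) {
    warning(sum(unknown), " gene(s) on contigs without candidate windows",
            call. = FALSE)
  }
  meth_col <- if (!is.null(candidates$methods)) candidates$methods
  else if (!is.null(candidates$method)) candidates$method
  else rep("", nrow(candidates))
  hits <- vector("list", nrow(genes))
  ext_start <- pmax(candidates$start - flank, 0)
  ext_end <- candidates$end + flank
  for (k in seq_len(nrow(genes))) {
    ov <- which(candidates$contig == genes$contig[k] &
                  ext_start < genes$end[k] & genes$start[k] < ext_end)
    if (length(ov)) hits[[k]] <- ov
  }
  hit_genes <- which(lengths(hits) > 0L)
  out <- data.frame(
    gene_id = genes$gene_id[hit_genes],
    contig = genes$contig[hit_genes],
    start = genes$start[hit_genes],
    end = genes$end[hit_genes],
    n_windows = lengths(hits[hit_genes]),
    windows = vapply(hits[hit_genes], function(ov)
      paste(sprintf("%s:%d-%d", candidates$contig[ov],
                    candidates$start[ov], candidates$end[ov]),
            collapse = ";"), character(1)),
    methods = vapply(hits[hit_genes], function(ov)
      paste(sort(unique(unlist(strsplit(meth_col[ov], ",")))),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(out, "flank") <- flank
  class(out) <- c("candidate_gene_report", "data.frame")
  out
}

#' Per-method gene counts and their overlaps
#'
#' Given one gene report per statistic, tabulates the gene count of each
#' method together with all pairwise intersections and the overall
#' intersection — the window-level analogue of a Venn diagram of candidate
#' genes across detection methods.
#'
#' @param reports Named list of `candidate_gene_report`s (or character
#'   vectors of gene ids), one per method/statistic.
#' @return List with `counts` (named per-method gene counts), `pairwise`
#'   (matrix of intersection cardinalities), `all_methods` (character
#'   vector of genes found by every method) and `gene_sets`.
#' @export
per_method_gene_counts <- function(reports) {
  sets <- lapply(reports, function(r)
    unique(if (is.character(r)) r else r$gene_id))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("method", seq_along(sets))
  }
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  list(counts = vapply(sets, length, integer(1)),
       pairwise = pw,
       all_methods = Reduce(intersect, sets),
       gene_sets = sets)
}
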