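#' Read a sample-to-population map
#'
#' Two whitespace-separated columns: sample id, population label. A sample
#' listed twice with conflicting labels is an error; exact duplicate rows
#' are tolerated.
#'
#' @param path Path to the map file.
#' @return An object of class `population_map`: a named character vector of
#'   labels (names are sample ids) with a `populations` attribute holding
#'   the ordered set of labels.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"),
                           colClasses = "character")
  population_map(stats::setNames(tab$population, tab$sample))
}

#' Build a population map from a named vector
#'
#' @param assignments Named character vector: `names()` are sample ids,
#'   values are population labels.
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignments) {
  samples <- names(assignments)
  if (is.null(samples) || any(samples == "")) {
    stop("assignments must be named by sample id", call. = FALSE)
  }
  dup <- samples[duplicated(samples)]
  for (s in unique(dup)) {
    if (length(unique(assignments[samples == s])) > 1L) {
      stop("sample '", s, "' assigned to more than one population",
           call. = FALSE)
    }
  }
  keep <- !duplicated(samples)
  out <- assignments[keep]
  attr(out, "populations") <- unique(unname(out))
  class(out) <- "population_map"
  out
}

#' Samples belonging to one population
#'
#' @param popmap A [population_map()].
#' @param population Population label.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(popmap, population) {
  if (!population %in% attr(popmap, "populations")) {
    stop("population '", population, "' not present in map", call. = FALSE)
  }
  names(popmap)[unname(unclass(popmap)) == population]
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = attr(x, "populations")))
  cat("population_map:", length(x), "samples in", length(tab),
      "populations\n")
  for (p in names(tab)) cat(sprintf("  %s: %d\n", p, tab[[p]]))
  invisible(x)
}

#' Read gene annotations from BED or GFF3
#'
#' GFF3 input is restricted to `gene` features. Coordinates are stored
#' 0-based half-open internally (BED convention); GFF3's 1-based inclusive
#' intervals are converted on ingestion.
#'
#' @param path Path to a `.bed`, `.gff` or `.gff3` file.
#' @return A `gene_set`: data frame with columns `gene_id`, `contig`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) {
                     stop("malformed GFF3 (", conditionMessage(e), ")",
                          call. = FALSE)
                   })
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    if (is.null(id)) id <- paste0("gene", seq_along(gr))
    gs <- data.frame(gene_id = as.character(id),
                     contig = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     stringsAsFactors = FALSE)
  } else if (ext == "bed") {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    gs <- data.frame(gene_id = if (ncol(raw) >= 4) as.character(raw[[4]])
                     else paste0("gene", seq_len(nrow(raw))),
                     contig = as.character(raw[[1]]),
                     start = raw[[2]], end = raw[[3]],
                     strand = if (ncol(raw) >= 6) raw[[6]] else "*",
                     stringsAsFactors = FALSE)
    if (any(gs$start > gs$end)) stop("BED gene with start > end",
                                     call. = FALSE)
  } else {
    stop("unrecognised gene annotation format: .", ext, call. = FALSE)
  }
  class(gs) <- c("gene_set", "data.frame")
  gs
}

#' Write windows (or candidate windows) as BED6
#'
#' Intervals are written 0-based half-open; column 4 is a window name,
#' column 5 the supplied statistic value, column 6 `.`.
#'
#' @param windows Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param path Output path.
#' @param score Numeric vector for column 5 (recycled); default 0.
#' @param name Names for column 4; default `contig:start-end`.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(windows, path, score = 0, name = NULL) {
  if (is.null(name)) {
    name <- sprintf("%s:%d-%d", windows$contig, windows$start, windows$end)
  }
  df <- data.frame(windows$contig, windows$start, windows$end, name,
                   rep_len(score, nrow(windows)),
                   rep_len(".", nrow(windows)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (3+ columns).
#' @return Data frame with `contig`, `start`, `end` (0-based half-open) and,
#'   when present, `name` and `score`.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(contig = as.character(raw[[1]]), start = raw[[2]],
                    end = raw[[3]], stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$score <- as.numeric(raw[[5]])
  out
}

#' Read FAI-style contig lengths
#'
#' @param path Two-or-more-column whitespace file: contig, length.
#' @return Named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}
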