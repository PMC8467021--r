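# Reading and writing peak catalogues in the ReMap BED dialect, CRM region
# handling, and peak-to-CRM assignment. Coordinates are BED 0-based half-open
# throughout; strand is carried along but ignored (peaks are strandless
# regions).

new_source_catalog <- function(datasets, regulators, abundance) {
  structure(list(datasets = datasets, regulators = regulators,
                 abundance = abundance),
            class = "source_catalog")
}

#' Source catalog: the (dataset, regulator) axes of the tensors
#'
#' Builds the bidirectional mapping between sources and tensor axes from a
#' peak table. Axis orders are deterministic: lexicographic unless explicit
#' orders are supplied. Per-source peak counts (abundances) are recorded for
#' the Q-score weighting and the normalization.
#'
#' @param peaks Peak data.frame with `dataset` and `regulator` columns.
#' @param datasets,regulators Optional explicit axis orders; every source seen
#'   in `peaks` must be covered.
#' @return An object of class `source_catalog` with `datasets`, `regulators`
#'   and an m x n `abundance` count matrix.
#' @export
source_catalog <- function(peaks, datasets = NULL, regulators = NULL) {
  if (is.null(datasets)) datasets <- sort(unique(peaks$dataset))
  if (is.null(regulators)) regulators <- sort(unique(peaks$regulator))
  if (!all(peaks$dataset %in% datasets) || !all(peaks$regulator %in% regulators)) {
    stop("peaks contain sources outside the supplied axis orders")
  }
  ab <- table(factor(peaks$dataset, levels = datasets),
              factor(peaks$regulator, levels = regulators))
  ab <- matrix(as.integer(ab), length(datasets), length(regulators),
               dimnames = list(datasets, regulators))
  new_source_catalog(datasets, regulators, ab)
}

#' @export
print.source_catalog <- function(x, ...) {
  cat(sprintf("source_catalog: %d datasets x %d regulators, %d peaks\n",
              length(x$datasets), length(x$regulators), sum(x$abundance)))
  invisible(x)
}

# "dataset.regulator.cellline"; extra dot-tokens are appended to the dataset.
parse_remap_names <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  ntok <- lengths(parts)
  ok <- ntok >= 3L
  dataset <- regulator <- cell_line <- rep(NA_character_, length(names))
  if (any(ok)) {
    dataset[ok] <- vapply(parts[ok], function(p) {
      paste(p[seq_len(length(p) - 2L)], collapse = ".")
    }, character(1))
    regulator[ok] <- vapply(parts[ok], function(p) p[length(p) - 1L], character(1))
    cell_line[ok] <- vapply(parts[ok], function(p) p[length(p)], character(1))
  }
  ok <- ok & !is.na(dataset) & nzchar(dataset) & nzchar(regulator)
  list(dataset = dataset, regulator = regulator, cell_line = cell_line, ok = ok)
}

#' Read a ReMap-dialect BED peak file
#'
#' One peak per line, BED6; the name field encodes `dataset.regulator.cellline`
#' (e.g. "GSE52924.BRD4.HELA"). Only peaks whose cell line matches exactly are
#' retained — cell-line variants such as "CD34_condition1" are excluded by the
#' exact match. Malformed name fields are reported with their line numbers and
#' skipped (or abort the read in strict mode).
#'
#' @param path BED file path.
#' @param cell_line Cell line to retain (exact match).
#' @param strict Abort on any unparsable name field instead of skipping.
#' @return List with `peaks` (data.frame: `chrom`, `start`, `end`, `name`,
#'   `dataset`, `regulator`, `cell_line`, `strand`, `line_index`) and
#'   `catalog` (a [source_catalog()] built from the retained records).
#' @export
read_remap_bed <- function(path, cell_line, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fill = TRUE, colClasses = "character")
  if (ncol(tab) < 4) stop("need at least BED4 (chrom, start, end, name)")
  if (ncol(tab) < 6) tab[, (ncol(tab) + 1):6] <- ""
  names(tab)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  parsed <- parse_remap_names(tab$name)
  if (any(!parsed$ok)) {
    bad <- which(!parsed$ok)
    msg <- paste0("unparsable name field on line(s) ",
                  paste(utils::head(bad, 20), collapse = ", "),
                  if (length(bad) > 20) sprintf(" (and %d more)", length(bad) - 20))
    if (strict) stop(msg)
    warning(msg, "; skipping")
  }
  keep <- parsed$ok & parsed$cell_line == cell_line
  keep[is.na(keep)] <- FALSE
  peaks <- data.frame(chrom = tab$chrom[keep], start = tab$start[keep],
                      end = tab$end[keep], name = tab$name[keep],
                      dataset = parsed$dataset[keep],
                      regulator = parsed$regulator[keep],
                      cell_line = parsed$cell_line[keep],
                      strand = ifelse(is.na(tab$strand[keep]) |
                                        !nzchar(tab$strand[keep]),
                                      ".", tab$strand[keep]),
                      line_index = which(keep),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0) {
    stop("no peaks for cell line '", cell_line, "' in ", path)
  }
  if (any(peaks$start >= peaks$end)) stop("invalid interval(s): start >= end")
  list(peaks = peaks, catalog = source_catalog(peaks))
}

#' Read candidate CRM regions (BED3+1)
#'
#' @param path BED path: chrom, start, end, and optionally a stable crm_id
#'   (4th column, default the line number) and peak_count (5th column).
#' @return data.frame with `chrom`, `start`, `end`, `crm_id`, `peak_count`
#'   (NA when absent from the file).
#' @export
read_crm_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    crm_id = if (ncol(tab) >= 4) as.integer(tab[[4]]) else
                      seq_len(nrow(tab)),
                    peak_count = if (ncol(tab) >= 5) as.integer(tab[[5]]) else
                      NA_integer_)
  if (any(out$start >= out$end)) stop("invalid region(s): start >= end")
  out
}

#' Filter candidate CRMs on peak count
#'
#' The reference selection keeps CRMs binding at least 100 peaks to focus on
#' the densest genomic regions; the threshold is configurable here.
#'
#' @param regions CRM data.frame with a populated `peak_count`.
#' @param min_peaks Minimum number of peaks (default 100).
#' @return The filtered regions, input order preserved.
#' @export
filter_crms <- function(regions, min_peaks = 100L) {
  if (anyNA(regions$peak_count)) stop("peak_count is not populated")
  regions[regions$peak_count >= min_peaks, , drop = FALSE]
}

peaks_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

check_sorted <- function(df, what) {
  o <- order(df$chrom, df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    stop(what, " must be sorted by (chrom, start)")
  }
}

#' Assign peaks to overlapping CRM windows
#'
#' A peak is assigned to every region it overlaps by at least 1 bp (half-open
#' intervals); peaks overlapping two CRMs are assigned to both, as required by
#' the cross-window score merge. Peaks overlapping no region land in the
#' `unassigned` bucket.
#'
#' @param peaks Peak data.frame, sorted by (chrom, start).
#' @param regions CRM data.frame with `crm_id`, sorted by (chrom, start).
#' @return List with `assigned` (named list: as.character(crm_id) -> integer
#'   row indices into `peaks`) and `unassigned` (integer row indices).
#' @export
assign_peaks <- function(peaks, regions) {
  check_sorted(peaks, "peaks")
  check_sorted(regions, "regions")
  hits <- GenomicRanges::findOverlaps(peaks_granges(peaks),
                                      peaks_granges(regions),
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  assigned <- split(qh, regions$crm_id[sh])
  unassigned <- setdiff(seq_len(nrow(peaks)), unique(qh))
  list(assigned = assigned, unassigned = unassigned)
}

#' Fill per-region peak counts
#'
#' @param peaks Peak data.frame, sorted by (chrom, start).
#' @param regions CRM regions, sorted by (chrom, start).
#' @return `regions` with `peak_count` populated (a peak spanning two regions
#'   counts in both).
#' @export
crm_peak_counts <- function(peaks, regions) {
  asg <- assign_peaks(peaks, regions)
  counts <- lengths(asg$assigned)
  regions$peak_count <- as.integer(counts[as.character(regions$crm_id)])
  regions$peak_count[is.na(regions$peak_count)] <- 0L
  regions
}

#' Write a scored BED file
#'
#' BED6+1: the score field holds the final normalized score clamped to
#' [0, 1000] and rounded to integer; a seventh column carries the unclamped
#' score. Input order is preserved and the name field is written back
#' unchanged.
#'
#' @param peaks Peak data.frame from [read_remap_bed()] (or equivalent with
#'   `chrom`, `start`, `end`, `name`, `strand`).
#' @param scores Numeric vector of final scores, one per peak.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_bed <- function(peaks, scores, path) {
  if (length(scores) != nrow(peaks) || anyNA(scores)) {
    stop("need one non-missing score per peak")
  }
  clamped <- as.integer(round(pmin(pmax(scores, 0), 1000)))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    clamped, peaks$strand, scores)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
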