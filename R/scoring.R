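# Reconstruction-error scoring: the anomaly tensor A, per-peak max read-out,
# and cross-window merging.

#' Anomaly tensor
#'
#' Elementwise comparison of a tensor with its reconstruction:
#' `A = 0` where the original is 0, else `1 - (orig - rebuilt)/orig`
#' (algebraically `rebuilt/orig`). Dividing by the original value makes the
#' score invariant to crumbing. Rebuilt values are not clipped, so negative
#' reconstructions yield negative A values; these are handled later by
#' normalization and the final clamping.
#'
#' @param original,rebuilt [crm_tensor]s (or 3D arrays) of identical shape.
#' @return A `crm_tensor` with the same geometry holding A.
#' @export
anomaly_tensor <- function(original, rebuilt) {
  ov <- tensor_values(original)
  rv <- tensor_values(rebuilt)
  if (!all(dim(ov) == dim(rv))) stop("original and rebuilt shapes differ")
  a <- rv / ov
  a[ov == 0] <- 0
  if (!all(is.finite(a))) stop("non-finite anomaly values")
  tensor_like(original, a)
}

# Bin span of a genomic interval inside a tensor window, margins excluded.
# Returns NULL when the clipped span is empty.
bin_span <- function(anchor, bin_size, margin, X, start, end) {
  bs <- bin_size
  core_start <- anchor + margin * bs
  core_end <- anchor + (X - margin) * bs
  s <- max(start, core_start)
  e <- min(end, core_end)
  if (e <= s) return(NULL)
  b1 <- margin + floor((s - core_start) / bs) + 1L
  b2 <- margin + ceiling((e - core_start) / bs)
  c(b1, b2)
}

peak_bin_span <- function(tensor, start, end) {
  bin_span(tensor$anchor, tensor$bin_size, tensor$margin,
           dim(tensor$values)[1], start, end)
}

#' Per-window anomaly score of one peak
#'
#' The score is the maximum value of A across all bins the peak covers (a peak
#' covering any part of a bin includes that bin; margins are excluded), at the
#' peak's (dataset, regulator) coordinates. The max read-out corrects for
#' nearby peaks that are only well-rebuilt where they overlap, and for peaks
#' shorter than the convolution kernels.
#'
#' @param anomaly The anomaly [crm_tensor] from [anomaly_tensor()].
#' @param peak One-row peak data.frame (`start`, `end`, `dataset`, `regulator`).
#' @param catalog The [source_catalog()] mapping sources to axes.
#' @return The per-window score (scalar).
#' @export
score_peak <- function(anomaly, peak, catalog) {
  y <- match(peak$dataset, catalog$datasets)
  z <- match(peak$regulator, catalog$regulators)
  if (is.na(y) || is.na(z)) {
    stop("peak source ", peak$dataset, ".", peak$regulator, " not in catalog")
  }
  span <- peak_bin_span(anomaly, peak$start, peak$end)
  if (is.null(span)) stop("peak does not map into the window")
  max(anomaly$values[span[1]:span[2], y, z])
}

#' Merge per-window scores of a peak
#'
#' Peaks split between consecutive tensor windows get one score per window;
#' the merged raw score is their arithmetic mean.
#'
#' @param window_scores Numeric vector of per-window scores (length >= 1).
#' @return The merged raw score.
#' @export
merge_windows <- function(window_scores) {
  if (length(window_scores) == 0) stop("no window scores to merge")
  mean(window_scores)
}

#' Raw anomaly scores for the peaks of one CRM
#'
#' Runs the tensor pipeline, reconstructs each window through the model,
#' forms the anomaly tensor, reads out each peak's per-window max, and merges
#' across windows.
#'
#' @param model A trained `anopeak_model` (or reconstructor function).
#' @param crm One-row CRM data.frame.
#' @param peaks Peaks assigned to the CRM.
#' @param catalog The [source_catalog()].
#' @param ... Tensor pipeline options passed to [prepare_tensors()].
#' @return `peaks` with columns `raw` (merged raw score) and `n_windows`.
#' @export
score_peaks <- function(model, crm, peaks, catalog, ...) {
  tens <- prepare_tensors(crm, peaks, catalog, ...)
  per_window <- lapply(tens, function(tt) {
    a <- anomaly_tensor(tt, reconstruct(model, tt))
    vapply(seq_len(nrow(peaks)), function(i) {
      if (is.null(peak_bin_span(a, peaks$start[i], peaks$end[i]))) NA_real_
      else score_peak(a, peaks[i, ], catalog)
    }, numeric(1))
  })
  mat <- do.call(cbind, per_window)
  peaks$raw <- apply(mat, 1, function(v) merge_windows(v[!is.na(v)]))
  peaks$n_windows <- rowSums(!is.na(mat))
  peaks
}

# Batched raw scoring over a tensor_set where peaks carry a window (column)
# index. Used by the pipeline and the artificial-data evaluations; equivalent
# to score_peaks() window by window.
score_peaks_set <- function(orig_set, recon, peaks, window_of, catalog) {
  stopifnot(length(window_of) == nrow(peaks))
  X <- orig_set$shape[1]
  a <- recon / orig_set$data
  a[orig_set$data == 0] <- 0
  y <- match(peaks$dataset, catalog$datasets)
  z <- match(peaks$regulator, catalog$regulators)
  if (anyNA(y) || anyNA(z)) stop("peak source not in catalog")
  vapply(seq_len(nrow(peaks)), function(i) {
    j <- window_of[i]
    span <- bin_span(orig_set$anchor[j], orig_set$bin_size, orig_set$margin,
                     X, peaks$start[i], peaks$end[i])
    if (is.null(span)) return(NA_real_)
    rows <- (z[i] - 1L) * X * orig_set$shape[2] + (y[i] - 1L) * X +
      (span[1]:span[2])
    max(a[rows, j])
  }, numeric(1))
}
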