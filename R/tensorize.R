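# CRM tensor construction: binarize peak presence over a fixed genomic window,
# max-pool ("squish") the position axis, add zero margins for the convolutions,
# and optionally "crumb" sparse real data.

new_crm_tensor <- function(values, chrom, anchor, bin_size, margin, crumbed) {
  structure(list(values = values, chrom = chrom, anchor = anchor,
                 bin_size = bin_size, margin = as.integer(margin),
                 crumbed = isTRUE(crumbed)),
            class = "crm_tensor")
}

tensor_values <- function(x) {
  if (inherits(x, "crm_tensor")) x$values else x
}

# copy geometry, replace values
tensor_like <- function(x, values) {
  if (inherits(x, "crm_tensor")) {
    y <- x
    y$values <- values
    y
  } else values
}

#' @export
print.crm_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("crm_tensor %s:%d  %d bins x %d datasets x %d regulators (bin %d bp, margin %d, %s)\n",
              x$chrom, x$anchor, d[1], d[2], d[3], x$bin_size, x$margin,
              if (x$crumbed) "crumbed" else "binary"))
  invisible(x)
}

#' Build presence tensors for a CRM
#'
#' Encodes the peaks of one candidate cis-regulatory module as 3D tensors of
#' peak presence at base-pair resolution: value 1 at (x, dataset, regulator)
#' wherever a peak of that source covers genomic base x, 0 elsewhere
#' (presence, not count). CRMs longer than `window_bp` are split into
#' consecutive windows so that every peak appears in at least one window;
#' shorter CRMs are zero-padded to `window_bp`.
#'
#' @param crm A one-row data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), as returned by [read_crm_bed()].
#' @param peaks Peak data.frame (see [read_remap_bed()]); all peaks must
#'   overlap the CRM and have sources present in `catalog`.
#' @param catalog A [source_catalog()] fixing the dataset (Y) and regulator (Z)
#'   axis order.
#' @param window_bp Window length in bp (default 3200).
#' @return A list of [crm_tensor] objects, one per window, with `bin_size = 1`
#'   and no margins.
#' @export
build_tensor <- function(crm, peaks, catalog, window_bp = 3200L) {
  stopifnot(window_bp > 0, nrow(crm) == 1)
  m <- length(catalog$datasets)
  n <- length(catalog$regulators)
  y <- match(peaks$dataset, catalog$datasets)
  z <- match(peaks$regulator, catalog$regulators)
  if (anyNA(y) || anyNA(z)) {
    bad <- unique(paste0(peaks$dataset, ".", peaks$regulator)[is.na(y) | is.na(z)])
    stop("peak source(s) absent from catalog: ", paste(bad, collapse = ", "))
  }
  len <- crm$end - crm$start
  n_win <- max(1L, as.integer(ceiling(len / window_bp)))
  lapply(seq_len(n_win), function(w) {
    wstart <- crm$start + (w - 1L) * window_bp
    vals <- array(0, dim = c(window_bp, m, n))
    for (i in seq_len(nrow(peaks))) {
      x1 <- max(peaks$start[i], wstart) - wstart
      x2 <- min(peaks$end[i], wstart + window_bp) - wstart
      if (x2 > x1) vals[(x1 + 1L):x2, y[i], z[i]] <- 1
    }
    new_crm_tensor(vals, crm$chrom, wstart, 1L, 0L, FALSE)
  })
}

#' Downscale the position axis by max-pooling ("squishing")
#'
#' Each output bin takes the maximum over its `factor` input positions, so any
#' coverage within a bin marks it (presence pooling keeps the \{0, 1\} domain).
#'
#' @param tensor A [crm_tensor].
#' @param factor Pooling factor (default 10).
#' @return The squished `crm_tensor`; `bin_size` is multiplied by `factor`.
#' @export
squish <- function(tensor, factor = 10L) {
  stopifnot(inherits(tensor, "crm_tensor"), factor >= 1)
  if (tensor$crumbed) stop("squish must be applied before crumbing")
  d <- dim(tensor$values)
  if (d[1] %% factor != 0) {
    stop("position axis length ", d[1], " is not divisible by factor ", factor)
  }
  if (tensor$margin %% factor != 0) {
    stop("margin must be divisible by the squish factor (squish before padding)")
  }
  v <- tensor$values
  dim(v) <- c(factor, (d[1] %/% factor) * d[2] * d[3])
  out <- v[1, ]
  for (i in seq_len(factor)[-1]) out <- pmax(out, v[i, ])
  dim(out) <- c(d[1] %/% factor, d[2], d[3])
  tensor$values <- out
  tensor$bin_size <- tensor$bin_size * as.integer(factor)
  tensor$margin <- tensor$margin %/% as.integer(factor)
  tensor
}

#' Add zero margins along the position axis
#'
#' Prepends and appends `2 * kernel_len` all-zero bins so that convolutional
#' border effects fall outside the scored region. The genomic anchor is shifted
#' so that coordinate mapping is preserved, and the margin width is recorded
#' for exclusion at score read-out.
#'
#' @param tensor A [crm_tensor].
#' @param kernel_len Convolutional kernel length k (default 20); the margin is
#'   2k bins on each side.
#' @return The padded `crm_tensor`.
#' @export
pad_margins <- function(tensor, kernel_len = 20L) {
  stopifnot(inherits(tensor, "crm_tensor"), kernel_len >= 0)
  if (kernel_len == 0) return(tensor)
  if (tensor$crumbed) stop("pad_margins must be applied before crumbing")
  pad <- 2L * as.integer(kernel_len)
  d <- dim(tensor$values)
  vals <- array(0, dim = c(d[1] + 2L * pad, d[2], d[3]))
  vals[(pad + 1L):(pad + d[1]), , ] <- tensor$values
  tensor$values <- vals
  tensor$anchor <- tensor$anchor - pad * tensor$bin_size
  tensor$margin <- tensor$margin + pad
  tensor
}

#' Crumb a sparse tensor
#'
#' For every cell (x, y, z) holding an original value v > 0, `fraction * v` is
#' added to every other cell in the same position slice sharing the dataset
#' (x, y, z') or the regulator (x, y', z) — the "+" pattern that gives the
#' model a sparsity hint on real data. Crumbing is cumulative: contributions
#' from multiple peaks sum, and originally non-zero cells also receive crumbs
#' from other peaks.
#'
#' @param tensor A not-yet-crumbed [crm_tensor].
#' @param fraction Crumb fraction (default 0.1).
#' @return The crumbed `crm_tensor` (values may now exceed 1).
#' @export
crumb <- function(tensor, fraction = 0.1) {
  stopifnot(inherits(tensor, "crm_tensor"))
  if (tensor$crumbed) stop("tensor is already crumbed")
  v <- tensor$values
  d <- dim(v)
  # row/column sums within each X slice; subtract own value: a cell never
  # crumbs itself, and received crumbs add to the original value.
  sum_y <- apply(v, c(1, 3), sum)                 # (X, n): sum over datasets
  sum_z <- apply(v, c(1, 2), sum)                 # (X, m): sum over regulators
  crumbs <- fraction * (aperm(array(sum_y, c(d[1], d[3], d[2])), c(1, 3, 2)) - v) +
            fraction * (array(sum_z, c(d[1], d[2], d[3])) - v)
  tensor$values <- v + crumbs
  tensor$crumbed <- TRUE
  tensor
}

#' Run the full tensor pipeline for one CRM
#'
#' build -> squish -> pad -> (crumb). Crumbing is off by default and should be
#' enabled only for sparse real biological data.
#'
#' @inheritParams build_tensor
#' @param squish_factor Position downscaling factor.
#' @param kernel_len Conv kernel length (sets the margin width 2k per side).
#' @param crumb_enabled Apply crumbing after padding.
#' @param crumb_fraction Crumb fraction.
#' @return A list of model-ready [crm_tensor] windows.
#' @export
prepare_tensors <- function(crm, peaks, catalog, window_bp = 3200L,
                            squish_factor = 10L, kernel_len = 20L,
                            crumb_enabled = FALSE, crumb_fraction = 0.1) {
  tens <- build_tensor(crm, peaks, catalog, window_bp)
  lapply(tens, function(tt) {
    tt <- squish(tt, squish_factor)
    tt <- pad_margins(tt, kernel_len)
    if (crumb_enabled) tt <- crumb(tt, crumb_fraction)
    tt
  })
}

#' Bundle tensors of identical geometry into a dense set
#'
#' Flattens a list of [crm_tensor] objects (position fastest, then dataset,
#' then regulator) into one matrix with a tensor per column — the container
#' used by training, scoring, calibration and the Q-score.
#'
#' @param tensors List of `crm_tensor`s sharing shape, margin and bin size.
#' @return An object of class `tensor_set` with elements `data` (matrix
#'   X*m*n x N), `shape`, `margin`, `bin_size`, `crumbed`, and per-tensor
#'   `chrom`/`anchor` vectors.
#' @export
tensor_set <- function(tensors) {
  stopifnot(length(tensors) > 0)
  d <- dim(tensors[[1]]$values)
  mg <- tensors[[1]]$margin
  bs <- tensors[[1]]$bin_size
  cr <- tensors[[1]]$crumbed
  data <- vapply(tensors, function(tt) {
    if (!all(dim(tt$values) == d) || tt$margin != mg || tt$bin_size != bs ||
        tt$crumbed != cr) {
      stop("all tensors in a set must share shape, margin, bin size and crumb state")
    }
    as.vector(tt$values)
  }, numeric(prod(d)))
  structure(list(data = matrix(data, nrow = prod(d)), shape = d, margin = mg,
                 bin_size = bs, crumbed = cr,
                 chrom = vapply(tensors, `[[`, character(1), "chrom"),
                 anchor = vapply(tensors, `[[`, numeric(1), "anchor")),
            class = "tensor_set")
}

#' @export
print.tensor_set <- function(x, ...) {
  cat(sprintf("tensor_set: %d tensors of %s (margin %d, bin %d bp%s)\n",
              ncol(x$data), paste(x$shape, collapse = " x "), x$margin,
              x$bin_size, if (x$crumbed) ", crumbed" else ""))
  invisible(x)
}

# Extract tensor j of a set as a crm_tensor.
set_tensor <- function(set, j) {
  new_crm_tensor(array(set$data[, j], dim = set$shape), set$chrom[j],
                 set$anchor[j], set$bin_size, set$margin, set$crumbed)
}
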