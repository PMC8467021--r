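# Q-score: does the model respect every pairwise correlation between
# dimensions (datasets with datasets, regulators with regulators)? For each
# correlated pair, presence of one should raise the rebuilt (and phantom)
# value of the other; for uncorrelated pairs it should not. Lower is better.

# Per-dimension presence and rebuilt means over a tensor sample.
# Dimensions are the m datasets followed by the n regulators.
dim_summaries <- function(set, recon) {
  X <- set$shape[1]; m <- set$shape[2]; n <- set$shape[3]
  src_pres <- block_max_cpp(set$data, X, set$margin) > 0      # (m*n, N)
  src_mean <- block_mean_cpp(recon, X, set$margin)            # (m*n, N)
  N <- ncol(src_pres)
  pres <- matrix(FALSE, m + n, N)
  rebuilt <- matrix(0, m + n, N)
  for (y in seq_len(m)) {
    rows <- (seq_len(n) - 1L) * m + y
    pres[y, ] <- colSums(src_pres[rows, , drop = FALSE]) > 0
    rebuilt[y, ] <- colMeans(src_mean[rows, , drop = FALSE])
  }
  for (z in seq_len(n)) {
    rows <- (z - 1L) * m + seq_len(m)
    pres[m + z, ] <- colSums(src_pres[rows, , drop = FALSE]) > 0
    rebuilt[m + z, ] <- colMeans(src_mean[rows, , drop = FALSE])
  }
  list(presence = pres, rebuilt = rebuilt)
}

# Nucleotide-level presence of each dimension: one binary value per
# (non-margin bin, CRM), any coverage across the orthogonal axis counts.
dim_nucleotide_presence <- function(set) {
  X <- set$shape[1]; m <- set$shape[2]; n <- set$shape[3]
  margin <- set$margin
  N <- ncol(set$data)
  core <- (margin + 1L):(X - margin)
  nc <- length(core)
  out <- vector("list", m + n)
  arr <- set$data
  dim(arr) <- c(X, m, n, N)
  for (y in seq_len(m)) {
    sl <- arr[core, y, 1, ]
    for (z in seq_len(n)[-1]) sl <- pmax(sl, arr[core, y, z, ])
    out[[y]] <- as.vector(sl > 0)
  }
  for (z in seq_len(n)) {
    sl <- arr[core, 1, z, ]
    for (y in seq_len(m)[-1]) sl <- pmax(sl, arr[core, y, z, ])
    out[[m + z]] <- as.vector(sl > 0)
  }
  matrix(unlist(out), nrow = nc * N)
}

#' Pairwise correlation indicators between dimensions
#'
#' Pearson coefficients between the nucleotide-level presence tracks of every
#' same-type dimension pair (dataset-dataset and regulator-regulator),
#' computed across a sample of CRM tensors. Negative coefficients are set
#' aside; the indicator `C` is 1 iff a pair's coefficient exceeds the mean of
#' the retained (positive) coefficients. Pairs with a constant dimension are
#' skipped with a warning.
#'
#' @param set A [tensor_set()] (>= 2 CRMs).
#' @param m,n Dataset and regulator counts (defaults from the set shape).
#' @return List with `pearson` ((m+n) square matrix, NA across types), `C`
#'   (0/1/NA) and `mean_positive`.
#' @export
pairwise_correlation <- function(set, m = set$shape[2], n = set$shape[3]) {
  stopifnot(ncol(set$data) >= 2)
  tracks <- dim_nucleotide_presence(set)
  nd <- m + n
  pear <- matrix(NA_real_, nd, nd)
  same_type <- function(i, j) (i <= m) == (j <= m)
  const <- apply(tracks, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("constant dimension(s) skipped in pairwise correlation: ",
            paste(which(const), collapse = ", "))
  }
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      if (!same_type(i, j) || const[i] || const[j]) next
      pear[i, j] <- pear[j, i] <- stats::cor(tracks[, i], tracks[, j])
    }
  }
  pos <- pear[upper.tri(pear)]
  pos <- pos[!is.na(pos) & pos > 0]
  mu <- if (length(pos)) mean(pos) else NA_real_
  C <- ifelse(is.na(pear), NA, as.numeric(pear > mu))
  list(pearson = pear, C = C, mean_positive = mu)
}

# Welch two-sample p-value robust to zero-variance strata.
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx < 1e-18 && vy < 1e-18) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Q-score of a trained model
#'
#' For every ordered same-type dimension pair (i, j): does the presence of j
#' raise the rebuilt value of i when i is present (`P` term), and does it
#' raise the phantom value of i when i is absent (`R` term)? Each question is
#' answered by a two-sided Welch test at the Bonferroni level
#' `alpha / #(dimensions)` with the additional requirement that the effect be
#' positive. A correlated pair (C = 1) should answer yes to both, an
#' uncorrelated pair no: each mismatch contributes
#' `sqrt(A_i * A_j)` (relative abundances) to Q. Lower is better.
#'
#' @param model Trained `anopeak_model` or reconstructor function.
#' @param set A [tensor_set()] of CRM tensors.
#' @param catalog The [source_catalog()] (for the abundances).
#' @param alpha Base significance level (default 0.05).
#' @param max_crms CRMs sampled for the test (default 10000, or all if fewer).
#' @param seed Sampling seed.
#' @return Object of class `qscore_report`: `Q`, `contributions` matrix,
#'   `pearson`, `C`, `welch_p_present`, `welch_p_phantom`, `n_crms`,
#'   `dim_names`.
#' @export
qscore <- function(model, set, catalog, alpha = 0.05, max_crms = 10000L,
                   seed = 1L) {
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  stopifnot(all(set$shape[2:3] == c(m, n)))
  sm <- sample_set(set, max_crms, seed)
  N <- ncol(sm$data)
  recon <- reconstruct_set(model, sm)
  ds <- dim_summaries(sm, recon)
  pc <- pairwise_correlation(sm, m, n)
  nd <- m + n
  eps <- alpha / nd
  abund <- c(rowSums(catalog$abundance), colSums(catalog$abundance)) /
    sum(catalog$abundance)

  p_pres <- matrix(NA_real_, nd, nd)
  p_phan <- matrix(NA_real_, nd, nd)
  contrib <- matrix(NA_real_, nd, nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i == j || is.na(pc$C[i, j])) next
      Cij <- pc$C[i, j]
      vi <- ds$rebuilt[i, ]
      pi <- ds$presence[i, ]
      pj <- ds$presence[j, ]
      term <- 0
      skipped <- TRUE
      # P: i present — does presence of j raise i's rebuilt value?
      both <- vi[pi & pj]; alone <- vi[pi & !pj]
      pv <- welch_p(both, alone)
      p_pres[i, j] <- pv
      if (!is.na(pv)) {
        sig <- as.numeric(pv < eps && mean(both) > mean(alone))
        term <- term + (Cij - sig)^2
        skipped <- FALSE
      }
      # R: i absent — does presence of j raise i's phantom value?
      phb <- vi[!pi & pj]; phn <- vi[!pi & !pj]
      pv2 <- welch_p(phb, phn)
      p_phan[i, j] <- pv2
      if (!is.na(pv2)) {
        sig2 <- as.numeric(pv2 < eps && mean(phb) > mean(phn))
        term <- term + (Cij - sig2)^2
        skipped <- FALSE
      }
      if (!skipped) contrib[i, j] <- sqrt(abund[i] * abund[j]) * term
    }
  }
  dim_names <- c(catalog$datasets, catalog$regulators)
  dimnames(contrib) <- list(dim_names, dim_names)
  structure(list(Q = sum(contrib, na.rm = TRUE), contributions = contrib,
                 pearson = pc$pearson, C = pc$C,
                 welch_p_present = p_pres, welch_p_phantom = p_phan,
                 alpha = alpha, bonferroni = eps, n_crms = N,
                 dim_names = dim_names, abundance = abund),
            class = "qscore_report")
}

#' @export
print.qscore_report <- function(x, ...) {
  cat(sprintf("qscore_report: Q = %.4f over %d dimensions, %d CRMs (alpha %g, Bonferroni %g)\n",
              x$Q, length(x$dim_names), x$n_crms, x$alpha, x$bonferroni))
  invisible(x)
}

#' Write the Q-score contribution matrix
#'
#' @param report A [qscore()] report.
#' @param path Output TSV path.
#' @return The matrix, invisibly.
#' @export
write_qscore_report <- function(report, path) {
  utils::write.table(report$contributions, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(report$contributions)
}
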