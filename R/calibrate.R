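# Correction of learned-group biases. Each source (dataset, regulator) gets a
# multiplicative weight k = min(k1 * k2 * k3, cap) applied to its raw anomaly
# scores, then scores are standardized per regulator onto the 750-centered
# 0-1000 scale.

# Tensor of one full-length unit peak for a source (the "request" probe U_s).
request_tensor <- function(shape, margin, bin_size, source_yz,
                           crumbed = FALSE, crumb_fraction = 0.1) {
  X <- shape[1]
  vals <- array(0, dim = shape)
  vals[(margin + 1L):(X - margin), source_yz[1], source_yz[2]] <- 1
  tt <- new_crm_tensor(vals, "probe", 0, bin_size, margin, FALSE)
  if (crumbed) tt <- crumb(tt, crumb_fraction)
  tt
}

# "Full CRM" probe F_t: every source with non-zero abundance present along the
# whole non-margin length.
full_tensor <- function(shape, margin, bin_size, abundance,
                        crumbed = FALSE, crumb_fraction = 0.1) {
  X <- shape[1]
  vals <- array(0, dim = shape)
  present <- which(abundance > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(present))) {
    vals[(margin + 1L):(X - margin), present[i, 1], present[i, 2]] <- 1
  }
  tt <- new_crm_tensor(vals, "probe", 0, bin_size, margin, FALSE)
  if (crumbed) tt <- crumb(tt, crumb_fraction)
  tt
}

model_geometry <- function(model, set = NULL) {
  if (inherits(model, "anopeak_model")) {
    list(shape = model$shape,
         margin = if (!is.null(model$margin)) model$margin else
           2L * model$config$kernel_len,
         bin_size = if (!is.null(model$bin_size)) model$bin_size else 10L,
         crumbed = isTRUE(model$crumbed))
  } else {
    stopifnot(!is.null(set))
    list(shape = set$shape, margin = set$margin, bin_size = set$bin_size,
         crumbed = isTRUE(set$crumbed))
  }
}

#' Request mask of a source
#'
#' Reconstructs a probe tensor `U_s` that is empty except for one full-length
#' unit peak for the given source (crumbed iff the training data was), and
#' averages the reconstruction over the non-margin positions. The resulting
#' m x n map `R` shows which phantoms the model adds for this source — its
#' estimated correlation group. The normalized mask is `M = R / max(R)`.
#'
#' @param model A trained `anopeak_model` or reconstructor function.
#' @param source Integer pair (dataset index, regulator index), or a character
#'   pair (dataset name, regulator name) resolved against `catalog`.
#' @param catalog Optional [source_catalog()] for name resolution/dimnames.
#' @param set A [tensor_set()] supplying the geometry when `model` is a bare
#'   function.
#' @return List of class `request_mask`: `R`, `M` (NULL for an unlearned
#'   source), `source`, `unlearned` flag.
#' @export
request_mask <- function(model, source, catalog = NULL, set = NULL) {
  geo <- model_geometry(model, set)
  if (is.character(source)) {
    stopifnot(!is.null(catalog))
    source <- c(match(source[1], catalog$datasets),
                match(source[2], catalog$regulators))
  }
  source <- as.integer(source)
  u <- request_tensor(geo$shape, geo$margin, geo$bin_size, source, geo$crumbed)
  h <- reconstruct(model, u)
  X <- geo$shape[1]
  core <- (geo$margin + 1L):(X - geo$margin)
  R <- apply(h$values[core, , , drop = FALSE], c(2, 3), mean)
  if (!is.null(catalog)) dimnames(R) <- list(catalog$datasets, catalog$regulators)
  own <- R[source[1], source[2]]
  unlearned <- !is.finite(own) || own <= 1e-6 || max(R) <= 0
  structure(list(R = R, M = if (unlearned) NULL else R / max(R),
                 source = source, unlearned = unlearned),
            class = "request_mask")
}

#' Intra-group rebuilding weight k1
#'
#' For each source, the ratio of the summed reconstruction to the summed
#' original is computed on the source's request tensor U_s; its reciprocal is
#' the multiplicative correction, so under-rebuilt sources are boosted. Both
#' the raw ratio and the weight are returned; sources whose probe is not
#' rebuilt at all are flagged unlearned (their k is later forced to the cap).
#'
#' @inheritParams request_mask
#' @param catalog The [source_catalog()].
#' @return List with matrices `raw` (printed-formula ratio sum(h(U))/sum(U)),
#'   `k1` (its reciprocal) and logical `unlearned`.
#' @export
k1_intra <- function(model, catalog, set = NULL) {
  geo <- model_geometry(model, set)
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  raw <- matrix(NA_real_, m, n, dimnames = list(catalog$datasets,
                                                catalog$regulators))
  unlearned <- matrix(FALSE, m, n)
  for (y in seq_len(m)) {
    for (z in seq_len(n)) {
      u <- request_tensor(geo$shape, geo$margin, geo$bin_size, c(y, z),
                          geo$crumbed)
      h <- reconstruct(model, u)
      raw[y, z] <- sum(h$values) / sum(u$values)
    }
  }
  unlearned <- !is.finite(raw) | raw <= 1e-6
  k1 <- 1 / raw
  k1[unlearned] <- Inf
  list(raw = raw, k1 = k1, unlearned = unlearned)
}

# Occupancy of each sampled CRM for one source: sum over sources of
# mask * max_X(T) * IW (all pointwise).
occupancy <- function(mask, iw, maxmat) {
  w <- as.vector(mask) * as.vector(iw)
  as.vector(crossprod(maxmat, w))
}

#' Inter-group completeness weight k2
#'
#' Groups have different sizes and typical completeness; k2 rescales each
#' source so that equal relative group completeness yields equal weighted
#' scores. The occupancy of a CRM for a source is the masked, k1-weighted sum
#' of its per-source presence maxima; a Monte Carlo sample of CRMs gives the
#' average occupancy `mu(theta)` over CRMs where the source is actually
#' present, and `k2 = theta_F / mu(theta)` where `theta_F` is the occupancy of
#' the all-sources-present full CRM.
#'
#' @param model Trained model or reconstructor function.
#' @param set [tensor_set()] of CRM tensors to sample from.
#' @param masks List of [request_mask()] objects, one per source, in
#'   column-major (dataset fastest) order.
#' @param iw Matrix of intra-group weights (k1) used inside the occupancy.
#' @param catalog The [source_catalog()].
#' @param mc_sample_size CRMs sampled (default 10000, or all if fewer).
#' @param seed Sampling seed.
#' @return List with matrix `k2` and logical `never_present`.
#' @export
k2_inter <- function(model, set, masks, iw, catalog, mc_sample_size = 10000L,
                     seed = 1L) {
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  sm <- sample_set(set, mc_sample_size, seed)
  maxmat <- block_max_cpp(sm$data, sm$shape[1], sm$margin)   # (m*n, N)
  f_t <- full_tensor(sm$shape, sm$margin, sm$bin_size, catalog$abundance,
                     sm$crumbed)
  fmax <- as.vector(block_max_cpp(matrix(as.vector(f_t$values), ncol = 1),
                                  sm$shape[1], sm$margin))
  k2 <- matrix(1, m, n, dimnames = list(catalog$datasets, catalog$regulators))
  never <- matrix(FALSE, m, n)
  for (z in seq_len(n)) {
    for (y in seq_len(m)) {
      s_idx <- (z - 1L) * m + y
      mk <- masks[[s_idx]]
      if (is.null(mk$M)) next
      present <- maxmat[s_idx, ] > 0
      if (!any(present)) {
        never[y, z] <- TRUE
        next
      }
      occ <- occupancy(mk$M, iw, maxmat[, present, drop = FALSE])
      mu_theta <- mean(occ)
      theta_f <- sum(as.vector(mk$M) * as.vector(iw) * fmax)
      if (is.finite(mu_theta) && mu_theta > 0) k2[y, z] <- theta_f / mu_theta
    }
  }
  list(k2 = k2, never_present = never)
}

#' Overlapping-group weight k3
#'
#' Sources belonging to several learned groups accumulate phantoms from all of
#' them. A negative mask `M_n = (F - R/R[s]) * F[s]` isolates the correlators
#' outside the source's own request; negative occupancies `eta` are computed
#' exactly like the occupancies of [k2_inter()] but with `M_n`, and
#' `k3 = 1 - (h(F)[s]/F[s]) * (mu(eta)/eta_F)`.
#'
#' @inheritParams k2_inter
#' @return List with matrix `k3`.
#' @export
k3_overlap <- function(model, set, masks, iw, catalog, mc_sample_size = 10000L,
                       seed = 1L) {
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  sm <- sample_set(set, mc_sample_size, seed)
  X <- sm$shape[1]
  maxmat <- block_max_cpp(sm$data, X, sm$margin)
  f_t <- full_tensor(sm$shape, sm$margin, sm$bin_size, catalog$abundance,
                     sm$crumbed)
  fmax <- as.vector(block_max_cpp(matrix(as.vector(f_t$values), ncol = 1),
                                  X, sm$margin))
  Fmap <- matrix(as.vector(block_mean_cpp(matrix(as.vector(f_t$values),
                                                 ncol = 1), X, sm$margin)),
                 m, n)
  hf <- reconstruct(model, f_t)
  hFmap <- matrix(as.vector(block_mean_cpp(matrix(as.vector(hf$values),
                                                  ncol = 1), X, sm$margin)),
                  m, n)
  k3 <- matrix(1, m, n, dimnames = list(catalog$datasets, catalog$regulators))
  for (z in seq_len(n)) {
    for (y in seq_len(m)) {
      s_idx <- (z - 1L) * m + y
      mk <- masks[[s_idx]]
      if (is.null(mk$M)) next
      r_s <- mk$R[y, z]
      f_s <- Fmap[y, z]
      if (!is.finite(r_s) || r_s <= 0 || f_s <= 0) next
      m_n <- (Fmap - mk$R / r_s) * f_s
      present <- maxmat[s_idx, ] > 0
      if (!any(present)) next
      eta <- occupancy(m_n, iw, maxmat[, present, drop = FALSE])
      eta_f <- sum(as.vector(m_n) * as.vector(iw) * fmax)
      if (abs(eta_f) < 1e-9) next
      k3[y, z] <- 1 - (hFmap[y, z] / f_s) * (mean(eta) / eta_f)
    }
  }
  list(k3 = k3)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic subsample of a tensor_set
sample_set <- function(set, size, seed) {
  N <- ncol(set$data)
  if (N <= size) return(set)
  idx <- with_seed(seed, sample.int(N, size))
  set$data <- set$data[, idx, drop = FALSE]
  set$chrom <- set$chrom[idx]
  set$anchor <- set$anchor[idx]
  set
}

#' Compute the full per-source normalization weights
#'
#' Runs [k1_intra()], [k2_inter()] and [k3_overlap()], combines them as
#' `k = k1 * k2 * k3`, caps every weight at `cap` (preventing overcorrection
#' of sources the model never learned) and floors it at `k_floor` so the
#' weight stays positive. Sources with zero abundance are excluded (k = NA).
#'
#' @inheritParams k2_inter
#' @param cap Upper bound on the combined weight (default 10).
#' @param k_floor Numerical lower bound keeping k positive.
#' @return Object of class `normalization_weights`: matrices `k1`, `k2`, `k3`,
#'   `k`, `raw_ratio`, logical matrices `unlearned`/`capped`/`floored`, the
#'   request `masks`, and the parameters used.
#' @export
normalization_weights <- function(model, set, catalog, cap = 10,
                                  mc_sample_size = 10000L, seed = 1L,
                                  k_floor = 0.01) {
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  masks <- vector("list", m * n)
  for (z in seq_len(n)) {
    for (y in seq_len(m)) {
      masks[[(z - 1L) * m + y]] <- request_mask(model, c(y, z), catalog, set)
    }
  }
  r1 <- k1_intra(model, catalog, set)
  iw <- r1$k1
  iw[!is.finite(iw)] <- cap
  iw <- pmin(iw, cap)
  r2 <- k2_inter(model, set, masks, iw, catalog, mc_sample_size, seed)
  r3 <- k3_overlap(model, set, masks, iw, catalog, mc_sample_size, seed)
  k <- r1$k1 * r2$k2 * r3$k3
  k[r1$unlearned] <- cap
  capped <- is.finite(k) & (k > cap)
  k <- pmin(k, cap)
  floored <- is.finite(k) & (k < k_floor)
  k <- pmax(k, k_floor)
  k[catalog$abundance == 0] <- NA_real_
  structure(list(k1 = r1$k1, k2 = r2$k2, k3 = r3$k3, k = k,
                 raw_ratio = r1$raw, unlearned = r1$unlearned,
                 capped = capped | r1$unlearned, floored = floored,
                 masks = masks, cap = cap, k_floor = k_floor,
                 mc_sample_size = mc_sample_size, seed = seed),
            class = "normalization_weights")
}

#' @export
print.normalization_weights <- function(x, ...) {
  cat(sprintf("normalization_weights: %d sources, cap %g, %d capped, %d unlearned\n",
              sum(!is.na(x$k)), x$cap, sum(x$capped, na.rm = TRUE),
              sum(x$unlearned, na.rm = TRUE)))
  invisible(x)
}

#' Write the per-source weights report
#'
#' @param weights A [normalization_weights()] object.
#' @param catalog The [source_catalog()].
#' @param path Output TSV path.
#' @return The report data.frame, invisibly.
#' @export
write_weights_report <- function(weights, catalog, path) {
  grid <- expand.grid(dataset = catalog$datasets,
                      regulator = catalog$regulators,
                      stringsAsFactors = FALSE)
  rep <- cbind(grid,
               k1 = as.vector(weights$k1), k2 = as.vector(weights$k2),
               k3 = as.vector(weights$k3), k = as.vector(weights$k),
               capped = as.vector(weights$capped),
               unlearned = as.vector(weights$unlearned))
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Apply the per-source weights to raw scores
#'
#' @param scores Data.frame with `dataset`, `regulator` and `raw` columns.
#' @param weights A [normalization_weights()] object (or a bare k matrix).
#' @param catalog The [source_catalog()].
#' @return `scores` with a `weighted` column (`raw * k[source]`).
#' @export
apply_weights <- function(scores, weights, catalog) {
  k <- if (inherits(weights, "normalization_weights")) weights$k else weights
  y <- match(scores$dataset, catalog$datasets)
  z <- match(scores$regulator, catalog$regulators)
  if (anyNA(y) || anyNA(z)) stop("score source not in catalog")
  kv <- k[cbind(y, z)]
  if (anyNA(kv)) stop("missing normalization weight for a scored source")
  scores$weighted <- scores$raw * kv
  scores
}

#' Per-regulator standardization onto the 750-centered scale
#'
#' Under the assumption that no regulator is inherently better than another,
#' weighted scores are centered and scaled per regulator:
#' `s_f = 750 * (1 + (s - mu_TR) / (2 * sigma_TR))`, so a peak in the average
#' configuration for its regulator scores 750/1000, mu - 2 sigma maps to 0 and
#' mu + 2 sigma to 1500 (clamped to 1000 only when writing BED output).
#'
#' @param scores Data.frame with `regulator` and `weighted` columns.
#' @param center Center of the output scale (750).
#' @return `scores` with a `final` column; per-regulator mu/sigma are attached
#'   as the "tr_stats" attribute. Regulators with zero spread (or a single
#'   peak) get a flat `center` with a warning.
#' @export
standardize_by_tr <- function(scores, center = 750) {
  mu <- tapply(scores$weighted, scores$regulator, mean)
  sg <- tapply(scores$weighted, scores$regulator, stats::sd)
  flat <- is.na(sg) | sg == 0
  if (any(flat)) {
    warning("zero score spread for regulator(s) ",
            paste(names(sg)[flat], collapse = ", "),
            "; their peaks all get ", center)
  }
  muv <- mu[scores$regulator]
  sgv <- sg[scores$regulator]
  final <- center * (1 + (scores$weighted - muv) / (2 * sgv))
  final[flat[scores$regulator]] <- center
  scores$final <- as.vector(final)
  attr(scores, "tr_stats") <- data.frame(regulator = names(mu),
                                         mu = as.vector(mu),
                                         sigma = as.vector(sg))
  scores
}
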