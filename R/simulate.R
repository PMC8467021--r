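# Artificial CRM generator: known correlation groups, a ubiquitous watermark
# control peak, and uniform noise. This is both the validation substrate for
# the model and the package's fixture generator.

#' Configuration of the artificial-CRM generator
#'
#' Defaults are the reference simulation conditions: 8 datasets x 8 regulators,
#' regulators split into two equiprobable correlation groups, the last half of
#' the datasets "reliable" (eligible for the stack), a full-length watermark
#' control peak with probability 0.75 for dataset 1 / regulator 1, stack-peak
#' false-negative removal probability 0.25, stack jitter uniform on +/-200 bp,
#' log-normal peak lengths of median 250 bp and log-scale shape 0.25, 3200 bp
#' regions, and Poisson(1) for every count variable.
#'
#' @param m,n Number of datasets (Y axis) and regulators (Z axis).
#' @param groups List of integer vectors partitioning (or covering) the
#'   regulator indices; the stack of each CRM is drawn from one group.
#'   Default: the regulators split in two halves.
#' @param group_probs Group selection probabilities (default equal).
#' @param reliable Dataset indices eligible for stack placement; default the
#'   ceiling(m/2) highest indices ("last half").
#' @param watermark_prob Probability the watermark peak is present.
#' @param removal_prob Probability `t` that each stack peak is removed
#'   (false-negative simulation).
#' @param jitter_bound Half-width of the uniform per-peak center jitter, bp.
#' @param length_median Median of the log-normal peak length distribution, bp.
#' @param length_shape Log-scale standard deviation of peak lengths.
#' @param region_bp Region length in bp.
#' @param lambda Mean of the Poisson variables governing the number of extra
#'   datasets (K), peak slots (N), regulator draws per slot (P) and noise
#'   peaks (F); each count used is the draw + 1.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(m = 8L, n = 8L,
                             groups = split_groups(n, 2L),
                             group_probs = NULL,
                             reliable = NULL,
                             watermark_prob = 0.75, removal_prob = 0.25,
                             jitter_bound = 200, length_median = 250,
                             length_shape = 0.25, region_bp = 3200L,
                             lambda = 1) {
  m <- as.integer(m); n <- as.integer(n)
  if (is.null(reliable)) reliable <- (m - ceiling(m / 2) + 1L):m
  if (is.null(group_probs)) group_probs <- rep(1 / length(groups), length(groups))
  cfg <- list(m = m, n = n, groups = lapply(groups, as.integer),
              group_probs = group_probs, reliable = as.integer(reliable),
              watermark_prob = watermark_prob, removal_prob = removal_prob,
              jitter_bound = jitter_bound, length_median = length_median,
              length_shape = length_shape, region_bp = as.integer(region_bp),
              lambda = lambda)
  if (any(vapply(cfg$groups, length, 1L) == 0)) {
    stop("every correlation group must contain at least one regulator")
  }
  stopifnot(length(cfg$group_probs) == length(cfg$groups),
            abs(sum(cfg$group_probs) - 1) < 1e-8,
            cfg$removal_prob >= 0, cfg$removal_prob <= 1,
            cfg$watermark_prob >= 0, cfg$watermark_prob <= 1,
            all(cfg$reliable >= 1), all(cfg$reliable <= m),
            all(unlist(cfg$groups) >= 1), all(unlist(cfg$groups) <= n))
  class(cfg) <- "generator_config"
  cfg
}

#' Standard regulator group partitions
#'
#' `split_groups(n, g)` splits regulators 1..n into `g` equal consecutive
#' blocks ("halves" for g = 2); `quarter_groups(n)` makes groups of 4;
#' `overlapping_groups(n)` returns the overlapping scheme G1 vs G1+G2 (the
#' second group contains all regulators).
#'
#' @param n Number of regulators.
#' @param g Number of groups.
#' @return A list of integer vectors.
#' @export
split_groups <- function(n, g = 2L) {
  unname(split(seq_len(n), cut(seq_len(n), g, labels = FALSE)))
}

#' @rdname split_groups
#' @export
quarter_groups <- function(n) split_groups(n, max(1L, n %/% 4L))

#' @rdname split_groups
#' @export
overlapping_groups <- function(n) {
  list(seq_len(ceiling(n / 2)), seq_len(n))
}

# uniform sample that is safe for length-1 vectors
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Draw peak lengths from the generator's length distribution
#'
#' Log-normal with location `log(length_median)` (so the stated median is the
#' distribution median) and shape `length_shape` on the log scale.
#'
#' @param count Number of lengths to draw.
#' @param config A [generator_config()].
#' @return Numeric vector of lengths in bp.
#' @export
draw_peak_length <- function(count, config = generator_config()) {
  stats::rlnorm(count, meanlog = log(config$length_median),
                sdlog = config$length_shape)
}

#' Generate one artificial CRM
#'
#' Three steps, using the current RNG state: (1) with probability
#' `watermark_prob`, a full-length watermark peak for dataset 1 / regulator 1;
#' (2) a stack of correlating peaks: one group is drawn, a common center is
#' placed uniformly, K+1 reliable datasets are drawn without replacement
#' (clipped to the reliable-set size), N+1 peak slots are created, each slot
#' draws P+1 regulators with replacement from the group, and each drawn
#' regulator receives a jittered, log-normal-length peak written identically
#' into all K+1 selected datasets; every stack peak is then removed with
#' probability `removal_prob`; (3) F+1 noise peaks with uniformly random
#' source and position — never the watermark source — are added. Peaks are
#' clipped (not rejected) at the region borders.
#'
#' @param config A [generator_config()].
#' @return A list of class `artificial_crm`: `peaks` (data.frame with `start`,
#'   `end`, `dataset`, `regulator`, `role`), `group` (chosen group index),
#'   `removed` (stack peaks deleted by the false-negative step), `draws` (raw
#'   Poisson draws K, N, P..., F for auditing) and `jitters` (all center
#'   displacements drawn).
#' @export
generate_crm <- function(config = generator_config()) {
  cfg <- config
  reg <- cfg$region_bp
  ps <- pe <- jitters <- numeric(0)
  py <- pz <- integer(0)
  prole <- character(0)

  # step 1: watermark
  if (stats::runif(1) < cfg$watermark_prob) {
    ps <- 0; pe <- reg; py <- 1L; pz <- 1L; prole <- "watermark"
  }

  # step 2: stack of correlating peaks
  g <- if (length(cfg$groups) == 1L) 1L else
    sample.int(length(cfg$groups), 1L, prob = cfg$group_probs)
  center <- stats::runif(1, 0, reg)
  K <- stats::rpois(1, cfg$lambda)
  nds <- min(K + 1L, length(cfg$reliable))
  ds <- resample(cfg$reliable, nds)
  N <- stats::rpois(1, cfg$lambda)
  Ps <- integer(N + 1L)
  ss <- se <- numeric(0)
  sz <- integer(0)
  for (slot in seq_len(N + 1L)) {
    P <- stats::rpois(1, cfg$lambda)
    Ps[slot] <- P
    trs <- resample(cfg$groups[[g]], P + 1L, replace = TRUE)
    jd <- stats::runif(P + 1L, -cfg$jitter_bound, cfg$jitter_bound)
    jitters <- c(jitters, jd)
    L <- draw_peak_length(P + 1L, cfg)
    s <- pmax(0, center + jd - L / 2)
    e <- pmin(reg, center + jd + L / 2)
    keep <- e > s
    ss <- c(ss, s[keep]); se <- c(se, e[keep]); sz <- c(sz, trs[keep])
  }
  # the same interval is written identically into every selected dataset
  n_int <- length(ss)
  stack <- data.frame(start = rep(ss, each = nds), end = rep(se, each = nds),
                      dataset = rep(ds, times = n_int),
                      regulator = rep(sz, each = nds),
                      role = if (n_int) "stack" else character(0))
  drop <- stats::runif(nrow(stack)) < cfg$removal_prob
  removed <- stack[drop, , drop = FALSE]
  stack <- stack[!drop, , drop = FALSE]

  # step 3: uniform noise, never in the watermark source
  Fdraw <- stats::rpois(1, cfg$lambda)
  for (i in seq_len(Fdraw + 1L)) {
    repeat {
      y <- sample.int(cfg$m, 1L)
      z <- sample.int(cfg$n, 1L)
      if (!(y == 1L && z == 1L)) break
    }
    pos <- stats::runif(1, 0, reg)
    L <- draw_peak_length(1L, cfg)
    s <- max(0, pos - L / 2)
    e <- min(reg, pos + L / 2)
    if (e > s) {
      ps <- c(ps, s); pe <- c(pe, e); py <- c(py, y); pz <- c(pz, z)
      prole <- c(prole, "noise")
    }
  }

  peaks <- rbind(data.frame(start = ps, end = pe, dataset = py,
                            regulator = pz, role = prole), stack)
  # watermark first, then stack, then noise (stable, readable ledgers)
  peaks <- peaks[order(match(peaks$role, c("watermark", "stack", "noise"))), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, group = g, removed = removed,
                 draws = list(K = K, N = N, P = Ps, F = Fdraw),
                 jitters = jitters),
            class = "artificial_crm")
}

#' Generate a batch of artificial CRMs
#'
#' Reproducible under a fixed seed; optionally runs every CRM through the
#' tensor pipeline (no crumbing: artificial data is dense enough).
#'
#' @param config A [generator_config()].
#' @param count Number of CRMs.
#' @param seed Integer seed.
#' @param tensors Also build the model-ready [tensor_set()] (default TRUE).
#' @param squish_factor,kernel_len Tensor pipeline parameters.
#' @return A list of class `artificial_batch`: `crms` (list of
#'   `artificial_crm`), `catalog` (the synthetic [source_catalog()]) and, when
#'   requested, `tensors`.
#' @export
generate_batch <- function(config = generator_config(), count, seed = 1L,
                           tensors = TRUE, squish_factor = 10L,
                           kernel_len = 20L) {
  stopifnot(count > 0)
  set.seed(seed)
  crms <- lapply(seq_len(count), function(i) generate_crm(config))
  catalog <- artificial_catalog(config, crms)
  out <- list(crms = crms, catalog = catalog, config = config, seed = seed)
  if (tensors) {
    out$tensors <- tensorize_crms(crms, config, catalog,
                                  squish_factor = squish_factor,
                                  kernel_len = kernel_len)
  }
  class(out) <- "artificial_batch"
  out
}

# synthetic dataset / regulator names in the ReMap dialect
synthetic_dataset_names <- function(m) sprintf("DS%02d", seq_len(m))
synthetic_regulator_names <- function(n) sprintf("TR%02d", seq_len(n))

#' Source catalog for artificial data
#'
#' @param config A [generator_config()].
#' @param crms Optional list of generated CRMs used to fill per-source
#'   abundances (otherwise abundances are zero).
#' @return A [source_catalog()] with synthetic dataset/regulator names.
#' @export
artificial_catalog <- function(config, crms = NULL) {
  ds <- synthetic_dataset_names(config$m)
  tr <- synthetic_regulator_names(config$n)
  ab <- matrix(0L, config$m, config$n, dimnames = list(ds, tr))
  if (!is.null(crms)) {
    pk <- artificial_peaks(crms)
    if (nrow(pk) > 0) {
      tb <- table(factor(pk$dataset, levels = seq_len(config$m)),
                  factor(pk$regulator, levels = seq_len(config$n)))
      ab <- matrix(as.integer(tb), config$m, config$n,
                   dimnames = list(ds, tr))
    }
  }
  new_source_catalog(ds, tr, ab)
}

#' Flatten generated CRMs into one peak table
#'
#' @param crms List of `artificial_crm` (or an `artificial_batch`).
#' @return data.frame with `crm_id`, `start`, `end`, `dataset`, `regulator`,
#'   `role`, `group`.
#' @export
artificial_peaks <- function(crms) {
  if (inherits(crms, "artificial_batch")) crms <- crms$crms
  out <- lapply(seq_along(crms), function(i) {
    p <- crms[[i]]$peaks
    if (nrow(p) == 0) return(NULL)
    cbind(crm_id = i, p, group = crms[[i]]$group)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(crm_id = integer(0), start = numeric(0), end = numeric(0),
                      dataset = integer(0), regulator = integer(0),
                      role = character(0), group = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Tensorize artificial CRMs through the standard pipeline
#'
#' @param crms List of `artificial_crm`.
#' @param config The [generator_config()] they came from.
#' @param catalog Optional catalog (defaults to the synthetic one).
#' @param squish_factor,kernel_len Tensor pipeline parameters.
#' @return A [tensor_set()], one window per CRM (regions fit in one window).
#' @export
tensorize_crms <- function(crms, config, catalog = NULL, squish_factor = 10L,
                           kernel_len = 20L) {
  if (is.null(catalog)) catalog <- artificial_catalog(config)
  ds <- catalog$datasets
  tr <- catalog$regulators
  tens <- lapply(crms, function(crm) {
    p <- crm$peaks
    pk <- data.frame(start = p$start, end = p$end,
                     dataset = ds[p$dataset], regulator = tr[p$regulator])
    region <- data.frame(chrom = "chrSIM", start = 0L, end = config$region_bp)
    prepare_tensors(region, pk, catalog, window_bp = config$region_bp,
                    squish_factor = squish_factor, kernel_len = kernel_len,
                    crumb_enabled = FALSE)[[1]]
  })
  tensor_set(tens)
}

#' Write the role ledger of a generated batch
#'
#' Tab-separated table (crm_id, start, end, dataset, regulator, role, group)
#' used to audit the generator and to stratify scores by peak type.
#'
#' @param crms List of `artificial_crm` or an `artificial_batch`.
#' @param path Output TSV path.
#' @return The ledger data.frame, invisibly.
#' @export
export_roles <- function(crms, path) {
  led <- artificial_peaks(crms)
  utils::write.table(led, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(led)
}

#' Export a generated batch as a ReMap-dialect BED peak table
#'
#' Peaks get synthetic names `DSxx.TRyy.SIM` and consecutive per-CRM regions on
#' a synthetic chromosome, so the artificial data can exercise the BED reading
#' and scoring plumbing end to end.
#'
#' @param batch An `artificial_batch`.
#' @param chrom Chromosome name used for all regions.
#' @return List with `peaks` (ReMap-dialect peak data.frame) and `regions`
#'   (CRM BED3+1 data.frame).
#' @export
as_remap_peaks <- function(batch, chrom = "chrSIM") {
  stopifnot(inherits(batch, "artificial_batch"))
  cfg <- batch$config
  pk <- artificial_peaks(batch)
  offset <- (pk$crm_id - 1) * cfg$region_bp
  ds <- synthetic_dataset_names(cfg$m)[pk$dataset]
  tr <- synthetic_regulator_names(cfg$n)[pk$regulator]
  peaks <- data.frame(chrom = chrom,
                      start = as.integer(floor(pk$start + offset)),
                      end = as.integer(ceiling(pk$end + offset)),
                      name = paste(ds, tr, "SIM", sep = "."),
                      dataset = ds, regulator = tr, cell_line = "SIM",
                      strand = ".",
                      line_index = seq_len(nrow(pk)))
  n_crm <- length(batch$crms)
  regions <- data.frame(chrom = chrom,
                        start = (seq_len(n_crm) - 1L) * cfg$region_bp,
                        end = seq_len(n_crm) * cfg$region_bp,
                        crm_id = seq_len(n_crm))
  list(peaks = peaks, regions = regions)
}
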