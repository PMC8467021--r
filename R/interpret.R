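# Model introspection: gradient-ascent ur-examples for the encoded latent
# units, and phantom-based correlation-group estimation via request masks.

# separable truncated-Gaussian blur along the three tensor axes
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w / sum(w)
}

blur_axis <- function(v, axis, kern) {
  if (length(kern) == 1) return(v)
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(v, perm)
  da <- dim(a)
  mat <- matrix(a, da[1], da[2] * da[3])
  r <- (length(kern) - 1L) %/% 2L
  out <- matrix(0, da[1], ncol(mat))
  for (i in seq_along(kern)) {
    off <- i - r - 1L
    src <- pmin(pmax(seq_len(da[1]) + off, 1L), da[1])  # replicate borders
    out <- out + kern[i] * mat[src, , drop = FALSE]
  }
  dim(out) <- da
  aperm(out, order(perm))
}

blur_tensor <- function(v, sigma) {
  v <- blur_axis(v, 1, gaussian_kernel(sigma[1]))
  v <- blur_axis(v, 2, gaussian_kernel(sigma[2]))
  v <- blur_axis(v, 3, gaussian_kernel(sigma[3]))
  v
}

#' Gradient-ascent ur-examples of the encoded units
#'
#' For each latent unit of the encoded layer, synthesizes the input tensor
#' that maximally activates it (mean activation across the position axis) by
#' gradient ascent from small uniform noise, with a Gaussian blur along the
#' (position, dataset, regulator) axes applied at regular intervals for more
#' natural-looking results. Units whose gradient is identically zero are
#' flagged dead ("some dimensions are never used"). Ascent directions are
#' RMS-normalized gradients. The model weights are never modified.
#'
#' @param model A trained `anopeak_model`.
#' @param steps Gradient-ascent steps (default 50).
#' @param step_size Ascent learning rate (default 1).
#' @param blur_sigma Blur standard deviations (sigma_x, sigma_y, sigma_z),
#'   default c(0.2, 1e-2, 1e-2).
#' @param blur_every Apply the blur every this many steps (default 5).
#' @param units Latent units to analyse (default all).
#' @param seed Seed for the uniform [0, 0.1] initialization.
#' @return List of class `ur_examples`; per unit: `unit`, `tensor` (3D array),
#'   `map` (mean over non-margin positions, m x n, negatives present), `map_pos`
#'   (negatives clipped to zero), `activation`, `dead`.
#' @export
ur_examples <- function(model, steps = 50L, step_size = 1,
                        blur_sigma = c(0.2, 1e-2, 1e-2), blur_every = 5L,
                        units = NULL, seed = 1L) {
  stopifnot(inherits(model, "anopeak_model"))
  if (!model$trained) stop("ur-examples need a trained model")
  shape <- model$shape
  X <- shape[1]
  E <- model$config$encoded_dim
  if (is.null(units)) units <- seq_len(E)
  margin <- if (!is.null(model$margin)) model$margin else
    2L * model$config$kernel_len
  core <- (margin + 1L):(X - margin)
  out <- with_seed(seed, lapply(units, function(i) {
    v <- array(stats::runif(prod(shape), 0, 0.1), dim = shape)
    denc <- matrix(0, E, X)
    denc[i, ] <- 1 / X
    dead <- FALSE
    for (s in seq_len(steps)) {
      xb <- matrix(as.vector(v), ncol = 1)
      gr <- nn_input_grad(model$params, xb, shape, model$config, denc)
      g <- array(gr$grad, dim = shape)
      rms <- sqrt(mean(g^2))
      if (rms == 0) {
        dead <- TRUE
        break
      }
      v <- v + step_size * g / rms
      if (s %% blur_every == 0) v <- blur_tensor(v, blur_sigma)
    }
    act <- mean(encode(model, v)[i, ])
    map <- apply(v[core, , , drop = FALSE], c(2, 3), mean)
    list(unit = i, tensor = v, map = map, map_pos = pmax(map, 0),
         activation = act, dead = dead)
  }))
  structure(out, class = "ur_examples")
}

#' Mean encoded activation of one latent unit on a tensor
#'
#' @param model A trained `anopeak_model`.
#' @param tensor A [crm_tensor] or 3D array.
#' @param unit Latent unit index.
#' @return Scalar mean activation across positions.
#' @export
unit_activation <- function(model, tensor, unit) {
  mean(encode(model, tensor)[unit, ])
}

#' Estimate the correlation groups of every source
#'
#' For each source, reconstructs the request probe `U_s` (one full-length peak
#' for the source) and ranks all other sources by their phantom strength in
#' the rebuilt map `R`. Sources whose phantom value exceeds
#' `threshold * R[s]` are reported as estimated same-group correlators. When
#' the model was trained on crumbed data the "+"-shaped crumb pattern is
#' annotated rather than interpreted. Overlap can be asymmetric (a source A
#' may boost B without B appearing in A's estimate), so all sources are
#' reported.
#'
#' @param model Trained `anopeak_model` or reconstructor function.
#' @param catalog The [source_catalog()].
#' @param threshold Phantom strength relative to the probed source's own
#'   rebuilt value required for group membership (default 0.25).
#' @param set A [tensor_set()] supplying geometry when `model` is a function.
#' @return List of class `group_estimates`; per source: `dataset`,
#'   `regulator`, `own` (rebuilt value of the probed source), `correlators`
#'   (data.frame ranked by phantom strength, negatives clipped in `value`,
#'   raw values kept in `value_raw`), `unlearned`, `crumb_pattern`.
#' @export
estimate_groups <- function(model, catalog, threshold = 0.25, set = NULL) {
  m <- length(catalog$datasets); n <- length(catalog$regulators)
  crumbed <- if (inherits(model, "anopeak_model")) isTRUE(model$crumbed) else
    isTRUE(set$crumbed)
  out <- vector("list", m * n)
  for (z in seq_len(n)) {
    for (y in seq_len(m)) {
      mk <- request_mask(model, c(y, z), catalog, set)
      own <- mk$R[y, z]
      grid <- expand.grid(dataset = catalog$datasets,
                          regulator = catalog$regulators,
                          stringsAsFactors = FALSE)
      vals <- as.vector(mk$R)
      self <- (z - 1L) * m + y
      cor_df <- grid[-self, , drop = FALSE]
      raw <- vals[-self]
      cor_df$value_raw <- raw
      cor_df$value <- pmax(raw, 0)
      cor_df$member <- !mk$unlearned & cor_df$value >= threshold * max(own, 0)
      cor_df <- cor_df[order(-cor_df$value), , drop = FALSE]
      out[[self]] <- list(dataset = catalog$datasets[y],
                          regulator = catalog$regulators[z],
                          own = own, correlators = cor_df,
                          unlearned = mk$unlearned,
                          crumb_pattern = crumbed)
    }
  }
  structure(out, class = "group_estimates")
}

#' Write group estimates as a TSV
#'
#' @param estimates A [estimate_groups()] result.
#' @param path Output path.
#' @return The flat table, invisibly.
#' @export
write_group_estimates <- function(estimates, path) {
  rows <- lapply(estimates, function(e) {
    mem <- e$correlators[e$correlators$member, , drop = FALSE]
    data.frame(dataset = e$dataset, regulator = e$regulator, own = e$own,
               unlearned = e$unlearned,
               members = paste(paste0(mem$dataset, ".", mem$regulator),
                               collapse = ","))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
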