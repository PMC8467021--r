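# Shared fixtures, built once per test run and memoised. Training the
# autoencoder is by far the most expensive step, so the trained models are
# shared across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  hit <- .fx[[name]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fx[[name]] <- val
  val
}

# Default 2-group 8x8 artificial data, 3000 CRMs.
fixture_batch <- function() {
  memo("batch", generate_batch(generator_config(), 3000, seed = 11,
                               tensors = TRUE))
}

# The default artificial-profile model trained on the fixture batch
# (deep dimension 32, 16 filters, learning rate 1e-3, early stopping; capped
# at 30 epochs — group structure is stable well before that).
fixture_model <- function() {
  memo("model", {
    set <- fixture_batch()$tensors
    cfg <- artificial_profile(seed = 1, max_epochs = 26L)
    train_model(build_model(cfg, set$shape), set)
  })
}

# Reconstructions of a column subset of the fixture tensors (not memoised:
# the full matrix is too large to keep around).
fixture_recon_cols <- function(cols) {
  set <- fixture_batch()$tensors
  sub <- set
  sub$data <- set$data[, cols, drop = FALSE]
  sub$chrom <- set$chrom[cols]
  sub$anchor <- set$anchor[cols]
  list(set = sub, recon = reconstruct_set(fixture_model(), sub))
}

# Raw anomaly scores of every artificial peak under the fixture model,
# annotated with generator roles.
fixture_scores <- function() {
  memo("scores", {
    batch <- fixture_batch()
    set <- batch$tensors
    catalog <- batch$catalog
    recon <- reconstruct_set(fixture_model(), set)
    pk <- artificial_peaks(batch)
    pk$dataset_name <- catalog$datasets[pk$dataset]
    pk$regulator_name <- catalog$regulators[pk$regulator]
    pk2 <- data.frame(start = pk$start, end = pk$end,
                      dataset = pk$dataset_name,
                      regulator = pk$regulator_name)
    pk$raw <- anopeak:::score_peaks_set(set, recon, pk2, pk$crm_id, catalog)
    pk$reliable <- pk$dataset %in% generator_config()$reliable
    pk
  })
}

# Smaller-budget models for the Q-score ordering and seed-averaging checks:
# same fixture data, 10 epochs, three seeds per deep dimension.
fixture_q_models <- function(deep_dim, seed) {
  memo(paste0("qmodel_", deep_dim, "_", seed), {
    set <- fixture_batch()$tensors
    cfg <- artificial_profile(deep_dim = as.integer(deep_dim),
                              encoded_dim = as.integer(deep_dim),
                              max_epochs = 10L, seed = seed)
    train_model(build_model(cfg, set$shape), set)
  })
}

# Tiny single-source training set and model for the interpretability checks:
# every CRM holds one peak for source (1, 1) at a random position.
fixture_one_source <- function() {
  memo("one_source", {
    set.seed(5)
    catalog <- anopeak:::new_source_catalog(
      c("DS01", "DS02"), c("TR01", "TR02"),
      matrix(c(200L, 0L, 0L, 0L), 2, 2))
    region <- data.frame(chrom = "chrT", start = 0L, end = 400L)
    tens <- lapply(seq_len(200), function(i) {
      ctr <- runif(1, 50, 350)
      pk <- data.frame(start = max(0, ctr - 60), end = min(400, ctr + 60),
                       dataset = "DS01", regulator = "TR01")
      prepare_tensors(region, pk, catalog, window_bp = 400L,
                      squish_factor = 10L, kernel_len = 5L)[[1]]
    })
    set <- tensor_set(tens)
    cfg <- model_config(kernel_len = 5L, conv_filters = 4L, deep_dim = 8L,
                        encoded_dim = 4L, learning_rate = 1e-3,
                        batch_size = 24L, batches_per_epoch = 8L,
                        max_epochs = 30L, seed = 2)
    model <- train_model(build_model(cfg, set$shape), set)
    list(model = model, set = set, catalog = catalog)
  })
}

# Oracle reconstructor emitting pure group-completeness values: for each
# regulator group, every (reliable dataset, group regulator) cell gets the
# fraction of such cells with a peak present, along the whole core span.
# Used as the independent reference for the Q-score.
oracle_reconstructor <- function(gcfg, margin) {
  force(gcfg); force(margin)
  function(vals) {
    d <- dim(vals)
    X <- d[1]
    core <- (margin + 1):(X - margin)
    out <- array(0, dim = d)
    pres <- apply(vals[core, , , drop = FALSE], c(2, 3), max) > 0
    for (g in seq_along(gcfg$groups)) {
      zs <- gcfg$groups[[g]]
      ys <- gcfg$reliable
      comp <- mean(pres[ys, zs])
      for (z in zs) for (y in ys) out[core, y, z] <- comp
    }
    out
  }
}

expect_sorted_desc <- function(...) {
  v <- c(...)
  expect_true(all(diff(v) < 0))
}
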