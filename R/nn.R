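# Internal neural-network engine for the stacked multiview convolutional
# autoencoder. All activations use a channel-first layout (channels x
# positions) so the compiled shifted-window convolutions in src/conv.cpp can
# run one BLAS gemm per kernel offset without reshuffling memory.
#
# Encoder:  conv over (X window k, all m datasets) depthwise per regulator
#        -> conv over (X window k, all n regulators x stage-1 filters)
#        -> 4 position-wise Dense layers (ReLU, dropout on all but the last)
# Decoder:  conv reading the whole encoded width -> conv with one filter per
#           (dataset, regulator) source, reshaped back to (X, m, n).

# Column indices of the X core positions inside the padded (X + k - 1 per
# group block) layout used by the convolutions. Memoised: training asks for
# the same few shapes thousands of times.
.idx_cache <- new.env(parent = emptyenv())
nn_core_idx <- function(X, G, k) {
  key <- paste(X, G, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  padl <- (k - 1L) %/% 2L
  Xp <- X + k - 1L
  idx <- as.vector(outer(padl + seq_len(X), (seq_len(G) - 1L) * Xp, "+"))
  .idx_cache[[key]] <- idx
  idx
}

# zero-pad each group block of X columns to X + k - 1 columns ("same" conv)
nn_pad <- function(a, X, G, k, idx = nn_core_idx(X, G, k)) {
  out <- matrix(0, nrow(a), (X + k - 1L) * G)
  out[, idx] <- a
  out
}

nn_unpad <- function(a, X, G, k, idx = nn_core_idx(X, G, k)) {
  a[, idx, drop = FALSE]
}

# force the pad columns of a padded-layout matrix to zero
nn_zero_pads <- function(a, X, G, k, idx = nn_core_idx(X, G, k)) {
  out <- matrix(0, nrow(a), ncol(a))
  out[, idx] <- a[, idx]
  out
}

# Glorot-uniform initialization; conv fans include the kernel extent.
nn_glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

nn_init_params <- function(shape, cfg) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  k <- cfg$kernel_len
  F1 <- cfg$conv_filters; F2 <- cfg$conv_filters; Fd <- cfg$conv_filters
  D <- cfg$deep_dim; E <- cfg$encoded_dim
  C2 <- F1 * n
  mn <- m * n
  list(
    W1  = nn_glorot(c(m, F1, k), k * m, k * F1),   b1  = numeric(F1),
    W2  = nn_glorot(c(C2, F2, k), k * C2, k * F2), b2  = numeric(F2),
    Wd1 = nn_glorot(c(D, F2), F2, D),              bd1 = numeric(D),
    Wd2 = nn_glorot(c(D, D), D, D),                bd2 = numeric(D),
    Wd3 = nn_glorot(c(D, D), D, D),                bd3 = numeric(D),
    We  = nn_glorot(c(E, D), D, E),                be  = numeric(E),
    Wdc = nn_glorot(c(E, Fd, k), k * E, k * Fd),   bdc = numeric(Fd),
    Wo  = nn_glorot(c(Fd, mn, k), k * Fd, k * mn), bo  = numeric(mn)
  )
}

# xb: matrix (X*m*n, B), flattened tensors with position fastest, then
# dataset, then regulator. From the second conv stage on, activations live in
# the padded layout (X + k - 1 columns per batch block, pads zero where a
# convolution consumes them). Returns the output in core (m*n, X*B) layout
# plus, when requested, the cache needed for the backward pass.
nn_forward <- function(p, xb, shape, cfg, train = FALSE, cache = FALSE) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  B <- ncol(xb)
  k <- cfg$kernel_len
  F1 <- dim(p$W1)[2]
  drop_p <- if (train) cfg$dropout else 0
  idx1 <- nn_core_idx(X, n * B, k)
  idxB <- nn_core_idx(X, B, k)

  arr <- xb
  dim(arr) <- c(X, m, n, B)
  a1 <- aperm(arr, c(2, 1, 3, 4))          # (m, X, n, B)
  dim(a1) <- c(m, X * n * B)
  in1 <- nn_pad(a1, X, n * B, k, idx1)
  z1 <- conv_fwd_cpp(in1, p$W1, X, n * B) + p$b1
  pos1 <- z1 > 0
  h1 <- (z1 * pos1)[, idx1, drop = FALSE]  # (F1, X*n*B), core only

  dim(h1) <- c(F1, X, n, B)
  a2 <- aperm(h1, c(1, 3, 2, 4))           # (F1, n, X, B)
  dim(a2) <- c(F1 * n, X * B)
  in2 <- nn_pad(a2, X, B, k, idxB)
  z2 <- conv_fwd_cpp(in2, p$W2, X, B) + p$b2
  pos2 <- z2 > 0
  h2 <- z2 * pos2                          # (F2, Xp*B); pads = relu(b2),
                                           # harmless: they never reach a conv

  dense_fwd <- function(W, b, a) {
    z <- W %*% a + b
    pos <- z > 0
    list(h = z * pos, pos = pos)
  }
  drop_mask <- function(h) {
    if (drop_p <= 0) return(NULL)
    matrix(stats::runif(length(h)) >= drop_p, nrow(h)) / (1 - drop_p)
  }
  d1 <- dense_fwd(p$Wd1, p$bd1, h2); mk1 <- drop_mask(d1$h)
  hd1 <- if (is.null(mk1)) d1$h else d1$h * mk1
  d2 <- dense_fwd(p$Wd2, p$bd2, hd1); mk2 <- drop_mask(d2$h)
  hd2 <- if (is.null(mk2)) d2$h else d2$h * mk2
  d3 <- dense_fwd(p$Wd3, p$bd3, hd2); mk3 <- drop_mask(d3$h)
  hd3 <- if (is.null(mk3)) d3$h else d3$h * mk3
  de <- dense_fwd(p$We, p$be, hd3)
  enc <- nn_zero_pads(de$h, X, B, k, idxB) # (E, Xp*B), feeds a conv

  zdc <- conv_fwd_cpp(enc, p$Wdc, X, B) + p$bdc
  posdc <- zdc > 0
  hdc <- nn_zero_pads(zdc * posdc, X, B, k, idxB)

  outp <- conv_fwd_cpp(hdc, p$Wo, X, B) + p$bo  # (m*n, Xp*B), linear
  out <- outp[, idxB, drop = FALSE]

  res <- list(out = out, enc = enc[, idxB, drop = FALSE])
  if (cache) {
    res$cache <- list(in1 = in1, pos1 = pos1, in2 = in2, pos2 = pos2,
                      h2 = h2, d1 = d1, mk1 = mk1, hd1 = hd1,
                      d2 = d2, mk2 = mk2, hd2 = hd2,
                      d3 = d3, mk3 = mk3, hd3 = hd3,
                      epos = de$pos, enc_pad = enc, posdc = posdc,
                      hdc = hdc, idx1 = idx1, idxB = idxB, B = B)
  }
  res
}

# Convert (m*n, X*B) model output back to flattened-tensor columns (X*m*n, B).
nn_out_to_tensor <- function(out, shape, B) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  dim(out) <- c(m, n, X, B)
  out <- aperm(out, c(3, 1, 2, 4))
  dim(out) <- c(X * m * n, B)
  out
}

# Target in the model's output layout.
nn_tensor_to_out <- function(xb, shape, B) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  dim(xb) <- c(X, m, n, B)
  tt <- aperm(xb, c(2, 3, 1, 4))
  dim(tt) <- c(m * n, X * B)
  tt
}

# Weighted MSE loss + full backward pass. Returns loss (data + L2 kernel
# penalty) and gradients for every parameter.
nn_loss_grads <- function(p, xb, shape, cfg, wcell) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  B <- ncol(xb)
  k <- cfg$kernel_len
  fw <- nn_forward(p, xb, shape, cfg, train = TRUE, cache = TRUE)
  cc <- fw$cache
  tt <- nn_tensor_to_out(xb, shape, B)
  diff <- fw$out - tt
  nel <- length(diff)
  l_data <- sum(wcell * diff * diff) / nel
  lam <- cfg$kernel_reg
  l_reg <- lam * (sum(p$W1^2) + sum(p$W2^2) + sum(p$Wdc^2) + sum(p$Wo^2))

  dout <- (2 / nel) * (wcell * diff)       # (m*n, X*B)
  doutp <- nn_pad(dout, X, B, k, cc$idxB)  # padded layout, zero pads

  g <- list()
  g$Wo <- conv_bwd_weights_cpp(cc$hdc, doutp, X, B, k) + 2 * lam * p$Wo
  g$bo <- rowSums(doutp)
  dhdc <- nn_zero_pads(conv_bwd_input_cpp(doutp, p$Wo, X, B), X, B, k, cc$idxB)
  dzdc <- dhdc * cc$posdc
  g$Wdc <- conv_bwd_weights_cpp(cc$enc_pad, dzdc, X, B, k) + 2 * lam * p$Wdc
  g$bdc <- rowSums(dzdc)
  denc <- nn_zero_pads(conv_bwd_input_cpp(dzdc, p$Wdc, X, B), X, B, k, cc$idxB)

  dze <- denc * cc$epos
  g$We <- tcrossprod(dze, cc$hd3)
  g$be <- rowSums(dze)
  dhd3 <- crossprod(p$We, dze)
  if (!is.null(cc$mk3)) dhd3 <- dhd3 * cc$mk3
  dzd3 <- dhd3 * cc$d3$pos
  g$Wd3 <- tcrossprod(dzd3, cc$hd2)
  g$bd3 <- rowSums(dzd3)
  dhd2 <- crossprod(p$Wd3, dzd3)
  if (!is.null(cc$mk2)) dhd2 <- dhd2 * cc$mk2
  dzd2 <- dhd2 * cc$d2$pos
  g$Wd2 <- tcrossprod(dzd2, cc$hd1)
  g$bd2 <- rowSums(dzd2)
  dhd1 <- crossprod(p$Wd2, dzd2)
  if (!is.null(cc$mk1)) dhd1 <- dhd1 * cc$mk1
  dzd1 <- dhd1 * cc$d1$pos
  g$Wd1 <- tcrossprod(dzd1, cc$h2)
  g$bd1 <- rowSums(dzd1)
  dh2 <- crossprod(p$Wd1, dzd1)

  dz2 <- dh2 * cc$pos2                     # padded layout; dh2 pads are zero
  g$W2 <- conv_bwd_weights_cpp(cc$in2, dz2, X, B, k) + 2 * lam * p$W2
  g$b2 <- rowSums(dz2)
  da2 <- nn_unpad(conv_bwd_input_cpp(dz2, p$W2, X, B), X, B, k, cc$idxB)

  F1 <- dim(p$W1)[2]
  dim(da2) <- c(F1, n, X, B)
  dh1 <- aperm(da2, c(1, 3, 2, 4))
  dim(dh1) <- c(F1, X * n * B)
  dz1 <- nn_pad(dh1, X, n * B, k, cc$idx1) * cc$pos1
  g$W1 <- conv_bwd_weights_cpp(cc$in1, dz1, X, n * B, k) + 2 * lam * p$W1
  g$b1 <- rowSums(dz1)

  list(loss = l_data + l_reg, data_loss = l_data, grads = g)
}

# Gradient of a scalar objective on the encoded layer with respect to the
# input tensor (used by the gradient-ascent ur-examples). denc: (E, X*B).
nn_input_grad <- function(p, xb, shape, cfg, denc) {
  X <- shape[1]; m <- shape[2]; n <- shape[3]
  B <- ncol(xb)
  k <- cfg$kernel_len
  fw <- nn_forward(p, xb, shape, cfg, train = FALSE, cache = TRUE)
  cc <- fw$cache
  dze <- nn_pad(denc, X, B, k, cc$idxB) * cc$epos
  dhd3 <- crossprod(p$We, dze)
  dzd3 <- dhd3 * cc$d3$pos
  dhd2 <- crossprod(p$Wd3, dzd3)
  dzd2 <- dhd2 * cc$d2$pos
  dhd1 <- crossprod(p$Wd2, dzd2)
  dzd1 <- dhd1 * cc$d1$pos
  dh2 <- crossprod(p$Wd1, dzd1)
  dz2 <- dh2 * cc$pos2
  da2 <- nn_unpad(conv_bwd_input_cpp(dz2, p$W2, X, B), X, B, k, cc$idxB)
  F1 <- dim(p$W1)[2]
  dim(da2) <- c(F1, n, X, B)
  dh1 <- aperm(da2, c(1, 3, 2, 4))
  dim(dh1) <- c(F1, X * n * B)
  dz1 <- nn_pad(dh1, X, n * B, k, cc$idx1) * cc$pos1
  da1 <- nn_unpad(conv_bwd_input_cpp(dz1, p$W1, X, n * B), X, n * B, k,
                  cc$idx1)
  dim(da1) <- c(m, X, n, B)
  dx <- aperm(da1, c(2, 1, 3, 4))
  dim(dx) <- c(X * m * n, B)
  list(grad = dx, enc = fw$enc)
}

nn_adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0L)
}

nn_adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (nm in names(p)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(p = p, st = st)
}

# Per-cell loss weights in the (m*n, X*B) output layout: product of the
# per-dataset and per-regulator multipliers, recycled down the columns.
nn_cell_weights <- function(shape, cfg) {
  m <- shape[2]; n <- shape[3]
  wd <- cfg$loss_weights$datasets
  wt <- cfg$loss_weights$regulators
  if (is.null(wd)) wd <- rep(1, m)
  if (is.null(wt)) wt <- rep(1, n)
  stopifnot(length(wd) == m, length(wt) == n)
  as.vector(outer(wd, wt))
}
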