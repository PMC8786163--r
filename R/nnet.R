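# Compact CNN machinery: im2col 3x3 convolutions (pad 1, stride 1), 2x2
# average pooling, nearest-neighbour 2x upsampling, global average
# pooling, a linear head, and Adam. Written against base R matrix
# algebra; batches are arrays of shape (H, W, B, C) — batch before
# channel, so conv outputs reshape without transposition.
#
# Conventions:
#  * conv weights are matrices of shape (9 * C_in) x C_out; the 9 kernel
#    taps are flattened column-major (row offset fastest) within each
#    input-channel block.
#  * im2col row order is (pixel within image, column-major), then image,
#    so array(Y, c(H, W, B, C_out)) reshapes losslessly.
#  * the input gradient is computed as a transposed convolution (im2col
#    of the output gradient times a tap-reversed weight), avoiding
#    scatter-adds.

# memoized gather-index matrices, keyed by (H, W, B, C)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, B, C) {
  key <- sprintf("%d_%d_%d_%d", H, W, B, C)
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  S <- (H + 2L) * (W + 2L)
  I <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    I[, k] <- (j + dj) * (H + 2L) + (i + di) + 1L
  }
  boff <- (seq_len(B) - 1L) * S
  IDX <- matrix(0L, H * W * B, 9L * C)
  for (cc in seq_len(C)) {
    coff <- (cc - 1L) * S * B
    for (k in 1:9)
      IDX[, (cc - 1L) * 9L + k] <- as.vector(outer(I[, k], boff, "+")) + coff
  }
  .im2col_cache[[key]] <- IDX
  IDX
}

# x: (H, W, B, C) -> (H*W*B) x (9*C)
im2col <- function(x) {
  d <- dim(x)
  pad <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  IDX <- im2col_index(d[1], d[2], d[3], d[4])
  M <- pad[as.vector(IDX)]
  dim(M) <- dim(IDX)
  M
}

conv_forward <- function(x, W, b, keep_M = FALSE) {
  d <- dim(x)
  M <- im2col(x)
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  y <- array(Y, c(d[1], d[2], d[3], ncol(W)))
  if (keep_M) list(y = y, M = M) else list(y = y)
}

# tap-reversed, channel-transposed weight for the transposed convolution
flip_weight <- function(W, C_in) {
  C_out <- ncol(W)
  Wf <- matrix(0, 9L * C_out, C_in)
  for (cin in seq_len(C_in)) for (k in 1:9)
    Wf[(seq_len(C_out) - 1L) * 9L + k, cin] <- W[(cin - 1L) * 9L + (10L - k), ]
  Wf
}

conv_backward <- function(dy, M, W, C_in, need_dx = TRUE) {
  d <- dim(dy)
  dYm <- matrix(dy, ncol = d[4])
  dW <- crossprod(M, dYm)
  db <- colSums(dYm)
  out <- list(dW = dW, db = db)
  if (need_dx) {
    Mg <- im2col(dy)
    dXm <- Mg %*% flip_weight(W, C_in)
    out$dx <- array(dXm, c(d[1], d[2], d[3], C_in))
  }
  out
}

# instance normalization: standardize each (image, channel) plane over
# its spatial extent; removes per-section staining gain and tint from the
# feature maps. A pass-through variant supports raw featurizers.
inorm_identity <- function(x) list(y = x, identity = TRUE)

inorm_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  per <- d[1] * d[2]
  m <- matrix(x, per, d[3] * d[4])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = per)
  sd_ <- sqrt(colMeans(xc * xc) + eps)
  xh <- xc / rep(sd_, each = per)
  y <- xh
  dim(y) <- d
  list(y = y, xh = xh, sd = sd_, per = per)
}

inorm_backward <- function(dy, cache) {
  if (isTRUE(cache$identity)) return(dy)
  d <- dim(dy)
  per <- cache$per
  g <- matrix(dy, per, d[3] * d[4])
  gm <- colMeans(g)
  gx <- colMeans(g * cache$xh)
  dx <- (g - rep(gm, each = per) - cache$xh * rep(gx, each = per)) /
    rep(cache$sd, each = per)
  dim(dx) <- d
  dx
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  (x[oi, oj, , , drop = FALSE] + x[ei, oj, , , drop = FALSE] +
     x[oi, ej, , , drop = FALSE] + x[ei, ej, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  oi <- seq(1L, in_dim[1], 2L); oj <- seq(1L, in_dim[2], 2L)
  g <- dy / 4
  dx[oi, oj, , ] <- g
  dx[oi + 1L, oj, , ] <- g
  dx[oi, oj + 1L, , ] <- g
  dx[oi + 1L, oj + 1L, , ] <- g
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  oi <- seq(1L, d[1], 2L); oj <- seq(1L, d[2], 2L)
  dy[oi, oj, , , drop = FALSE] + dy[oi + 1L, oj, , , drop = FALSE] +
    dy[oi, oj + 1L, , , drop = FALSE] + dy[oi + 1L, oj + 1L, , , drop = FALSE]
}

# (H, W, B, C) -> (B x C) spatial means
gap_forward <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_backward <- function(dF, in_dim) {
  per <- in_dim[1] * in_dim[2]
  array(rep(as.vector(dF) / per, each = per), in_dim)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# ---- tiny_cnn backbone: 3 conv+relu+pool blocks, GAP, linear head -----

tiny_cnn_init <- function(input_side, embedding_dim, filters = c(8L, 16L, 32L),
                          seed = 1L, l2_normalize = TRUE,
                          instance_norm = TRUE) {
  if (input_side %% 16L != 0L)
    stop_invalid("tiny_cnn input side must be divisible by 16, got %d",
                 input_side)
  with_seed(seed, {
    cin <- c(1L, filters[1], filters[2])
    params <- list(
      W1 = he_init(9 * cin[1], filters[1], 9 * cin[1]), b1 = rep(0, filters[1]),
      W2 = he_init(9 * cin[2], filters[2], 9 * cin[2]), b2 = rep(0, filters[2]),
      W3 = he_init(9 * cin[3], filters[3], 9 * cin[3]), b3 = rep(0, filters[3]),
      Wf = he_init(filters[3], embedding_dim, filters[3]),
      bf = rep(0, embedding_dim)
    )
    list(params = params, filters = filters, input_side = input_side,
         embedding_dim = embedding_dim, l2_normalize = l2_normalize,
         instance_norm = instance_norm)
  })
}

tiny_cnn_forward <- function(net, x, keep_cache = FALSE) {
  p <- net$params
  B <- dim(x)[3]
  x <- (x - 0.9) * 5                            # centre the stain scale
  x <- avgpool2_forward(x)                      # stride-2 pooling stem
  norm_fun <- if (isTRUE(net$instance_norm)) inorm_forward else inorm_identity
  c1 <- conv_forward(x, p$W1, p$b1, keep_M = keep_cache)
  n1 <- norm_fun(c1$y)
  r1 <- pmax(n1$y, 0); p1 <- avgpool2_forward(r1)
  c2 <- conv_forward(p1, p$W2, p$b2, keep_M = keep_cache)
  n2 <- norm_fun(c2$y)
  r2 <- pmax(n2$y, 0); p2 <- avgpool2_forward(r2)
  c3 <- conv_forward(p2, p$W3, p$b3, keep_M = keep_cache)
  n3 <- norm_fun(c3$y)
  r3 <- pmax(n3$y, 0); p3 <- avgpool2_forward(r3)
  feat <- gap_forward(p3)                       # B x C3
  emb <- feat %*% p$Wf + rep(p$bf, each = B)
  norms <- NULL
  if (isTRUE(net$l2_normalize)) {
    norms <- sqrt(rowSums(emb * emb) + 1e-12)
    emb <- emb / norms
  }
  if (!keep_cache) return(list(emb = emb))
  list(emb = emb,
       cache = list(c1 = c1, n1 = n1, c2 = c2, n2 = n2, c3 = c3, n3 = n3,
                    p3 = p3, feat = feat, B = B, norms = norms, embn = emb))
}

tiny_cnn_backward <- function(net, cache, demb) {
  p <- net$params
  if (isTRUE(net$l2_normalize)) {
    # gradient through row-wise unit normalisation
    proj <- rowSums(demb * cache$embn)
    demb <- (demb - cache$embn * proj) / cache$norms
  }
  dWf <- crossprod(cache$feat, demb)
  dbf <- colSums(demb)
  dfeat <- tcrossprod(demb, p$Wf)
  dp3 <- gap_backward(dfeat, dim(cache$p3))
  dr3 <- avgpool2_backward(dp3, dim(cache$n3$y))
  dn3 <- inorm_backward(dr3 * (cache$n3$y > 0), cache$n3)
  g3 <- conv_backward(dn3, cache$c3$M, p$W3, net$filters[2])
  dr2 <- avgpool2_backward(g3$dx, dim(cache$n2$y))
  dn2 <- inorm_backward(dr2 * (cache$n2$y > 0), cache$n2)
  g2 <- conv_backward(dn2, cache$c2$M, p$W2, net$filters[1])
  dr1 <- avgpool2_backward(g2$dx, dim(cache$n1$y))
  dn1 <- inorm_backward(dr1 * (cache$n1$y > 0), cache$n1)
  g1 <- conv_backward(dn1, cache$c1$M, p$W1, 1L, need_dx = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, Wf = dWf, bf = dbf)
}

# stack a list of equal-size matrices into an (H, W, B, 1) batch array
stack_patches <- function(patch_list) {
  h <- nrow(patch_list[[1]]); w <- ncol(patch_list[[1]])
  array(unlist(patch_list, use.names = FALSE), c(h, w, length(patch_list), 1L))
}

# area-average resize of a square patch to the network input side
resize_patch <- function(m, side) {
  if (nrow(m) == side && ncol(m) == side) return(m)
  downsample_to(m, side)
}
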