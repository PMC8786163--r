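#' Triplet-loss gene embedding
#'
#' The embedder learns a convolutional map from ISH image patches to a
#' fixed-dimension vector space in which patches assaying the same gene
#' lie close together. Training uses the batch-hard variant of the
#' triplet loss: each batch holds P genes x K patches; for every anchor
#' patch the hardest positive (farthest same-gene patch) and hardest
#' negative (nearest other-gene patch) are mined inside the batch, and
#' the soft-margin loss log(1 + exp(d_ap - d_an)) (or a hinge with a
#' numeric margin) is averaged over anchors.
#'
#' @name embedder
NULL

#' Training configuration for the triplet embedder
#'
#' Defaults follow the tuned values reported for full-scale ISH training
#' (P = K = 17, initial learning rate 7e-5, Euclidean metric, soft
#' margin, horizontal + vertical flip augmentation, 128-d output). For
#' desk-scale runs with the \code{tiny_cnn} backbone a larger learning
#' rate (~1e-3) and a small \code{embedding_dim} are appropriate.
#'
#' @param batch_p genes per batch (>= 2).
#' @param batch_k patches per gene per batch (>= 2).
#' @param margin \code{"soft"} or a non-negative number (hinge margin).
#' @param learning_rate positive initial Adam learning rate.
#' @param train_iterations number of gradient steps.
#' @param metric one of \code{"euclidean"}, \code{"sqeuclidean"},
#'   \code{"cityblock"}.
#' @param flip_horizontal,flip_vertical enable random flips (p = 0.5 each).
#' @param embedding_dim output dimension (default 128).
#' @param backbone \code{"tiny_cnn"} (implemented) or
#'   \code{"resnet50_pretrained"} (requires external weights; not bundled).
#' @param input_side side to which patches are resized before the network
#'   (must be divisible by 8 for \code{tiny_cnn}).
#' @param decay_start_fraction fraction of iterations after which the
#'   learning rate decays exponentially to 1e-3 x its initial value.
#' @param l2_normalize project embeddings onto the unit sphere (default
#'   TRUE; prevents scale collapse when training from random
#'   initialisation, see the methods vignette). Set FALSE to keep raw
#'   magnitudes, e.g. when using the untrained backbone as a fixed
#'   featurizer.
#' @param instance_norm apply per-image, per-channel feature
#'   normalization after each convolution (default TRUE; removes
#'   per-section staining gain and tint). Set FALSE for a raw featurizer
#'   that retains absolute stain statistics.
#' @param seed integer seed governing init, batching and augmentation.
#' @return list of class \code{"training_config"}.
#' @export
training_config <- function(batch_p = 17L, batch_k = 17L, margin = "soft",
                            learning_rate = 7e-5, train_iterations = 1000L,
                            metric = c("euclidean", "sqeuclidean", "cityblock"),
                            flip_horizontal = TRUE, flip_vertical = TRUE,
                            embedding_dim = 128L,
                            backbone = c("tiny_cnn", "resnet50_pretrained"),
                            input_side = 64L, decay_start_fraction = 0.75,
                            l2_normalize = TRUE, instance_norm = TRUE,
                            seed = 1L) {
  metric <- match.arg(metric)
  backbone <- match.arg(backbone)
  if (batch_p < 2) stop_invalid("batch_p must be >= 2")
  if (batch_k < 2) stop_invalid("batch_k must be >= 2")
  if (learning_rate < 0) stop_invalid("learning_rate must be >= 0")
  if (embedding_dim < 2) stop_invalid("embedding_dim must be >= 2")
  if (!identical(margin, "soft")) {
    margin <- as.numeric(margin)
    if (!is.finite(margin) || margin < 0)
      stop_invalid("margin must be \"soft\" or a non-negative number")
  }
  structure(list(batch_p = as.integer(batch_p), batch_k = as.integer(batch_k),
                 margin = margin, learning_rate = learning_rate,
                 train_iterations = as.integer(train_iterations),
                 metric = metric, flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 embedding_dim = as.integer(embedding_dim),
                 backbone = backbone, input_side = as.integer(input_side),
                 decay_start_fraction = decay_start_fraction,
                 l2_normalize = isTRUE(l2_normalize),
                 instance_norm = isTRUE(instance_norm),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Batch-size helper: K = floor(300 / P)
#'
#' The reference full-scale configuration couples the two batch sizes
#' through a memory budget of 300 patches per batch.
#'
#' @param batch_p genes per batch.
#' @return floor(300 / batch_p).
#' @export
batch_k_for_p <- function(batch_p) as.integer(300 %/% batch_p)

#' Pairwise distances between embedding vectors
#'
#' @param vectors n x d numeric matrix.
#' @param metric \code{"euclidean"}, \code{"sqeuclidean"} or
#'   \code{"cityblock"}.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
pairwise_distances <- function(vectors,
                               metric = c("euclidean", "sqeuclidean",
                                          "cityblock")) {
  metric <- match.arg(metric)
  if (!all(is.finite(vectors))) stop_invalid("non-finite embedding values")
  D <- switch(metric,
    euclidean = as.matrix(stats::dist(vectors, method = "euclidean")),
    sqeuclidean = as.matrix(stats::dist(vectors, method = "euclidean"))^2,
    cityblock = as.matrix(stats::dist(vectors, method = "manhattan")))
  dimnames(D) <- NULL
  D
}

validate_triplet_labels <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L)
    stop_invalid("batch-hard triplet loss needs >= 2 distinct labels")
  if (any(tab < 2L))
    stop_invalid("every label needs >= 2 occurrences (anchor needs a positive)")
}

# loss and (optionally) gradient w.r.t. the embedding vectors
batch_hard_core <- function(vectors, labels, margin, metric,
                            want_grad = FALSE) {
  validate_triplet_labels(labels)
  n <- nrow(vectors)
  D <- pairwise_distances(vectors, metric)
  same <- outer(labels, labels, "==")
  pos <- same; diag(pos) <- FALSE
  Dp <- D; Dp[!pos] <- -Inf
  Dn <- D; Dn[same] <- Inf
  hp <- max.col(Dp, ties.method = "first")
  hn <- max.col(-Dn, ties.method = "first")
  d_ap <- D[cbind(seq_len(n), hp)]
  d_an <- D[cbind(seq_len(n), hn)]
  delta <- d_ap - d_an
  if (identical(margin, "soft")) {
    per <- log1p(exp(-abs(delta))) + pmax(delta, 0)   # stable softplus
    coef <- 1 / (1 + exp(-delta))
  } else {
    per <- pmax(0, delta + margin)
    coef <- as.numeric(per > 0)
  }
  loss <- mean(per)
  if (!want_grad) return(list(loss = loss))

  pair_grad <- function(a, b, dval) {
    diff <- vectors[a, ] - vectors[b, ]
    switch(metric,
      euclidean = diff / max(dval, 1e-12),
      sqeuclidean = 2 * diff,
      cityblock = sign(diff))
  }
  G <- matrix(0, n, ncol(vectors))
  w <- coef / n
  for (a in seq_len(n)) {
    if (w[a] == 0) next
    gp <- pair_grad(a, hp[a], d_ap[a]) * w[a]
    gn <- pair_grad(a, hn[a], d_an[a]) * w[a]
    G[a, ] <- G[a, ] + gp - gn
    G[hp[a], ] <- G[hp[a], ] - gp
    G[hn[a], ] <- G[hn[a], ] + gn
  }
  list(loss = loss, grad = G)
}

#' Batch-hard triplet loss
#'
#' For each anchor, the hardest positive is its maximum distance to a
#' same-label sample (self excluded) and the hardest negative its minimum
#' distance to a different-label sample. Per-anchor loss is
#' \code{log(1 + exp(d_ap - d_an))} under the soft margin, or
#' \code{max(0, d_ap - d_an + m)} for a numeric margin m; the batch loss
#' is the mean over anchors.
#'
#' @param vectors n x d embedding matrix.
#' @param labels length-n label vector (gene ids); every label must occur
#'   at least twice and at least two labels must be present.
#' @param margin \code{"soft"} or non-negative numeric.
#' @param metric distance metric (see \code{\link{pairwise_distances}}).
#' @return scalar loss.
#' @export
batch_hard_triplet_loss <- function(vectors, labels, margin = "soft",
                                    metric = "euclidean") {
  batch_hard_core(vectors, labels, margin, metric, want_grad = FALSE)$loss
}

#' Sample a P x K training batch
#'
#' Samples \code{p} genes uniformly without replacement, then \code{k}
#' patches per gene (without replacement when the gene has >= k patches,
#' with replacement otherwise).
#'
#' @param patch_table data.frame with columns \code{patch_id},
#'   \code{gene_id}.
#' @param p,k batch dimensions.
#' @param seed integer seed.
#' @return data.frame of p*k rows (patch_id, gene_id).
#' @export
make_pk_batch <- function(patch_table, p, k, seed) {
  genes <- unique(patch_table$gene_id)
  if (length(genes) < p)
    stop_invalid("need >= %d genes with patches, have %d", p, length(genes))
  with_seed(seed, {
    chosen <- sample(genes, p)
    rows <- lapply(chosen, function(g) {
      ids <- patch_table$patch_id[patch_table$gene_id == g]
      picked <- if (length(ids) >= k) sample(ids, k)
                else ids[sample.int(length(ids), k, replace = TRUE)]
      data.frame(patch_id = picked, gene_id = g, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Random flip augmentation
#'
#' Each enabled flip (horizontal = left-right, vertical = upside down) is
#' applied independently with probability 0.5.
#'
#' @param pixels square patch matrix.
#' @param flip_horizontal,flip_vertical enable the respective flip.
#' @param seed integer seed.
#' @return the (possibly flipped) patch.
#' @export
augment_flips <- function(pixels, flip_horizontal = TRUE,
                          flip_vertical = TRUE, seed = 1L) {
  with_seed(seed, {
    if (flip_horizontal && stats::runif(1) < 0.5)
      pixels <- pixels[, rev(seq_len(ncol(pixels)))]
    if (flip_vertical && stats::runif(1) < 0.5)
      pixels <- pixels[rev(seq_len(nrow(pixels))), ]
    pixels
  })
}

lr_at <- function(step, total, lr0, decay_start_fraction) {
  t0 <- ceiling(decay_start_fraction * total)
  if (step <= t0 || total <= t0) return(lr0)
  lr0 * (1e-3)^((step - t0) / (total - t0))
}

#' Fit a triplet-loss patch embedder
#'
#' Trains the configured backbone with batch-hard triplet loss over
#' P x K gene batches. Each step samples a batch
#' (\code{\link{make_pk_batch}}), applies flip augmentation, runs the
#' network forward, computes the loss and its gradient, and takes an Adam
#' step; the learning rate is constant until
#' \code{decay_start_fraction} x iterations, then decays exponentially to
#' 1e-3 x its initial value. With \code{train_iterations = 0} the
#' randomly initialised (untrained) model is returned, which serves as a
#' baseline.
#'
#' @param patches named list of square patch matrices (values in [0,1]),
#'   names are patch ids.
#' @param patch_table data.frame mapping \code{patch_id} to
#'   \code{gene_id} (extra columns are kept as provenance).
#' @param config a \code{\link{training_config}}.
#' @return object of class \code{"ish_embedder"} with elements
#'   \code{net}, \code{config} and \code{loss_trace} (data.frame with
#'   step, loss, lr).
#' @export
ish_embedder <- function(patches, patch_table, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  if (config$backbone == "resnet50_pretrained")
    stop_invalid(paste("backbone 'resnet50_pretrained' requires external",
                       "pretrained weights which are not bundled;",
                       "use backbone 'tiny_cnn'"))
  if (!all(patch_table$patch_id %in% names(patches)))
    stop_invalid("patch_table references patch ids missing from `patches`")
  n_genes <- length(unique(patch_table$gene_id))
  if (config$train_iterations > 0L && n_genes < config$batch_p)
    stop_invalid("need >= batch_p (%d) genes with patches, have %d",
                 config$batch_p, n_genes)

  side <- config$input_side
  patches <- lapply(patches, resize_patch, side = side)
  net <- tiny_cnn_init(side, config$embedding_dim,
                       seed = substream_seed(config$seed, "init"),
                       l2_normalize = config$l2_normalize,
                       instance_norm = config$instance_norm)

  trace <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  if (config$train_iterations > 0L) {
    opt <- adam_init(net$params)
    total <- config$train_iterations
    trace <- data.frame(step = seq_len(total), loss = NA_real_,
                        lr = NA_real_)
    for (step in seq_len(total)) {
      batch <- make_pk_batch(patch_table, config$batch_p, config$batch_k,
                             substream_seed(config$seed, "batch", step))
      px <- lapply(seq_len(nrow(batch)), function(i)
        augment_flips(patches[[batch$patch_id[i]]],
                      config$flip_horizontal, config$flip_vertical,
                      substream_seed(config$seed, "flip",
                                     step * 100000L + i)))
      x <- stack_patches(px)
      fw <- tiny_cnn_forward(net, x, keep_cache = TRUE)
      lg <- batch_hard_core(fw$emb, batch$gene_id, config$margin,
                            config$metric, want_grad = TRUE)
      grads <- tiny_cnn_backward(net, fw$cache, lg$grad)
      lr <- lr_at(step, total, config$learning_rate,
                  config$decay_start_fraction)
      upd <- adam_step(net$params, grads, opt, lr)
      net$params <- upd$params
      opt <- upd$state
      trace$loss[step] <- lg$loss
      trace$lr[step] <- lr
    }
  }
  structure(list(net = net, config = config, loss_trace = trace),
            class = "ish_embedder")
}

#' @export
print.ish_embedder <- function(x, ...) {
  cat(sprintf(
    "<ish_embedder> backbone=%s  input=%dpx  dim=%d  trained %d steps\n",
    x$config$backbone, x$config$input_side, x$config$embedding_dim,
    nrow(x$loss_trace)))
  invisible(x)
}

#' @export
summary.ish_embedder <- function(object, ...) {
  tr <- object$loss_trace
  cat(sprintf("Triplet embedder (%s), embedding dim %d\n",
              object$config$backbone, object$config$embedding_dim))
  if (nrow(tr) > 0) {
    head_n <- min(50L, nrow(tr))
    cat(sprintf("  steps: %d   first-%d mean loss: %.4f   last-%d mean loss: %.4f\n",
                nrow(tr), head_n, mean(tr$loss[seq_len(head_n)]),
                head_n, mean(tr$loss[(nrow(tr) - head_n + 1):nrow(tr)])))
  } else cat("  untrained (random initialisation)\n")
  invisible(object)
}

#' @export
plot.ish_embedder <- function(x, ...) {
  tr <- x$loss_trace
  if (nrow(tr) == 0) stop_invalid("no loss trace: model is untrained")
  graphics::plot(tr$step, tr$loss, type = "l", xlab = "step",
                 ylab = "batch-hard triplet loss", ...)
  invisible(x)
}

#' Embed patches with a trained model
#'
#' Runs the network forward without augmentation; deterministic.
#'
#' @param object an \code{ish_embedder}.
#' @param patches named list of patch matrices.
#' @param chunk_size forward-pass batch size.
#' @param ... unused.
#' @return an \code{\link{embedding_matrix}} at level \code{"patch"}.
#' @export
predict.ish_embedder <- function(object, patches, chunk_size = 64L, ...) {
  side <- object$config$input_side
  patches <- lapply(patches, resize_patch, side = side)
  ids <- names(patches)
  if (is.null(ids)) stop_invalid("patches must be a named list (patch ids)")
  out <- matrix(0, length(patches), object$config$embedding_dim)
  i <- 1L
  while (i <= length(patches)) {
    j <- min(i + chunk_size - 1L, length(patches))
    x <- stack_patches(patches[i:j])
    out[i:j, ] <- tiny_cnn_forward(object$net, x)$emb
    i <- j + 1L
  }
  rownames(out) <- ids
  embedding_matrix(out, "patch")
}

#' Embed patches (functional form)
#'
#' @inheritParams predict.ish_embedder
#' @param model an \code{ish_embedder}.
#' @return patch-level \code{\link{embedding_matrix}}.
#' @export
embed_patches <- function(model, patches) predict(model, patches)

#' Grid search over training configurations
#'
#' Trains each configuration on the training genes' patches and scores it
#' by image-level rank-1 re-identification (donor-excluding) on the
#' validation genes; ties are broken by first occurrence.
#'
#' @param configs list of \code{\link{training_config}} objects.
#' @param patches named list of patch matrices (train + validation).
#' @param patch_table data.frame (patch_id, image_id, gene_id).
#' @param image_table data.frame (image_id, gene_id, donor_id, ...).
#' @param train_genes,val_genes character vectors of gene ids.
#' @return list with \code{best_config}, \code{best_index} and
#'   \code{results} (one row per config with its validation rank-1).
#' @export
grid_search <- function(configs, patches, patch_table, image_table,
                        train_genes, val_genes) {
  if (length(configs) == 0) stop_invalid("empty config list")
  rank1s <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    tr_tab <- patch_table[patch_table$gene_id %in% train_genes, ]
    model <- ish_embedder(patches[tr_tab$patch_id], tr_tab, configs[[ci]])
    va_tab <- patch_table[patch_table$gene_id %in% val_genes, ]
    pe <- predict(model, patches[va_tab$patch_id])
    ie <- aggregate_mean(pe, stats::setNames(va_tab$image_id,
                                             va_tab$patch_id), "image")
    res <- rank1_accuracy(
      ie,
      stats::setNames(image_table$gene_id, image_table$image_id),
      stats::setNames(image_table$donor_id, image_table$image_id))
    rank1s[ci] <- res$rank1
  }
  best <- which.max(rank1s)
  list(best_config = configs[[best]], best_index = best,
       results = data.frame(config = seq_along(configs),
                            val_rank1 = rank1s))
}
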