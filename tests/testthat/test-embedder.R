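test_that("pairwise distances match closed forms and a brute-force loop", {
  v <- rbind(c(0, 0), c(3, 4))
  expect_equal(pairwise_distances(v, "euclidean")[1, 2], 5)
  expect_equal(pairwise_distances(v, "sqeuclidean")[1, 2], 25)
  expect_equal(pairwise_distances(v, "cityblock")[1, 2], 7)

  set.seed(4)
  m <- matrix(rnorm(24), 6, 4)
  for (metric in c("euclidean", "sqeuclidean", "cityblock")) {
    D <- pairwise_distances(m, metric)
    expect_equal(diag(D), rep(0, 6))
    expect_equal(D, t(D))
    ref <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6)
      ref[i, j] <- switch(metric,
        euclidean = sqrt(sum((m[i, ] - m[j, ])^2)),
        sqeuclidean = sum((m[i, ] - m[j, ])^2),
        cityblock = sum(abs(m[i, ] - m[j, ])))
    expect_lt(max(abs(D - ref)), 1e-9)
  }
  expect_error(pairwise_distances(m, "cosine"))
})

test_that("batch-hard loss matches limits, oracle, and validates labels", {
  # identical vectors: d_ap = d_an = 0, soft loss = log 2 per anchor
  v <- matrix(1, 6, 3)
  l <- rep(c("a", "b"), each = 3)
  expect_equal(batch_hard_triplet_loss(v, l), log(2))

  # far-separated tight clusters: loss ~ 0
  far <- rbind(matrix(0, 3, 2), matrix(100, 3, 2))
  expect_lt(batch_hard_triplet_loss(far, l), 1e-10)

  # soft-margin loss is strictly positive
  set.seed(1)
  v2 <- matrix(rnorm(20), 10, 2)
  l2 <- rep(c("a", "b"), 5)
  expect_gt(batch_hard_triplet_loss(v2, l2), 0)

  # oracle agreement on random batches, all margins and metrics
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    labs <- rand_labels(n, sample(2:5, 1))
    vv <- matrix(rnorm(n * 3), n, 3)
    metric <- sample(c("euclidean", "sqeuclidean", "cityblock"), 1)
    margin <- if (runif(1) < 0.5) "soft" else runif(1, 0, 2)
    expect_equal(batch_hard_triplet_loss(vv, labs, margin, metric),
                 oracle_triplet_loss(vv, labs, margin, metric),
                 tolerance = 1e-9)
  }

  # rigid rotation leaves the euclidean loss unchanged
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  vv <- matrix(rnorm(30), 10, 3)
  labs <- rep(c("a", "b"), 5)
  expect_equal(batch_hard_triplet_loss(vv, labs),
               batch_hard_triplet_loss(vv %*% Q, labs), tolerance = 1e-9)

  expect_error(batch_hard_triplet_loss(vv, rep("a", 10)), "distinct")
  expect_error(batch_hard_triplet_loss(vv, c(rep("a", 9), "b")), "positive")
})

test_that("P x K batches sample genes and patches by the stated rules", {
  tab <- data.frame(
    patch_id = sprintf("p%02d", 1:7),
    gene_id = c("A", "B", "B", "C", "C", "C", "D"),
    stringsAsFactors = FALSE)

  # a single-patch gene is repeated when k exceeds its patches
  b <- make_pk_batch(tab[tab$gene_id %in% c("A", "B"), ], p = 2, k = 2,
                     seed = 1)
  expect_equal(sum(b$patch_id == "p01"), 2L)

  # p equal to the gene count uses every gene exactly once
  b2 <- make_pk_batch(tab, p = 4, k = 2, seed = 5)
  expect_setequal(unique(b2$gene_id), c("A", "B", "C", "D"))
  expect_equal(nrow(b2), 8L)

  expect_identical(make_pk_batch(tab, 3, 2, seed = 9),
                   make_pk_batch(tab, 3, 2, seed = 9))
  expect_error(make_pk_batch(tab, p = 5, k = 2, seed = 1), "genes")
})

test_that("flip augmentation is an involution with calibrated frequencies", {
  px <- matrix(runif(64), 8, 8)
  expect_identical(augment_flips(px, FALSE, FALSE, seed = 1), px)

  # manual double flip is the identity
  fh <- px[, 8:1]
  expect_identical(fh[, 8:1], px)

  variants <- list(px, px[, 8:1], px[8:1, ], px[8:1, 8:1])
  counts <- integer(4)
  for (s in 1:1000) {
    out <- augment_flips(px, TRUE, TRUE, seed = s)
    hit <- which(vapply(variants, identical, logical(1), y = out))
    counts[hit] <- counts[hit] + 1L
  }
  expect_true(all(abs(counts / 1000 - 0.25) <= 0.05))
})

test_that("embedding inference is deterministic and shape-correct", {
  ex <- small_patches()
  tab <- ex$patch_table
  cfg <- training_config(batch_p = 4, batch_k = 2, train_iterations = 0,
                         embedding_dim = 8, input_side = 32, seed = 1)
  model <- ish_embedder(ex$patches, tab, cfg)

  ids <- tab$patch_id[1:10]
  pe <- predict(model, ex$patches[ids])
  expect_equal(dim(pe), c(10L, 8L))
  expect_identical(rownames(pe), ids)
  expect_equal(attr(pe, "level"), "patch")

  # duplicate inputs give identical rows
  dup <- ex$patches[c(ids[1], ids[1])]
  names(dup) <- c("a", "b")
  pd <- predict(model, dup)
  expect_equal(unname(pd[1, ]), unname(pd[2, ]))

  # permutation consistency
  pe2 <- predict(model, ex$patches[rev(ids)])
  expect_equal(unclass(pe2[ids, ]), unclass(pe[ids, ]))
})

test_that("training runs, records its trace, and a frozen-batch run is flat", {
  ex <- small_patches()
  tab <- ex$patch_table

  cfg <- training_config(batch_p = 4, batch_k = 2, learning_rate = 1e-3,
                         train_iterations = 30, embedding_dim = 8,
                         input_side = 32, seed = 2)
  m <- ish_embedder(ex$patches, tab, cfg)
  expect_equal(nrow(m$loss_trace), 30L)
  expect_true(all(is.finite(m$loss_trace$loss)))
  expect_true(all(m$loss_trace$lr[1:20] == 1e-3))
  expect_lt(m$loss_trace$lr[30], 1e-3)

  # with lr = 0, no augmentation, and the whole dataset in every batch
  # (p = all genes, k = patches per gene) the loss trace is constant
  genes <- unique(tab$gene_id)
  two_each <- do.call(rbind, lapply(genes, function(g)
    utils::head(tab[tab$gene_id == g, ], 2)))
  cfg0 <- training_config(batch_p = length(genes), batch_k = 2,
                          learning_rate = 0, train_iterations = 5,
                          flip_horizontal = FALSE, flip_vertical = FALSE,
                          embedding_dim = 8, input_side = 32, seed = 2)
  m0 <- ish_embedder(ex$patches[two_each$patch_id], two_each, cfg0)
  expect_lt(diff(range(m0$loss_trace$loss)), 1e-12)

  expect_error(
    ish_embedder(ex$patches, tab,
                 training_config(batch_p = 50, batch_k = 2,
                                 train_iterations = 10, embedding_dim = 8,
                                 input_side = 32)),
    "batch_p")
  expect_error(
    ish_embedder(ex$patches, tab,
                 training_config(backbone = "resnet50_pretrained",
                                 input_side = 32)),
    "pretrained")
})

test_that("grid search ranks a learning configuration above a frozen one", {
  ex <- small_patches()
  st <- small_study()
  tab <- ex$patch_table
  genes <- sort(unique(tab$gene_id))
  train_genes <- genes[1:5]
  val_genes <- genes[6:8]
  configs <- list(
    training_config(batch_p = 4, batch_k = 2, learning_rate = 1e-6,
                    train_iterations = 5, embedding_dim = 8,
                    input_side = 32, seed = 1),
    training_config(batch_p = 4, batch_k = 2, learning_rate = 2e-3,
                    train_iterations = 150, embedding_dim = 8,
                    input_side = 32, seed = 1))
  gs <- grid_search(configs, ex$patches, tab, st$image_table,
                    train_genes, val_genes)
  expect_equal(nrow(gs$results), 2L)
  expect_true(gs$best_index %in% 1:2)
  # single-config list returns that config
  gs1 <- grid_search(configs[1], ex$patches, tab, st$image_table,
                     train_genes, val_genes)
  expect_identical(gs1$best_config, configs[[1]])
  expect_error(grid_search(list(), ex$patches, tab, st$image_table,
                           train_genes, val_genes), "empty")
})
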