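# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    spec <- study_spec(n_genes = 8, n_donors = 3, genes_per_donor = "all",
                      images_per_gene_donor = 1, image_side_px = 128,
                      master_seed = 42)
    .fixture_env$study <- generate_study(spec)
  }
  .fixture_env$study
}

small_patches <- function() {
  if (is.null(.fixture_env$ex)) {
    .fixture_env$ex <- extract_study_patches(
      small_study(),
      patch_config(source_side_px = 64, output_side_px = 32,
                   max_patches = 6, max_attempts = 150),
      segmentation_config(working_side_px = 64), seed = 7)
  }
  .fixture_env$ex
}

# truth mask reduced to the working scale (area-average then 0.5 vote)
downsample_to_mask <- function(mask, side) {
  ishreid:::downsample_to(matrix(as.numeric(mask > 0), nrow(mask)), side)
}

rand_emb <- function(n, d, seed = 1, prefix = "e") {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(n))
  m
}

# a random gene/donor design over n images
rand_design <- function(n_images, n_genes, n_donors, seed) {
  set.seed(seed)
  ids <- sprintf("i%03d", seq_len(n_images))
  list(ids = ids,
       gene = stats::setNames(sample(sprintf("g%02d", seq_len(n_genes)),
                                     n_images, replace = TRUE), ids),
       donor = stats::setNames(sample(sprintf("d%02d", seq_len(n_donors)),
                                      n_images, replace = TRUE), ids))
}

# brute-force rank-1 with donor exclusion (independent of the package path)
oracle_rank1 <- function(emb, gene, donor, metric = "euclidean") {
  ids <- sort(rownames(emb))
  dfun <- switch(metric,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    sqeuclidean = function(a, b) sum((a - b)^2),
    cityblock = function(a, b) sum(abs(a - b)))
  hits <- 0L; used <- 0L; excl <- 0L
  for (q in ids) {
    gallery <- ids[donor[ids] != donor[q]]
    if (!any(gene[gallery] == gene[q])) { excl <- excl + 1L; next }
    used <- used + 1L
    best <- Inf; best_id <- NA_character_
    for (cand in gallery) {             # ids sorted -> first best = smallest id
      dd <- dfun(emb[q, ], emb[cand, ])
      if (dd < best) { best <- dd; best_id <- cand }
    }
    if (gene[best_id] == gene[q]) hits <- hits + 1L
  }
  list(rank1 = if (used > 0) hits / used else NA_real_,
       used = used, excluded = excl)
}

with_seed_local <- function(seed, expr) ishreid:::with_seed(seed, expr)

# n labels over at most k classes with every class appearing >= 2 times
rand_labels <- function(n, k) {
  k <- max(2L, min(k, n %/% 2L))
  extra <- if (n > 2L * k) sample(letters[1:k], n - 2L * k, replace = TRUE)
           else character(0)
  sample(c(rep(letters[1:k], 2), extra))
}

# triple-loop batch-hard triplet loss oracle
oracle_triplet_loss <- function(vectors, labels, margin = "soft",
                                metric = "euclidean") {
  n <- nrow(vectors)
  dfun <- switch(metric,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    sqeuclidean = function(a, b) sum((a - b)^2),
    cityblock = function(a, b) sum(abs(a - b)))
  per <- numeric(n)
  for (a in seq_len(n)) {
    dap <- -Inf; dan <- Inf
    for (p in seq_len(n))
      if (p != a && labels[p] == labels[a])
        dap <- max(dap, dfun(vectors[a, ], vectors[p, ]))
    for (g in seq_len(n))
      if (labels[g] != labels[a])
        dan <- min(dan, dfun(vectors[a, ], vectors[g, ]))
    per[a] <- if (identical(margin, "soft")) log1p(exp(dap - dan))
              else max(0, dap - dan + margin)
  }
  mean(per)
}
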