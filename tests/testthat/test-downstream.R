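test_that("annotation prediction separates a separable fixture and not noise", {
  set.seed(10)
  genes <- sprintf("g%03d", 1:60)
  pos <- genes[1:20]
  # one informative coordinate (the annotation signal) + noise dims
  X <- cbind(ifelse(genes %in% pos, 1, 0) + rnorm(60, 0, 0.1),
             matrix(rnorm(60 * 3), 60, 3))
  rownames(X) <- genes
  task <- annotation_task("signal", pos, genes)
  res <- predict_annotation(X, task, seed = 1)
  expect_gte(res$auc, 0.95)
  expect_gte(res$auc_pr, 0.9)
  expect_lt(res$max_mwu_p, 0.05)

  # shuffled labels: chance-level AUC
  set.seed(11)
  task_sh <- annotation_task("shuffled", sample(genes, 20), genes)
  res_sh <- predict_annotation(X, task_sh, seed = 1)
  expect_gt(res_sh$auc, 0.3)
  expect_lt(res_sh$auc, 0.7)

  # constant features: AUC exactly 0.5 under midrank ties
  Xc <- matrix(1, 60, 2, dimnames = list(genes, NULL))
  expect_equal(predict_annotation(Xc, task, seed = 1)$auc, 0.5)

  expect_error(predict_annotation(X, annotation_task("few", genes[1:5],
                                                     genes), folds = 6),
               "fewer positives")
})

test_that("the annotation suite applies size filters and reports all tasks", {
  genes <- sprintf("g%03d", 1:60)
  ann <- rbind(
    data.frame(gene_id = genes[1:4], annotation_name = "tiny", value = "yes"),
    data.frame(gene_id = genes[1:20], annotation_name = "grp", value = "a"),
    data.frame(gene_id = genes[21:40], annotation_name = "grp", value = "b"),
    data.frame(gene_id = genes[1:39], annotation_name = "small_go",
               value = "x"),
    data.frame(gene_id = genes[1:45], annotation_name = "go", value = "y"))
  X <- rand_emb(60, 4, seed = 3)
  rownames(X) <- genes

  out <- run_annotation_suite(X, ann, min_positives = 5, seed = 1)
  expect_false("tiny" %in% out$annotation)     # 4 positives < 5
  expect_equal(nrow(out), 4L)

  # GO-style size window keeps the 45-gene group, drops the 39-gene one
  out2 <- run_annotation_suite(X, ann, min_positives = 5,
                               group_size_range = c(40, 200), seed = 1)
  expect_equal(out2$annotation, "go")

  expect_warning(
    run_annotation_suite(X, ann[ann$annotation_name == "tiny", ],
                         min_positives = 5, seed = 1), "filtered")
})

test_that("the donor-presence control flags a donor-confounded annotation", {
  set.seed(66)
  n_genes <- 40
  genes <- sprintf("g%03d", seq_len(n_genes))
  donors <- sprintf("d%02d", 1:8)
  conf <- genes[1:10]       # assayed only in donors 1-2
  rows <- lapply(genes, function(g) {
    ds <- if (g %in% conf) sample(donors[1:2], 2)
          else sample(donors, 3)
    data.frame(image_id = paste0(g, "_", ds), gene_id = g, donor_id = ds)
  })
  it <- do.call(rbind, rows)
  pm <- donor_presence_matrix(it)

  confounded <- annotation_task("confounded", conf, genes)
  balanced <- annotation_task("balanced", sample(genes, 10), genes)
  auc_conf <- control_with_presence_matrix(pm, confounded, seed = 3)$auc
  auc_bal <- control_with_presence_matrix(pm, balanced, seed = 3)$auc
  expect_gt(auc_conf, 0.7)
  expect_lt(auc_bal, 0.65)

  # an all-ones presence matrix is uninformative
  ones <- matrix(1, n_genes, 8, dimnames = list(genes, donors))
  expect_equal(control_with_presence_matrix(ones, confounded, seed = 2)$auc,
               0.5)
})

test_that("demographic encoding one-hots categoricals and keeps numerics", {
  dt <- data.frame(donor_id = sprintf("d%d", 1:4),
                   diagnosis = c("control", "schizophrenia", "control",
                                 "schizophrenia"),
                   age = c(30, 40, 50, 60),
                   sex = c("M", "F", "F", "M"),
                   smoker = c("yes", "no", "unknown", "no"),
                   stringsAsFactors = FALSE)
  enc <- encode_demographics(dt)
  X <- enc$features
  expect_equal(rownames(X), dt$donor_id)
  expect_false(any(grepl("diagnosis", colnames(X))))
  expect_equal(unname(X[, "age"]), dt$age)
  sex_cols <- grep("^sex\\.", colnames(X))
  expect_length(sex_cols, 2L)
  expect_equal(unname(rowSums(X[, sex_cols])), rep(1, 4))
  smoker_cols <- grep("^smoker\\.", colnames(X))
  expect_length(smoker_cols, 3L)
  # labels recoverable from the indicators
  lev <- sub("^smoker\\.", "", colnames(X)[smoker_cols])
  rec <- lev[apply(X[, smoker_cols], 1, which.max)]
  expect_identical(rec, dt$smoker)

  num_only <- data.frame(donor_id = c("a", "b"), age = c(1, 2), ph = c(6, 7))
  expect_equal(colnames(encode_demographics(num_only)$features),
               c("age", "ph"))
  expect_error(encode_demographics(dt[0, ]), "empty")
})

make_diag_fixture <- function(n_donors = 24, seed = 1, effect = 2) {
  set.seed(seed)
  donors <- sprintf("d%02d", seq_len(n_donors))
  diag <- rep(c("control", "schizophrenia"), length.out = n_donors)
  dt <- data.frame(donor_id = donors, diagnosis = diag,
                   age = round(runif(n_donors, 25, 60)),
                   sex = sample(c("M", "F"), n_donors, TRUE),
                   stringsAsFactors = FALSE)
  mk <- function(gene, shift) {
    m <- matrix(rnorm(n_donors * 6), n_donors, 6)
    m[, 2] <- m[, 2] + shift * (diag == "schizophrenia")
    rownames(m) <- paste(gene, donors, sep = "|")
    m
  }
  emb <- rbind(mk("gEff", effect), mk("gNull", 0))
  list(donor_table = dt, pair_emb = embedding_matrix(emb, "gene_donor"))
}

test_that("diagnosis prediction recovers a planted effect and not a null", {
  fx <- make_diag_fixture(effect = 3)
  res_eff <- predict_diagnosis(fx$pair_emb, "gEff", fx$donor_table,
                               "embeddings", seed = 2)
  res_null <- predict_diagnosis(fx$pair_emb, "gNull", fx$donor_table,
                                "embeddings", seed = 2)
  expect_gte(res_eff$auc, 0.85)
  expect_gt(res_null$auc, 0.3)
  expect_lt(res_null$auc, 0.7)

  # demographics mode ignores the embeddings entirely
  d1 <- predict_diagnosis(fx$pair_emb, "gEff", fx$donor_table,
                          "demographics", seed = 2)
  d2 <- predict_diagnosis(fx$pair_emb, "gNull", fx$donor_table,
                          "demographics", seed = 2)
  expect_equal(d1$auc, d2$auc)

  # shuffled diagnosis labels: chance
  sh <- fx$donor_table
  set.seed(9)
  sh$diagnosis <- sample(sh$diagnosis)
  res_sh <- predict_diagnosis(fx$pair_emb, "gEff", sh, "embeddings",
                              seed = 2)
  expect_gt(res_sh$auc, 0.2)
  expect_lt(res_sh$auc, 0.8)

  expect_error(predict_diagnosis(fx$pair_emb, "gMissing", fx$donor_table),
               "no embeddings")
  one_class <- fx$donor_table
  one_class$diagnosis <- "control"
  expect_error(predict_diagnosis(fx$pair_emb, "gEff", one_class),
               "single diagnosis")
})

test_that("paired comparison of result tables matches a hand-rolled t-test", {
  a <- data.frame(gene_id = sprintf("g%02d", 1:20),
                  auc = runif(20, 0.4, 0.9))
  same <- compare_embedding_sources(a, a, "auc")
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  b <- a; b$auc <- a$auc + 0.1
  shift <- compare_embedding_sources(a, b, "auc")
  expect_equal(shift$mean_difference, 0.1)
  expect_lt(shift$p_value, 1e-6)

  set.seed(31)
  a2 <- data.frame(gene_id = sprintf("g%02d", 1:62), auc = runif(62))
  b2 <- data.frame(gene_id = a2$gene_id, auc = runif(62))
  got <- compare_embedding_sources(a2, b2, "auc")
  d <- b2$auc - a2$auc
  tref <- mean(d) / (sd(d) / sqrt(62))
  pref <- 2 * pt(-abs(tref), df = 61)
  expect_equal(got$t, tref, tolerance = 1e-9)
  expect_equal(got$p_value, pref, tolerance = 1e-9)

  expect_error(compare_embedding_sources(a[1:2, ], a[1:2, ]), "paired")
})

test_that("extreme-patch selection is exact, tie-stable and labelled", {
  emb <- embedding_matrix(
    matrix(c(-1, 0, 2), ncol = 1, dimnames = list(c("p1", "p2", "p3"))),
    "patch")
  ex1 <- extreme_patches_for_dimension(emb, 1, k = 1)
  expect_equal(ex1$lowest$patch_id, "p1")
  expect_equal(ex1$highest$patch_id, "p3")

  tied <- embedding_matrix(
    matrix(0, 6, 1, dimnames = list(sprintf("p%d", 6:1))), "patch")
  ext <- extreme_patches_for_dimension(tied, 1, k = 2)
  expect_equal(ext$lowest$patch_id, c("p1", "p2"))   # id order breaks ties
  expect_equal(ext$highest$patch_id, c("p6", "p5"))

  big <- rand_emb(100, 5, seed = 7, prefix = "p")
  ptab <- data.frame(patch_id = rownames(big),
                     donor_id = sample(sprintf("d%d", 1:8), 100, TRUE),
                     diagnosis = sample(c("control", "schizophrenia"), 100,
                                        TRUE))
  got <- extreme_patches_for_dimension(embedding_matrix(big, "patch"), 3,
                                       k = 5, patch_table = ptab)
  ord <- order(big[, 3], rownames(big))
  expect_equal(got$lowest$patch_id, rownames(big)[ord[1:5]])
  expect_equal(got$highest$patch_id, rownames(big)[rev(ord)[1:5]])
  expect_true(all(c("donor_id", "diagnosis") %in% names(got$highest)))

  expect_error(extreme_patches_for_dimension(embedding_matrix(big, "patch"),
                                             9, k = 5), "dimension")
})

test_that("the most diagnosis-predictive dimension recovers a planted signal", {
  fx <- make_diag_fixture(effect = 4, seed = 3)
  got <- most_predictive_dimension(fx$pair_emb, "gEff", fx$donor_table,
                                   seed = 4)
  expect_equal(got$dimension, 2L)
  expect_gt(max(got$auc), 0.8)

  one_dim <- embedding_matrix(
    matrix(rnorm(24), 24, 1,
           dimnames = list(paste("g", fx$donor_table$donor_id, sep = "|"))),
    "gene_donor")
  expect_equal(most_predictive_dimension(one_dim, "g", fx$donor_table,
                                         seed = 1)$dimension, 1L)
})

test_that("planted diagnosis effects of growing size raise the AUC", {
  aucs <- vapply(c(0.5, 1.5, 4), function(eff) {
    fx <- make_diag_fixture(effect = eff, seed = 6)
    predict_diagnosis(fx$pair_emb, "gEff", fx$donor_table, "embeddings",
                      seed = 3)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0) || aucs[3] > aucs[1])
  expect_gt(aucs[3], 0.9)
})
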