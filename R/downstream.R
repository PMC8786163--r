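#' Downstream evaluation of embeddings
#'
#' Embeddings are evaluated as features for supervised tasks: binary
#' gene-annotation prediction (one task per annotation label),
#' GO-style group prediction with a donor-presence confounding control,
#' and per-gene schizophrenia diagnosis prediction from (gene, donor)
#' embeddings and/or demographic covariates. All tasks use unpenalized
#' binary logistic regression (max 500 iterations) under stratified
#' 5-fold cross-validation; metrics (AUC, AUC-PR, F1 at probability 0.5)
#' are computed on pooled out-of-fold predictions, and a one-sided
#' Mann-Whitney U test (positives score higher) is run per fold, with
#' the maximum p-value across folds reported.
#'
#' @name downstream
NULL

# midrank (Mann-Whitney) AUC; exactly 0.5 for constant scores
score_auc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision with tie-aware threshold groups
score_auc_pr <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos)
  if (n1 == 0 || all(pos)) return(NA_real_)
  lev <- sort(unique(scores), decreasing = TRUE)
  tp <- 0; fp <- 0; ap <- 0
  for (s in lev) {
    sel <- scores == s
    tp_new <- tp + sum(pos & sel)
    fp_new <- fp + sum(!pos & sel)
    prec <- tp_new / (tp_new + fp_new)
    ap <- ap + (tp_new - tp) / n1 * prec
    tp <- tp_new; fp <- fp_new
  }
  ap
}

score_f1 <- function(scores, labels, threshold = 0.5) {
  pred <- scores >= threshold
  pos <- labels > 0
  tp <- sum(pred & pos)
  denom <- 2 * tp + sum(pred & !pos) + sum(!pred & pos)
  if (denom == 0) return(0)
  2 * tp / denom
}

# round-robin stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

# stratified CV of unpenalized logistic regression; pooled OOF scores
cv_logistic <- function(X, y, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))   # stable formula terms
  y <- as.integer(y > 0)
  fold <- stratified_folds(y, folds, seed)
  scores <- rep(NA_real_, length(y))
  fold_p <- rep(NA_real_, folds)
  skipped <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    df_tr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    df_te <- data.frame(X[te, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df_tr, family = stats::binomial(),
                 control = list(maxit = 500)))
    scores[te] <- suppressWarnings(
      stats::predict(fit, newdata = df_te, type = "response"))
    if (length(unique(y[te])) < 2L) {
      skipped <- skipped + 1L
    } else {
      fold_p[f] <- suppressWarnings(stats::wilcox.test(
        scores[te][y[te] == 1], scores[te][y[te] == 0],
        alternative = "greater", exact = FALSE)$p.value)
    }
  }
  list(scores = scores, y = y, fold = fold,
       max_mwu_p = if (all(is.na(fold_p))) NA_real_ else max(fold_p, na.rm = TRUE),
       folds_skipped = skipped)
}

task_result <- function(cv, seed) {
  structure(list(
    auc = score_auc(cv$scores, cv$y),
    auc_pr = score_auc_pr(cv$scores, cv$y),
    f1 = score_f1(cv$scores, cv$y),
    max_mwu_p = cv$max_mwu_p,
    n_pos = sum(cv$y == 1), n_neg = sum(cv$y == 0),
    folds_skipped = cv$folds_skipped, seed = seed
  ), class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("AUC %.3f  AUC-PR %.3f  F1 %.3f  max MWU p %.3g  (%d pos / %d neg)\n",
              x$auc, x$auc_pr, x$f1, x$max_mwu_p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Define a binary annotation task
#'
#' @param name task label.
#' @param positive_genes character vector of positive gene ids.
#' @param universe ordered character vector of all genes under test.
#' @param min_positives minimum positives for the task to be valid.
#' @return list of class \code{"annotation_task"}.
#' @export
annotation_task <- function(name, positive_genes, universe,
                            min_positives = 5L) {
  positive_genes <- intersect(positive_genes, universe)
  if (length(positive_genes) < min_positives)
    stop_invalid("task '%s' has %d positives (< %d required)", name,
                 length(positive_genes), min_positives)
  if (length(positive_genes) == length(universe))
    stop_invalid("task '%s' has no negatives", name)
  structure(list(name = name, positive_genes = positive_genes,
                 universe = universe,
                 min_positives = as.integer(min_positives)),
            class = "annotation_task")
}

#' Predict a gene annotation from embeddings
#'
#' Stratified k-fold CV of unpenalized logistic regression on gene-level
#' features; metrics on pooled out-of-fold predicted probabilities.
#'
#' @param features matrix with row names covering the task universe
#'   (typically a gene-level \code{\link{embedding_matrix}}).
#' @param task an \code{\link{annotation_task}}.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (fold assignment).
#' @return a \code{task_result} (auc, auc_pr, f1, max_mwu_p, n_pos,
#'   n_neg).
#' @export
predict_annotation <- function(features, task, folds = 5L, seed = 1L) {
  stopifnot(inherits(task, "annotation_task"))
  if (!all(task$universe %in% rownames(features)))
    stop_invalid("features do not cover the task universe")
  if (length(task$positive_genes) < folds)
    stop_invalid("fewer positives (%d) than folds (%d)",
                 length(task$positive_genes), folds)
  X <- unclass(features)[task$universe, , drop = FALSE]
  y <- task$universe %in% task$positive_genes
  task_result(cv_logistic(X, y, folds, seed), seed)
}

#' Run every annotation task in a table
#'
#' One binary task is formed per distinct (annotation_name, value) pair;
#' tasks failing the minimum-positives filter (or, when given, the
#' group-size range, e.g. 40..200 for GO-style groups) are skipped.
#'
#' @param features gene-level feature matrix (row names = gene ids).
#' @param annotation_table data.frame (gene_id, annotation_name, value).
#' @param min_positives minimum positive genes per task (default 5).
#' @param group_size_range optional length-2 numeric: keep tasks whose
#'   positive count lies within the closed range.
#' @param folds,seed CV settings.
#' @return data.frame, one row per retained task, sorted by AUC
#'   (descending): annotation, value, n_pos, n_neg, auc, auc_pr, f1,
#'   max_mwu_p.
#' @export
run_annotation_suite <- function(features, annotation_table,
                                 min_positives = 5L,
                                 group_size_range = NULL, folds = 5L,
                                 seed = 1L) {
  if (nrow(annotation_table) == 0) stop_invalid("empty annotation table")
  universe <- sort(rownames(features))   # unannotated genes count as negatives
  keys <- unique(annotation_table[c("annotation_name", "value")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    an <- keys$annotation_name[i]; val <- keys$value[i]
    pos <- annotation_table$gene_id[annotation_table$annotation_name == an &
                                      annotation_table$value == val]
    pos <- intersect(pos, universe)
    if (length(pos) < min_positives || length(pos) >= length(universe)) next
    if (!is.null(group_size_range) &&
        (length(pos) < group_size_range[1] || length(pos) > group_size_range[2]))
      next
    tk <- annotation_task(paste(an, val, sep = "="), pos, universe,
                          min_positives)
    res <- predict_annotation(features, tk, folds, seed)
    rows[[length(rows) + 1L]] <- data.frame(
      annotation = an, value = val, n_pos = res$n_pos, n_neg = res$n_neg,
      auc = res$auc, auc_pr = res$auc_pr, f1 = res$f1,
      max_mwu_p = res$max_mwu_p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("all annotations filtered out")
    return(data.frame(annotation = character(0), value = character(0),
                      n_pos = integer(0), n_neg = integer(0),
                      auc = numeric(0), auc_pr = numeric(0),
                      f1 = numeric(0), max_mwu_p = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$auc), ]
}

#' Predict an annotation from the donor-presence control matrix
#'
#' Identical protocol to \code{\link{predict_annotation}} but with the
#' binary gene x donor presence matrix as the feature set; a high AUC
#' here flags donor-composition confounding for the task.
#'
#' @param presence binary gene x donor matrix (see
#'   \code{\link{donor_presence_matrix}}).
#' @inheritParams predict_annotation
#' @export
control_with_presence_matrix <- function(presence, task, folds = 5L,
                                         seed = 1L) {
  predict_annotation(presence, task, folds, seed)
}

#' One-hot encode demographic covariates
#'
#' Numeric columns pass through; each categorical column expands to one
#' indicator column per observed level (missing values become their own
#' \code{"missing"} level), so indicator blocks sum to 1 per donor.
#'
#' @param donor_table data.frame with a \code{donor_id} column.
#' @param exclude columns never encoded as features (identity, the
#'   prediction target, and generator internals).
#' @return list with \code{features} (numeric matrix, rownames =
#'   donor_id) and \code{encoding} (named list of level vectors).
#' @export
encode_demographics <- function(donor_table,
                                exclude = c("donor_id", "diagnosis",
                                            "stain_gain",
                                            "tissue_shape_seed")) {
  if (nrow(donor_table) == 0) stop_invalid("empty donor table")
  if (!"donor_id" %in% names(donor_table))
    stop_invalid("donor table needs a donor_id column")
  cols <- setdiff(names(donor_table), exclude)
  blocks <- list(); encoding <- list()
  for (cn in cols) {
    v <- donor_table[[cn]]
    if (is.numeric(v)) {
      blocks[[cn]] <- matrix(v, ncol = 1,
                             dimnames = list(NULL, cn))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      levs <- sort(unique(v))
      encoding[[cn]] <- levs
      ind <- outer(v, levs, "==") * 1
      colnames(ind) <- paste(cn, levs, sep = ".")
      blocks[[cn]] <- ind
    }
  }
  feat <- do.call(cbind, blocks)
  rownames(feat) <- donor_table$donor_id
  list(features = feat, encoding = encoding)
}

# parse "gene|donor" row names of a gene_donor embedding
split_pair_ids <- function(ids) {
  data.frame(gene_id = sub("\\|.*$", "", ids),
             donor_id = sub("^.*\\|", "", ids),
             stringsAsFactors = FALSE)
}

#' Per-gene diagnosis prediction
#'
#' For one gene, each donor contributes one observation: the gene's
#' donor-level embedding and/or the donor's one-hot demographic vector.
#' Diagnosis (schizophrenia vs control) is predicted with stratified
#' k-fold logistic regression; donors, not images, are the CV unit.
#'
#' @param pair_emb (gene, donor)-level \code{\link{embedding_matrix}}
#'   (row names \code{"gene|donor"}).
#' @param gene_id the gene to evaluate.
#' @param donor_table data.frame with donor_id and diagnosis columns.
#' @param feature_mode \code{"embeddings"}, \code{"demographics"} or
#'   \code{"both"}.
#' @param folds,seed CV settings.
#' @param min_donors minimum donors with an embedding for this gene
#'   (default 10; full-scale analyses typically require 50).
#' @return a \code{task_result}.
#' @export
predict_diagnosis <- function(pair_emb, gene_id, donor_table,
                              feature_mode = c("embeddings", "demographics",
                                               "both"),
                              folds = 5L, seed = 1L, min_donors = 10L) {
  feature_mode <- match.arg(feature_mode)
  pairs <- split_pair_ids(rownames(pair_emb))
  sel <- pairs$gene_id == gene_id
  if (!any(sel)) stop_invalid("no embeddings for gene '%s'", gene_id)
  donors <- pairs$donor_id[sel]
  if (length(donors) < min_donors)
    stop_invalid("gene '%s' has embeddings for %d donors (< %d)", gene_id,
                 length(donors), min_donors)
  dt <- donor_table[match(donors, donor_table$donor_id), ]
  y <- dt$diagnosis == "schizophrenia"
  if (length(unique(y)) < 2L)
    stop_invalid("donors for gene '%s' span a single diagnosis class",
                 gene_id)
  emb <- unclass(pair_emb)[sel, , drop = FALSE]
  demo <- encode_demographics(donor_table)$features[donors, , drop = FALSE]
  X <- switch(feature_mode,
              embeddings = emb,
              demographics = demo,
              both = cbind(emb, demo))
  task_result(cv_logistic(X, y, folds, seed), seed)
}

#' Compare two per-gene result tables with a paired t-test
#'
#' Two-sided paired t-test over the shared genes on the chosen metric.
#' If every paired difference is zero the comparison is reported as
#' t = 0, p = 1 by convention.
#'
#' @param results_a,results_b data.frames with \code{gene_id} and the
#'   metric column.
#' @param metric \code{"auc"} or \code{"f1"}.
#' @return list with \code{mean_difference} (b - a), \code{t},
#'   \code{p_value}, \code{n}.
#' @export
compare_embedding_sources <- function(results_a, results_b,
                                      metric = c("auc", "f1")) {
  metric <- match.arg(metric)
  genes <- intersect(results_a$gene_id, results_b$gene_id)
  if (length(genes) < 3) stop_invalid("need >= 3 paired genes")
  a <- results_a[[metric]][match(genes, results_a$gene_id)]
  b <- results_b[[metric]][match(genes, results_b$gene_id)]
  d <- b - a
  if (all(d == 0))
    return(list(mean_difference = 0, t = 0, p_value = 1, n = length(genes)))
  if (stats::sd(d) == 0)
    return(list(mean_difference = mean(d), t = sign(mean(d)) * Inf,
                p_value = 0, n = length(genes)))
  tt <- stats::t.test(b, a, paired = TRUE)
  list(mean_difference = unname(tt$estimate), t = unname(tt$statistic),
       p_value = tt$p.value, n = length(genes))
}

#' Most extreme patches along one embedding dimension
#'
#' Exact bottom-k and top-k patches by the scalar coordinate (1-based
#' dimension index); ties are broken by patch id. Donor (and, when
#' available, diagnosis) labels are attached so donor-uniqueness of the
#' extremes can be checked.
#'
#' @param patch_emb patch-level \code{\link{embedding_matrix}}.
#' @param dimension 1-based coordinate index.
#' @param k number of patches per extreme (default 5).
#' @param patch_table data.frame with patch_id, donor_id (and optional
#'   diagnosis) columns.
#' @return list with \code{lowest} and \code{highest} data.frames
#'   (patch_id, value, donor_id, diagnosis if present).
#' @export
extreme_patches_for_dimension <- function(patch_emb, dimension, k = 5L,
                                          patch_table = NULL) {
  d <- ncol(patch_emb)
  if (dimension < 1 || dimension > d)
    stop_invalid("dimension must be in 1..%d, got %s", d, dimension)
  if (nrow(patch_emb) < 2 * k)
    stop_invalid("need >= 2k = %d patches, have %d", 2 * k, nrow(patch_emb))
  val <- unclass(patch_emb)[, dimension]
  ids <- rownames(patch_emb)
  ord <- order(val, ids)
  take <- function(idx) {
    df <- data.frame(patch_id = ids[idx], value = val[idx],
                     stringsAsFactors = FALSE)
    if (!is.null(patch_table)) {
      m <- match(df$patch_id, patch_table$patch_id)
      df$donor_id <- patch_table$donor_id[m]
      if ("diagnosis" %in% names(patch_table))
        df$diagnosis <- patch_table$diagnosis[m]
    }
    rownames(df) <- NULL
    df
  }
  list(lowest = take(ord[seq_len(k)]),
       highest = take(rev(ord)[seq_len(k)]))
}

#' Embedding dimension most predictive of diagnosis
#'
#' Scores each coordinate as a single-feature logistic CV (AUC) for the
#' diagnosis of the donors carrying the gene's embeddings, and returns
#' the argmax (ties to the lowest index).
#'
#' @inheritParams predict_diagnosis
#' @return list with \code{dimension} (1-based) and \code{auc} (vector
#'   of per-dimension CV AUCs).
#' @export
most_predictive_dimension <- function(pair_emb, gene_id, donor_table,
                                      folds = 5L, seed = 1L,
                                      min_donors = 10L) {
  pairs <- split_pair_ids(rownames(pair_emb))
  sel <- pairs$gene_id == gene_id
  if (!any(sel)) stop_invalid("no embeddings for gene '%s'", gene_id)
  donors <- pairs$donor_id[sel]
  if (length(donors) < min_donors)
    stop_invalid("gene '%s' has embeddings for %d donors (< %d)", gene_id,
                 length(donors), min_donors)
  dt <- donor_table[match(donors, donor_table$donor_id), ]
  y <- dt$diagnosis == "schizophrenia"
  if (length(unique(y)) < 2L)
    stop_invalid("single diagnosis class for gene '%s'", gene_id)
  emb <- unclass(pair_emb)[sel, , drop = FALSE]
  aucs <- vapply(seq_len(ncol(emb)), function(j) {
    cv <- cv_logistic(emb[, j, drop = FALSE], y, folds, seed)
    score_auc(cv$scores, cv$y)
  }, numeric(1))
  list(dimension = which.max(aucs), auc = aucs)
}
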