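#' Gene re-identification metrics
#'
#' Rank-1 accuracy: the fraction of query images whose nearest gallery
#' image (by the stated metric) assays the same gene. The gallery for a
#' query excludes all images from the query's own donor, so the score
#' cannot be earned by recognising donor-specific features. Queries with
#' no same-gene image in their gallery cannot possibly score a hit and
#' are excluded from the denominator (their count is reported).
#'
#' @name reid
NULL

reid_setup <- function(ids, gene_of, donor_of) {
  if (!all(ids %in% names(gene_of)) || !all(ids %in% names(donor_of)))
    stop_invalid("gene/donor maps must cover every image id")
  list(gene = gene_of[ids], donor = donor_of[ids])
}

#' Rank-1 re-identification accuracy with donor exclusion
#'
#' @param emb image-level \code{\link{embedding_matrix}} (row names are
#'   image ids).
#' @param gene_of,donor_of named character vectors mapping image id to
#'   gene / donor.
#' @param metric distance metric (see \code{\link{pairwise_distances}}).
#' @return list of class \code{"reid_result"}: \code{rank1},
#'   \code{n_queries_used}, \code{n_queries_excluded}, \code{hits}.
#' @export
rank1_accuracy <- function(emb, gene_of, donor_of, metric = "euclidean") {
  ids <- rownames(emb)
  if (length(ids) < 2) stop_invalid("need >= 2 images")
  ord <- order(ids)                     # lexicographic id order for ties
  emb <- emb[ord, , drop = FALSE]
  ids <- ids[ord]
  maps <- reid_setup(ids, gene_of, donor_of)
  D <- pairwise_distances(unclass(emb), metric)
  n <- length(ids)
  hits <- 0L; used <- 0L; excluded <- 0L
  for (q in seq_len(n)) {
    gallery <- which(maps$donor != maps$donor[q])
    if (!any(maps$gene[gallery] == maps$gene[q])) {
      excluded <- excluded + 1L
      next
    }
    used <- used + 1L
    nearest <- gallery[which.min(D[q, gallery])]  # first index = smallest id
    if (maps$gene[nearest] == maps$gene[q]) hits <- hits + 1L
  }
  if (used == 0L)
    stop_invalid("every query excluded: no gene has images in >= 2 donors")
  structure(list(rank1 = hits / used, n_queries_used = used,
                 n_queries_excluded = excluded, hits = hits),
            class = "reid_result")
}

#' @export
print.reid_result <- function(x, ...) {
  cat(sprintf("rank-1: %.4f  (%d/%d queries; %d excluded)\n",
              x$rank1, x$hits, x$n_queries_used, x$n_queries_excluded))
  invisible(x)
}

#' Analytic chance baseline for rank-1
#'
#' Expected hit rate when the nearest neighbour is uniform over the
#' query's gallery: the mean over non-excluded queries of
#' (same-gene gallery images) / (gallery size), under the same
#' same-donor exclusion as the metric itself. For a design of G genes
#' with two images each, all donors distinct, this equals 1/(2G - 1)
#' (e.g. 0.63% for 80 genes, 5.26% for 10).
#'
#' @param gene_of,donor_of named character vectors over image ids.
#' @return expected rank-1 under chance, as a fraction.
#' @export
analytic_random_baseline <- function(gene_of, donor_of) {
  ids <- names(gene_of)
  maps <- reid_setup(ids, gene_of, donor_of)
  fracs <- numeric(0)
  for (q in seq_along(ids)) {
    gallery <- which(maps$donor != maps$donor[q])
    same <- sum(maps$gene[gallery] == maps$gene[q])
    if (same == 0) next
    fracs <- c(fracs, same / length(gallery))
  }
  if (length(fracs) == 0)
    stop_invalid("every query excluded: baseline undefined")
  mean(fracs)
}

#' Monte-Carlo chance baseline for rank-1
#'
#' Each repetition assigns every non-excluded query a uniformly random
#' gallery image and scores the resulting rank-1.
#'
#' @inheritParams analytic_random_baseline
#' @param reps number of repetitions (>= 1).
#' @param seed integer seed.
#' @return list with \code{mean} and \code{sd} of the per-rep accuracies.
#' @export
permutation_baseline <- function(gene_of, donor_of, reps = 1000L, seed = 1L) {
  if (reps < 1) stop_invalid("reps must be >= 1")
  ids <- names(gene_of)
  maps <- reid_setup(ids, gene_of, donor_of)
  galleries <- lapply(seq_along(ids), function(q)
    which(maps$donor != maps$donor[q]))
  usable <- which(vapply(seq_along(ids), function(q)
    any(maps$gene[galleries[[q]]] == maps$gene[q]), logical(1)))
  if (length(usable) == 0)
    stop_invalid("every query excluded: baseline undefined")
  with_seed(seed, {
    accs <- vapply(seq_len(reps), function(r) {
      hits <- vapply(usable, function(q) {
        g <- galleries[[q]]
        pick <- g[sample.int(length(g), 1L)]
        maps$gene[pick] == maps$gene[q]
      }, logical(1))
      mean(hits)
    }, numeric(1))
    list(mean = mean(accs), sd = stats::sd(accs))
  })
}

#' Fold increase over a chance baseline
#'
#' @param observed observed rank-1 (fraction).
#' @param baseline chance rank-1 (fraction, > 0).
#' @return observed / baseline, to 3 significant figures.
#' @export
fold_increase <- function(observed, baseline) {
  if (!is.finite(baseline) || baseline <= 0)
    stop_invalid("baseline must be > 0")
  signif(observed / baseline, 3)
}

#' Rank-1 restricted to an image subset
#'
#' Both queries and galleries are restricted to the subset (e.g. one
#' cortical region), then scored as \code{\link{rank1_accuracy}}.
#'
#' @inheritParams rank1_accuracy
#' @param subset_of_images character vector of image ids.
#' @export
rank1_within_subset <- function(emb, gene_of, donor_of, subset_of_images,
                                metric = "euclidean") {
  keep <- intersect(rownames(emb), subset_of_images)
  if (length(keep) == 0) stop_invalid("empty image subset")
  rank1_accuracy(emb[keep, , drop = FALSE], gene_of, donor_of, metric)
}

#' Full re-identification report
#'
#' @inheritParams rank1_accuracy
#' @param reps repetitions for the permutation baseline.
#' @param seed seed for the permutation baseline.
#' @return list of class \code{"reid_report"} with rank1, query counts,
#'   analytic and permutation baselines, and the fold increase of the
#'   observed rank-1 over the analytic baseline.
#' @export
reid_report <- function(emb, gene_of, donor_of, metric = "euclidean",
                        reps = 1000L, seed = 1L) {
  r <- rank1_accuracy(emb, gene_of, donor_of, metric)
  ids <- rownames(emb)
  base <- analytic_random_baseline(gene_of[ids], donor_of[ids])
  perm <- permutation_baseline(gene_of[ids], donor_of[ids], reps, seed)
  structure(list(rank1 = r$rank1, n_queries_used = r$n_queries_used,
                 n_queries_excluded = r$n_queries_excluded,
                 baseline_analytic = base,
                 baseline_permutation_mean = perm$mean,
                 baseline_permutation_sd = perm$sd,
                 fold_increase = fold_increase(r$rank1, base)),
            class = "reid_report")
}

#' @export
print.reid_report <- function(x, ...) {
  cat(sprintf(
    "rank-1 %.2f%% (%.3gx over random %.2f%%); %d queries, %d excluded\n",
    100 * x$rank1, x$fold_increase, 100 * x$baseline_analytic,
    x$n_queries_used, x$n_queries_excluded))
  invisible(x)
}
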