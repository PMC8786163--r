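#' Gene-level train/validation/test splits
#'
#' Genes (not donors or images) are partitioned so that evaluation is on
#' unseen genes; images inherit their gene's set membership and donors
#' are shared across sets by design.
#'
#' @name splits
NULL

#' Split genes into train/validation/test sets
#'
#' Seeded uniform shuffle followed by contiguous slicing; set sizes are
#' chosen by largest-remainder rounding (floors first, remaining seats to
#' the sets with the largest fractional remainders, ties broken in
#' train > validation > test order).
#'
#' @param gene_ids character vector (>= 3 genes).
#' @param fractions positive length-3 numeric summing to 1 (default
#'   0.8 / 0.1 / 0.1).
#' @param seed integer seed.
#' @return list of class \code{"gene_split"} with \code{train},
#'   \code{validation}, \code{test}, \code{seed}, \code{fractions}.
#' @export
split_genes <- function(gene_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  gene_ids <- unique(as.character(gene_ids))
  if (length(gene_ids) < 3) stop_invalid("need >= 3 genes to split")
  if (length(fractions) != 3 || any(fractions <= 0))
    stop_invalid("fractions must be 3 positive numbers")
  fractions <- fractions / sum(fractions)
  n <- length(gene_ids)
  ideal <- n * fractions
  sizes <- floor(ideal)
  rem <- ideal - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[give] <- sizes[give] + 1L
  }
  shuffled <- with_seed(seed, sample(gene_ids))
  cuts <- cumsum(sizes)
  structure(list(
    train = sort(shuffled[seq_len(sizes[1])]),
    validation = sort(shuffled[(cuts[1] + 1):cuts[2]]),
    test = sort(shuffled[(cuts[2] + 1):cuts[3]]),
    seed = as.integer(seed), fractions = fractions
  ), class = "gene_split")
}

#' @export
print.gene_split <- function(x, ...) {
  cat(sprintf("<gene_split> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  if (!is.null(attr(x, "excluded")))
    cat(sprintf("  %d genes excluded\n", length(attr(x, "excluded"))))
  invisible(x)
}

#' Remove genes from a split
#'
#' Drops the listed genes from all three sets (e.g. genes shared with an
#' external evaluation study); the removal is recorded in the
#' \code{"excluded"} attribute.
#'
#' @param split a \code{\link{split_genes}} result.
#' @param genes_to_drop character vector of gene ids.
#' @return the reduced \code{gene_split}.
#' @export
exclude_genes <- function(split, genes_to_drop) {
  genes_to_drop <- as.character(genes_to_drop)
  out <- split
  out$train <- setdiff(split$train, genes_to_drop)
  out$validation <- setdiff(split$validation, genes_to_drop)
  out$test <- setdiff(split$test, genes_to_drop)
  if (length(out$test) == 0 && length(split$test) > 0)
    warning("test set is empty after exclusion")
  attr(out, "excluded") <- union(attr(split, "excluded"), genes_to_drop)
  out
}
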