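#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage sub-seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' (and each item within a stage) draws its own deterministic sub-seed so
#' stages can be re-run independently yet reproducibly.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. \code{"render"}).
#' @param index optional integer index within the stage.
#' @return an integer seed in \code{[0, 2^31)}.
#' @export
substream_seed <- function(master, stage, index = 0L) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  val <- (as.double(master) * 2654435761 + h * 97 + as.double(index) * 7919) %% 2147483647
  as.integer(val)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# luminance in [0,1] from a grayscale matrix or H x W x 3 array
luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3)
    return(0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3])
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) return(img[, , 1])
  stop_invalid("unsupported image array with %d dimensions", length(dim(img)))
}

#' Construct an embedding matrix
#'
#' A thin wrapper around a numeric matrix: rows are entities (row names hold
#' the ids), columns are embedding coordinates, and the aggregation level
#' (patch, image, donor, gene, or gene_donor) is recorded as an attribute.
#'
#' @param x numeric matrix with row names.
#' @param level one of \code{"patch"}, \code{"image"}, \code{"gene_donor"},
#'   \code{"donor"}, \code{"gene"}.
#' @return the matrix, classed \code{"embedding_matrix"}.
#' @export
embedding_matrix <- function(x, level) {
  level <- match.arg(level, c("patch", "image", "gene_donor", "donor", "gene"))
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop_invalid("embedding matrix needs row names (entity ids)")
  if (anyDuplicated(rownames(x))) stop_invalid("duplicate entity ids in embedding matrix")
  if (!all(is.finite(x))) stop_invalid("non-finite values in embedding matrix")
  attr(x, "level") <- level
  class(x) <- c("embedding_matrix", class(x))
  x
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat(sprintf("<embedding_matrix> level=%s  %d x %d\n",
              attr(x, "level"), nrow(x), ncol(x)))
  invisible(x)
}

embedding_level <- function(x) attr(x, "level")
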