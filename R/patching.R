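#' Random foreground patch extraction
#'
#' Square patches are sampled at uniformly random positions inside the
#' image; a candidate window is kept only if at least a minimum fraction
#' (default 90%) of its pixels are tissue foreground according to the
#' (upsampled) mask. Sampling stops after a maximum number of accepted
#' patches (default 50) or a maximum number of attempts (default 500).
#' Accepted windows are downsampled by area averaging from the source
#' side (default 1024) to the output side (default 256).
#'
#' @name patching
NULL

#' Patch extraction configuration
#'
#' @param source_side_px side of the sampling window in the source image.
#' @param output_side_px side after area-average downsampling.
#' @param max_patches maximum accepted patches per image.
#' @param max_attempts maximum random draws per image.
#' @param min_foreground_fraction acceptance threshold in (0, 1].
#' @return list of class \code{"patch_config"}.
#' @export
patch_config <- function(source_side_px = 1024L, output_side_px = 256L,
                         max_patches = 50L, max_attempts = 500L,
                         min_foreground_fraction = 0.90) {
  if (min_foreground_fraction <= 0 || min_foreground_fraction > 1)
    stop_invalid("min_foreground_fraction must be in (0, 1]")
  if (output_side_px > source_side_px)
    stop_invalid("output_side_px must be <= source_side_px")
  if (max_patches > max_attempts)
    stop_invalid("max_patches must be <= max_attempts")
  structure(list(source_side_px = as.integer(source_side_px),
                 output_side_px = as.integer(output_side_px),
                 max_patches = as.integer(max_patches),
                 max_attempts = as.integer(max_attempts),
                 min_foreground_fraction = min_foreground_fraction),
            class = "patch_config")
}

#' Foreground fraction of a window
#'
#' @param mask 0/1 matrix at image scale.
#' @param x,y 0-based top-left corner of the window (x = column,
#'   y = row); the window is half-open.
#' @param side window side in pixels.
#' @return (# foreground pixels in the window) / side^2.
#' @export
foreground_fraction <- function(mask, x, y, side) {
  if (x < 0 || y < 0 || y + side > nrow(mask) || x + side > ncol(mask))
    stop_invalid("window [%d, %d) x [%d, %d) outside mask dims %d x %d",
                 x, x + side, y, y + side, ncol(mask), nrow(mask))
  sum(mask[(y + 1):(y + side), (x + 1):(x + side)] > 0) / side^2
}

#' Sample random foreground patches from one image
#'
#' Corner positions are drawn uniformly with replacement (duplicates
#' allowed); determinism is guaranteed by the seed. If the image is
#' smaller than the source window in either dimension an empty patch set
#' is returned with a \code{reason} attribute.
#'
#' @param image grayscale matrix in [0,1].
#' @param mask 0/1 matrix; either at image scale or coarser (it is then
#'   upsampled with \code{\link{upsample_mask}}).
#' @param config a \code{\link{patch_config}}.
#' @param seed integer seed.
#' @param image_id id recorded in the coordinate table.
#' @return list of class \code{"patch_set"}: \code{patches} (named list
#'   of output_side_px matrices), \code{coords} (data.frame image_id,
#'   patch_id, x, y, attempt_index, seed), \code{n_attempts}.
#' @export
sample_patches <- function(image, mask, config = patch_config(), seed = 1L,
                           image_id = "img") {
  h <- nrow(image); w <- ncol(image)
  src <- config$source_side_px
  if (h < src || w < src) {
    out <- list(patches = list(),
                coords = data.frame(image_id = character(0),
                                    patch_id = character(0), x = integer(0),
                                    y = integer(0), attempt_index = integer(0),
                                    seed = integer(0)),
                n_attempts = 0L)
    attr(out, "reason") <- sprintf(
      "image %d x %d smaller than source side %d", w, h, src)
    class(out) <- "patch_set"
    return(out)
  }
  if (nrow(mask) != h || ncol(mask) != w) {
    if (nrow(mask) > h || ncol(mask) > w)
      stop_invalid("mask (%d x %d) larger than image (%d x %d)",
                   nrow(mask), ncol(mask), h, w)
    side <- max(h, w)   # masks are built on the white-padded square image
    mask <- upsample_mask(mask, side, side)[seq_len(h), seq_len(w), drop = FALSE]
  }
  with_seed(seed, {
    xs <- integer(0); ys <- integer(0); att <- integer(0)
    patches <- list()
    attempts <- 0L
    while (attempts < config$max_attempts &&
           length(patches) < config$max_patches) {
      attempts <- attempts + 1L
      x <- sample.int(w - src + 1L, 1L) - 1L
      y <- sample.int(h - src + 1L, 1L) - 1L
      if (foreground_fraction(mask, x, y, src) >=
          config$min_foreground_fraction) {
        win <- image[(y + 1):(y + src), (x + 1):(x + src)]
        patches[[length(patches) + 1L]] <-
          downsample_to(win, config$output_side_px)
        xs <- c(xs, x); ys <- c(ys, y); att <- c(att, attempts)
      }
    }
    ids <- sprintf("%s_p%03d", image_id, seq_along(patches))
    names(patches) <- ids
    structure(list(
      patches = patches,
      coords = data.frame(image_id = rep(image_id, length(patches)),
                          patch_id = ids, x = xs, y = ys,
                          attempt_index = att,
                          seed = rep(as.integer(seed), length(patches)),
                          stringsAsFactors = FALSE),
      n_attempts = attempts), class = "patch_set")
  })
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d attempts)\n",
              length(x$patches), x$n_attempts))
  if (!is.null(attr(x, "reason"))) cat("  reason:", attr(x, "reason"), "\n")
  invisible(x)
}

#' Extract patches for every image of a study
#'
#' Runs the mask + patch pipeline over a study bundle: computes (or takes
#' from truth) a foreground mask per image and samples patches. Per-image
#' seeds derive from \code{seed}.
#'
#' @param study an \code{ish_study} (or a list with \code{images} and
#'   \code{image_table}).
#' @param config a \code{\link{patch_config}}.
#' @param seg_config a \code{\link{segmentation_config}} used when
#'   \code{use_truth_masks} is FALSE.
#' @param use_truth_masks use the generator's truth masks instead of
#'   computed ones.
#' @param seed master seed for per-image sub-seeds.
#' @return list with \code{patches} (named list across all images) and
#'   \code{patch_table} (patch_id, image_id, gene_id, donor_id, x, y,
#'   attempt_index).
#' @export
extract_study_patches <- function(study, config = patch_config(),
                                  seg_config = segmentation_config(),
                                  use_truth_masks = FALSE, seed = 1L) {
  it <- study$image_table
  all_patches <- list()
  rows <- vector("list", nrow(it))
  for (i in seq_len(nrow(it))) {
    iid <- it$image_id[i]
    img <- study$images[[iid]]
    mask <- if (use_truth_masks) {
      (study$truth_masks[[iid]] > 0) * 1L
    } else {
      threshold_mask(img, seg_config)
    }
    ps <- sample_patches(img, mask, config,
                         seed = substream_seed(seed, "patch", i),
                         image_id = iid)
    all_patches <- c(all_patches, ps$patches)
    if (nrow(ps$coords) > 0) {
      co <- ps$coords
      co$gene_id <- it$gene_id[i]
      co$donor_id <- it$donor_id[i]
      rows[[i]] <- co
    }
  }
  patch_table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(patches = all_patches, patch_table = patch_table)
}
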