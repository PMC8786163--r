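#' Tissue-foreground segmentation
#'
#' Full images are padded to squares with white, downsampled to a small
#' working resolution (default 224 px), and segmented into tissue
#' foreground vs background. The default method is a deterministic
#' luminance threshold with small-component removal and morphological
#' closing; a small trainable encoder-decoder model
#' (\code{\link{mask_model}}) is available as a drop-in alternative.
#' Coarse masks are upsampled back to image scale (nearest neighbour)
#' before patch filtering.
#'
#' @name segmentation
NULL

#' Segmentation configuration
#'
#' @param working_side_px working resolution (>= 32, default 224).
#' @param method \code{"threshold"} or \code{"unet"}.
#' @param threshold_quantile foreground iff luminance < quantile x white
#'   level (default 0.95).
#' @param min_component_px connected components smaller than this are
#'   dropped (default 16 at 224 scale).
#' @return list of class \code{"segmentation_config"}.
#' @export
segmentation_config <- function(working_side_px = 224L,
                                method = c("threshold", "unet"),
                                threshold_quantile = 0.95,
                                min_component_px = 16L) {
  if (working_side_px < 32) stop_invalid("working_side_px must be >= 32")
  structure(list(working_side_px = as.integer(working_side_px),
                 method = match.arg(method),
                 threshold_quantile = threshold_quantile,
                 min_component_px = as.integer(min_component_px)),
            class = "segmentation_config")
}

#' Pad an image to a square with white
#'
#' Output side is max(height, width); original content is anchored at the
#' top-left corner and padding pixels are pure white (the maximum channel
#' value, 1 on the [0,1] scale).
#'
#' @param image grayscale matrix or H x W x C array with values in [0,1].
#' @return the padded image, same number of channels.
#' @export
pad_to_square_white <- function(image) {
  d <- dim(image)
  if (is.null(d) || any(d == 0)) stop_invalid("empty image")
  h <- d[1]; w <- d[2]
  if (h == w) return(image)
  side <- max(h, w)
  if (length(d) == 2L) {
    out <- matrix(1, side, side)
    out[seq_len(h), seq_len(w)] <- image
  } else {
    out <- array(1, c(side, side, d[3]))
    out[seq_len(h), seq_len(w), ] <- image
  }
  out
}

# area-average downsample of a matrix to side x side; pads to square
# first so aspect is preserved under the package's padding convention.
downsample_to <- function(img, side) {
  img <- pad_to_square_white(luminance(img))
  n <- nrow(img)
  if (n == side) return(img)
  if (n %% side == 0L) {
    f <- n %/% side
    # exact block mean via row/col group sums
    g <- rowsum(img, rep(seq_len(side), each = f)) / f
    t(rowsum(t(g), rep(seq_len(side), each = f))) / f
  } else {
    as.matrix(EBImage::resize(EBImage::Image(img), w = side, h = side,
                              antialias = TRUE))
  }
}

#' Threshold-based foreground mask
#'
#' Downsamples the (white-padded) image to the working resolution; a pixel
#' is foreground iff its luminance is below
#' \code{threshold_quantile} x the white level (1.0). Components smaller
#' than \code{min_component_px} are removed and a 3x3 morphological
#' closing is applied.
#'
#' @param image grayscale matrix or RGB array in [0,1].
#' @param config a \code{\link{segmentation_config}}.
#' @return integer 0/1 matrix of size working_side_px^2, with attributes
#'   \code{working_side_px} and \code{threshold}.
#' @export
threshold_mask <- function(image, config = segmentation_config()) {
  small <- downsample_to(image, config$working_side_px)
  m <- (small < config$threshold_quantile * 1.0) * 1L
  m <- prune_components(m, config$min_component_px)
  kern <- EBImage::makeBrush(3, shape = "box")
  m <- EBImage::closing(matrix(as.numeric(m), nrow(m)), kern)
  m <- matrix(as.integer(m > 0.5), nrow(m))
  attr(m, "working_side_px") <- config$working_side_px
  attr(m, "threshold") <- config$threshold_quantile
  m
}

prune_components <- function(mask01, min_px) {
  if (min_px <= 1L || !any(mask01 > 0)) return(mask01)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask01), nrow(mask01)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab %in% keep), nrow(mask01))
}

#' Upsample a binary mask (nearest neighbour)
#'
#' Each target pixel takes the value of its source pixel under the floor
#' index map; for integer scale factors this is exact block expansion and
#' preserves the foreground fraction exactly. Differing aspect is handled
#' by the same top-left square padding convention (padding = background).
#'
#' @param mask 0/1 matrix.
#' @param target_h,target_w target dimensions (>= mask dimensions).
#' @return 0/1 integer matrix of size target_h x target_w.
#' @export
upsample_mask <- function(mask, target_h, target_w) {
  mh <- nrow(mask); mw <- ncol(mask)
  if (target_h < mh || target_w < mw)
    stop_invalid("target dims (%d x %d) smaller than mask (%d x %d)",
                 target_h, target_w, mh, mw)
  ri <- floor((seq_len(target_h) - 1) * mh / target_h) + 1L
  ci <- floor((seq_len(target_w) - 1) * mw / target_w) + 1L
  matrix(as.integer(mask[ri, ci]), target_h, target_w)
}

#' Jaccard overlap of two binary masks
#'
#' @param a,b 0/1 matrices of equal size.
#' @return intersection over union; 1 when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Compute a foreground mask for an image
#'
#' Dispatches on the configured method: the deterministic threshold
#' masker or a trained \code{\link{mask_model}}.
#'
#' @param image grayscale or RGB image in [0,1].
#' @param config a \code{\link{segmentation_config}}.
#' @param model a trained \code{mask_model} (required for method "unet").
#' @return 0/1 matrix at working resolution.
#' @export
compute_mask <- function(image, config = segmentation_config(), model = NULL) {
  if (config$method == "threshold") return(threshold_mask(image, config))
  if (is.null(model)) stop_invalid("method 'unet' needs a trained mask model")
  predict(model, image)
}
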