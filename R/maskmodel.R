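#' Trainable encoder-decoder tissue segmenter
#'
#' A compact convolutional encoder-decoder (conv -> pool -> conv ->
#' nearest-neighbour upsample -> conv -> sigmoid) trained with pixel-wise
#' binary cross-entropy on (image, mask) pairs at the working resolution.
#' It is a drop-in alternative to \code{\link{threshold_mask}} for the
#' same job: coarse tissue-foreground masks used only to filter patches.
#'
#' @param pairs list of lists with elements \code{image} (grayscale
#'   matrix in [0,1]) and \code{mask} (0/1 matrix); at least 2 pairs.
#' @param config a \code{\link{segmentation_config}}; images and masks
#'   are resized to \code{working_side_px}.
#' @param steps number of Adam steps (full-batch).
#' @param learning_rate Adam learning rate.
#' @param filters channel widths of the two hidden conv layers.
#' @param seed integer seed for initialisation.
#' @return object of class \code{"mask_model"} with a \code{loss_trace}.
#' @export
mask_model <- function(pairs, config = segmentation_config(working_side_px = 64L),
                       steps = 50L, learning_rate = 0.02,
                       filters = c(8L, 8L), seed = 1L) {
  if (length(pairs) < 2L) stop_invalid("need >= 2 labelled (image, mask) pairs")
  side <- config$working_side_px
  if (side %% 2L != 0L) stop_invalid("working_side_px must be even")
  xs <- lapply(pairs, function(p) downsample_to(p$image, side))
  ys <- lapply(pairs, function(p) {
    m <- p$mask
    if (nrow(m) != side) m <- (downsample_to(matrix(as.numeric(m > 0),
                                                    nrow(m)), side) >= 0.5) * 1
    matrix(as.numeric(m > 0), side, side)
  })
  B <- length(xs)
  x <- stack_patches(xs)
  y <- array(unlist(ys), c(side, side, B, 1L))

  net <- with_seed(seed, list(
    params = list(
      W1 = he_init(9, filters[1], 9), b1 = rep(0, filters[1]),
      W2 = he_init(9 * filters[1], filters[2], 9 * filters[1]),
      b2 = rep(0, filters[2]),
      W3 = he_init(9 * filters[2], 1L, 9 * filters[2]), b3 = 0
    ),
    filters = filters, side = side
  ))

  forward <- function(net, x, keep = FALSE) {
    p <- net$params
    x <- (x - 0.9) * 5                  # centre the stain scale
    c1 <- conv_forward(x, p$W1, p$b1, keep_M = keep)
    r1 <- pmax(c1$y, 0)
    d1 <- avgpool2_forward(r1)
    c2 <- conv_forward(d1, p$W2, p$b2, keep_M = keep)
    r2 <- pmax(c2$y, 0)
    u2 <- upsample2_forward(r2)
    c3 <- conv_forward(u2, p$W3, p$b3, keep_M = keep)
    prob <- 1 / (1 + exp(-c3$y))
    if (!keep) return(list(prob = prob))
    list(prob = prob, cache = list(c1 = c1, r1 = r1, d1 = d1, c2 = c2,
                                   r2 = r2, u2 = u2, c3 = c3))
  }

  opt <- adam_init(net$params)
  trace <- data.frame(step = seq_len(steps), loss = NA_real_)
  for (s in seq_len(steps)) {
    fw <- forward(net, x, keep = TRUE)
    p_hat <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
    loss <- -mean(y * log(p_hat) + (1 - y) * log(1 - p_hat))
    n_el <- length(y)
    dlogits <- (fw$prob - y) / n_el
    ca <- fw$cache
    g3 <- conv_backward(dlogits, ca$c3$M, net$params$W3, filters[2])
    dr2 <- upsample2_backward(g3$dx)
    dr2 <- dr2 * (ca$c2$y > 0)
    g2 <- conv_backward(dr2, ca$c2$M, net$params$W2, filters[1])
    dr1 <- avgpool2_backward(g2$dx, dim(ca$r1))
    dr1 <- dr1 * (ca$c1$y > 0)
    g1 <- conv_backward(dr1, ca$c1$M, net$params$W1, 1L, need_dx = FALSE)
    grads <- list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                  W3 = g3$dW, b3 = g3$db)
    upd <- adam_step(net$params, grads, opt, learning_rate)
    net$params <- upd$params
    opt <- upd$state
    trace$loss[s] <- loss
  }
  structure(list(net = net, forward = forward, config = config,
                 loss_trace = trace), class = "mask_model")
}

#' Train a mask model from labelled pairs
#'
#' Functional alias for \code{\link{mask_model}} taking pairs first.
#'
#' @inheritParams mask_model
#' @param ... passed to \code{\link{mask_model}}.
#' @export
train_mask_model <- function(pairs, config = segmentation_config(working_side_px = 64L),
                             seed = 1L, ...) {
  mask_model(pairs, config = config, seed = seed, ...)
}

#' @export
print.mask_model <- function(x, ...) {
  cat(sprintf("<mask_model> encoder-decoder @ %dpx, trained %d steps (final BCE %.4f)\n",
              x$net$side, nrow(x$loss_trace),
              x$loss_trace$loss[nrow(x$loss_trace)]))
  invisible(x)
}

#' Predict a foreground mask for an image
#'
#' @param object a trained \code{mask_model}.
#' @param image grayscale or RGB image in [0,1].
#' @param ... unused.
#' @return 0/1 matrix at the model's working resolution.
#' @export
predict.mask_model <- function(object, image, ...) {
  xs <- downsample_to(image, object$net$side)
  x <- stack_patches(list(xs))
  prob <- object$forward(object$net, x)$prob
  m <- matrix(as.integer(prob[, , 1, 1] > 0.5), object$net$side)
  attr(m, "working_side_px") <- object$net$side
  m
}
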