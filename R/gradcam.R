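# Gradient-weighted class activation maps ------------------------------------------

# Identify the capture point for "the last convolution of the last stage":
# the final conv leaf inside the branch of the last block of stage 4.
default_cam_layer <- function(model) {
  nms <- names(model$nodes)
  s4 <- grep("^s4b", nms, value = TRUE)
  last_blk <- s4[length(s4)]
  branch <- model$nodes[[last_blk]]$blk$branch
  conv_idx <- which(vapply(branch, function(l) l$kind == "conv", logical(1)))
  sprintf("%s.branch.%d", last_blk, max(conv_idx))
}

cam_layer_exists <- function(model, layer) {
  parts <- strsplit(layer, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(parts %in% names(model$nodes))
  if (length(parts) != 3L) return(FALSE)
  node <- model$nodes[[parts[1]]]
  if (is.null(node) || node$kind != "block") return(FALSE)
  i <- suppressWarnings(as.integer(parts[3]))
  !is.na(i) && parts[2] %in% c("branch", "shortcut", "post") &&
    i >= 1L && i <= length(node$blk[[parts[2]]])
}

#' Grad-CAM heatmap for one image
#'
#' Computes the gradient of the target class score with respect to the feature
#' maps of a chosen convolutional layer, averages the gradient spatially to
#' obtain one weight per channel, forms the rectified weighted sum of the
#' feature maps, min-max normalises it to `[0, 1]` (a constant map yields all
#' zeros), and bilinearly upsamples to the input's spatial size.
#'
#' @param model A `seednet_model` (fitted or freshly initialised).
#' @param image `H x W x 3` array, values 0..255.
#' @param target_class Class index in 1..K.
#' @param layer Capture point, `"<node>.<part>.<index>"`; default is the last
#'   convolution of the last stage.
#' @return `H x W` matrix in `[0, 1]` of class `gradcam`.
#' @export
grad_cam <- function(model, image, target_class, layer = NULL) {
  if (is.null(layer)) layer <- default_cam_layer(model)
  if (!cam_layer_exists(model, layer)) {
    stop("unknown layer: ", layer, call. = FALSE)
  }
  stopifnot(target_class >= 1L, target_class <= model$cfg$num_classes)
  x <- images_to_batch(list(image))
  fw <- model_forward(model, x, training = FALSE, capture_id = layer)
  if (is.null(fw$captured)) stop("layer produced no capture: ", layer, call. = FALSE)
  dlogits <- matrix(0, model$cfg$num_classes, 1L)
  dlogits[target_class, 1L] <- 1
  bw <- model_backward(fw$model, fw$caches, dlogits, capture_id = layer)
  act <- fw$captured$out
  grd <- bw$captured_grad
  d <- dim(act)
  weights <- rowMeans(matrix(grd, nrow = d[1]))
  cam <- matrix(colSums(matrix(as.numeric(act), nrow = d[1]) * weights),
                d[2], d[3])
  cam <- pmax(cam, 0)
  rng <- range(cam)
  cam <- if (diff(rng) == 0) matrix(0, d[2], d[3]) else (cam - rng[1]) / diff(rng)
  out <- upsample_bilinear(cam, dim(image)[1], dim(image)[2])
  structure(out, class = c("gradcam", class(out)))
}

# Bilinear upsampling with half-pixel centre alignment.
upsample_bilinear <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  sy <- in_h / out_h; sx <- in_w / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), in_h - 1)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), in_w - 1)
  y0 <- pmin(floor(yc), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(floor(xc), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- yc - y0; wx <- xc - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - wy, 1 - wx)
  b <- m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - wy, wx)
  cc <- m[y1 + 1, x0 + 1, drop = FALSE] * outer(wy, 1 - wx)
  d <- m[y1 + 1, x1 + 1, drop = FALSE] * outer(wy, wx)
  a + b + cc + d
}
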