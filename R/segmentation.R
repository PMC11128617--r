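# Multi-seed scene segmentation ---------------------------------------------------
#
# Scene photograph -> grayscale -> automatic global threshold -> morphological
# cleaning -> connected components -> fixed-size single-seed crops centred on
# component centroids. Standard image operations (threshold selection,
# disk morphology, hole filling, component labelling) are delegated to EBImage.

#' Segmentation parameters
#'
#' @param threshold `"otsu_auto"` (between-class-variance maximisation) or
#'   `"fixed"` with `fixed_value` in 0..255.
#' @param fixed_value Grey-level threshold when `threshold = "fixed"`.
#' @param morph_open_radius Disk radius (pixels) of the morphological opening.
#' @param morph_close_radius Disk radius of the closing.
#' @param min_area Components smaller than this (pixels^2) are discarded.
#' @param crop_size Side of the square crop extracted per seed (>= 32).
#' @param background_fill Grey level used to pad crops that extend past the
#'   image border.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold = c("otsu_auto", "fixed"),
                                fixed_value = 128,
                                morph_open_radius = 3L,
                                morph_close_radius = 3L,
                                min_area = 400L,
                                crop_size = 224L,
                                background_fill = 12) {
  threshold <- match.arg(threshold)
  stopifnot(crop_size >= 32L, morph_open_radius >= 0L,
            morph_close_radius >= 0L, min_area >= 1L)
  if (threshold == "fixed") stopifnot(fixed_value >= 0, fixed_value <= 255)
  structure(list(threshold = threshold, fixed_value = fixed_value,
                 morph_open_radius = as.integer(morph_open_radius),
                 morph_close_radius = as.integer(morph_close_radius),
                 min_area = as.integer(min_area),
                 crop_size = as.integer(crop_size),
                 background_fill = background_fill),
            class = "segmentation_params")
}

#' Convert an RGB image to 8-bit luminance
#'
#' `0.299 R + 0.587 G + 0.114 B`, rounded to integer grey levels.
#'
#' @param rgb `H x W x 3` numeric array, values 0..255.
#' @return `H x W` integer-valued matrix.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("input must be an H x W x 3 array", call. = FALSE)
  }
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  g <- round(pmin(pmax(g, 0), 255))
  matrix(g, dim(rgb)[1], dim(rgb)[2])
}

#' Binarise a grayscale image by automatic global thresholding
#'
#' Foreground is everything above the threshold that maximises between-class
#' variance over the 256 grey levels (Otsu's criterion), or above a fixed
#' threshold. A constant image has no separable classes: an empty mask is
#' returned with a warning.
#'
#' @param gray `H x W` matrix of grey levels 0..255.
#' @param params A [segmentation_params()].
#' @return Binary `H x W` matrix (0/1) with attribute `"threshold"`.
#' @export
binarize <- function(gray, params = segmentation_params()) {
  stopifnot(is.matrix(gray))
  if (diff(range(gray)) == 0) {
    warning("constant image: threshold is degenerate, returning empty mask",
            call. = FALSE)
    m <- matrix(0L, nrow(gray), ncol(gray))
    attr(m, "threshold") <- NA_real_
    return(m)
  }
  thr <- if (params$threshold == "fixed") {
    params$fixed_value
  } else {
    255 * EBImage::otsu(gray / 255, range = c(0, 1), levels = 256)
  }
  m <- (gray > thr) * 1L
  attr(m, "threshold") <- thr
  m
}

disk_kernel <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

#' Morphologically clean a binary mask
#'
#' Opening (removes speckle smaller than the opening disk), closing (bridges
#' small gaps), hole filling, then rejection of components below `min_area`.
#'
#' @param mask Binary `H x W` matrix.
#' @param params A [segmentation_params()].
#' @return Cleaned binary matrix.
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  m <- mask
  storage.mode(m) <- "double"
  if (params$morph_open_radius > 0) {
    m <- EBImage::opening(m, disk_kernel(params$morph_open_radius))
  }
  if (params$morph_close_radius > 0) {
    m <- EBImage::closing(m, disk_kernel(params$morph_close_radius))
  }
  m <- EBImage::fillHull(m)
  lab <- label_components(m)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < params$min_area)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  out <- (m > 0) * 1L
  dim(out) <- dim(mask)
  out
}

# 8-connected component labelling: EBImage's bwlabel is 4-connected, so close
# diagonal links first by labelling a one-pixel dilation and restricting the
# labels to the original mask.
label_components <- function(mask) {
  m <- (mask > 0) * 1
  dil <- EBImage::dilate(m, matrix(1, 3, 3))
  lab <- EBImage::bwlabel(dil)
  lab <- as.matrix(lab) * m
  # relabel to consecutive ids over the original mask
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) lab <- matrix(match(lab, ids, nomatch = 0L), nrow(m), ncol(m))
  lab
}

#' Extract single-seed crops from a scene
#'
#' Labels the mask's 8-connected components, keeps those with at least
#' `min_area` pixels, and cuts one `crop_size x crop_size` window per
#' component, centred on its centroid; windows clipped by the image border are
#' padded with `background_fill`. Crops are ordered row-major by centroid.
#'
#' @param rgb `H x W x 3` scene image (0..255).
#' @param mask Binary matrix of the same spatial size.
#' @param params A [segmentation_params()].
#' @param source_id Identifier prefix recorded on each crop.
#' @return A `seed_crops` list; each element has `image` (crop), `centroid`
#'   (row, col), `area` (pixels), `source_id`. See [crop_manifest()].
#' @export
extract_seeds <- function(rgb, mask, params = segmentation_params(),
                          source_id = "scene") {
  stopifnot(all(dim(mask) == dim(rgb)[1:2]))
  lab <- label_components(mask)
  n <- max(lab)
  crops <- list()
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(areas >= params$min_area)
    if (length(keep)) {
      idx <- which(lab > 0, arr.ind = TRUE)
      ids <- lab[lab > 0]
      crow <- rowsum(as.numeric(idx[, 1]), ids)[, 1] / tabulate(ids, n)
      ccol <- rowsum(as.numeric(idx[, 2]), ids)[, 1] / tabulate(ids, n)
      ord <- keep[order(round(crow[keep]), round(ccol[keep]))]
      for (j in seq_along(ord)) {
        id <- ord[j]
        crops[[j]] <- list(
          image = crop_window(rgb, crow[id], ccol[id], params$crop_size,
                              params$background_fill),
          centroid = c(row = unname(crow[id]), col = unname(ccol[id])),
          area = areas[id],
          source_id = sprintf("%s_%02d", source_id, j)
        )
      }
    }
  }
  structure(crops, class = "seed_crops")
}

crop_window <- function(rgb, cy, cx, size, fill) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  r0 <- round(cy) - size %/% 2L
  c0 <- round(cx) - size %/% 2L
  out <- array(fill, dim = c(size, size, 3))
  rr <- max(1L, r0):min(h, r0 + size - 1L)
  cc <- max(1L, c0):min(w, c0 + size - 1L)
  if (length(rr) > 0 && length(cc) > 0) {
    out[rr - r0 + 1L, cc - c0 + 1L, ] <- rgb[rr, cc, ]
  }
  out
}

#' Tabulate extracted crops
#'
#' @param crops A `seed_crops` list from [extract_seeds()].
#' @return A tibble with one row per crop: `source_id`, `centroid_row`,
#'   `centroid_col`, `area`.
#' @export
crop_manifest <- function(crops) {
  tibble::tibble(
    source_id = vapply(crops, function(cr) cr$source_id, character(1)),
    centroid_row = vapply(crops, function(cr) cr$centroid["row"], numeric(1)),
    centroid_col = vapply(crops, function(cr) cr$centroid["col"], numeric(1)),
    area = vapply(crops, function(cr) cr$area, numeric(1))
  )
}

#' Run the full segmentation pipeline on one scene
#'
#' Grayscale conversion, automatic global thresholding, morphological
#' cleaning, and centroid-centred crop extraction.
#'
#' @param rgb `H x W x 3` scene image (0..255).
#' @param params A [segmentation_params()].
#' @param source_id Identifier recorded on each crop.
#' @return A `seed_crops` list.
#' @export
segment_scene <- function(rgb, params = segmentation_params(),
                          source_id = "scene") {
  g <- to_grayscale(rgb)
  m <- binarize(g, params)
  m <- clean_mask(m, params)
  extract_seeds(rgb, m, params, source_id = source_id)
}

#' Per-class train/validation split sizes
#'
#' The per-class ceiling rule: `train_n = ceiling(train_fraction * count)`,
#' `val_n = count - train_n`, with the actual index selection randomised under
#' `seed`. With the study's six class totals (976, 976, 976, 960, 998, 991)
#' and `train_fraction = 0.8` this yields 4703 training and 1174 validation
#' images.
#'
#' @param class_counts Positive integer vector, one total per class.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Optional seed; when given, list-columns `train_idx`/`val_idx`
#'   hold the within-class index assignment.
#' @return Tibble with columns `class`, `n`, `train_n`, `val_n` (and index
#'   list-columns when `seed` is given).
#' @export
split_dataset <- function(class_counts, train_fraction = 0.8, seed = NULL) {
  stopifnot(all(class_counts >= 1))
  train_n <- as.integer(ceiling(train_fraction * class_counts))
  out <- tibble::tibble(
    class = seq_along(class_counts),
    n = as.integer(class_counts),
    train_n = train_n,
    val_n = as.integer(class_counts) - train_n
  )
  if (!is.null(seed)) {
    idx <- withr::with_seed(seed, lapply(seq_along(class_counts), function(i) {
      sample.int(class_counts[i])
    }))
    out$train_idx <- lapply(seq_along(idx), function(i) {
      sort(idx[[i]][seq_len(train_n[i])])
    })
    out$val_idx <- lapply(seq_along(idx), function(i) {
      sort(idx[[i]][-seq_len(train_n[i])])
    })
  }
  out
}
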