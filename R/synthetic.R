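# Synthetic seed imagery ----------------------------------------------------------
#
# Fixture generator emulating the study's inputs: single-seed crops with
# class-dependent colour/texture on a dark background, and multi-seed scenes of
# disjoint elliptical seeds with exact ground truth (mask, centroids, count).
# The appearance model is deliberately simple -- an oriented ellipse filled
# with a class base colour modulated by a sinusoidal texture -- so that classes
# are separable by construction and training sanity checks are meaningful. It
# does not attempt photorealism or the appearance of real maize cultivars.

#' Synthetic dataset specification
#'
#' @param n_classes Number of seed varieties (default 6).
#' @param n_per_class Crops generated per class (default 40; use
#'   `study_scale = TRUE` in [generate_crop_dataset()] for ~980 per class,
#'   mirroring a 900-1000 sample-per-variety acquisition).
#' @param image_size Side of square single-seed crops in pixels (default 224).
#' @param scene_size Side of multi-seed scene images (default 1024).
#' @param seeds_per_scene Seeds per scene (default 12).
#' @param noise_sd Additive Gaussian pixel noise, grey levels (default 5).
#' @param class_palette Data frame with one row per class: `r`, `g`, `b` (base
#'   colour, 0-255), `freq` (texture cycles across the seed), `ecc_lo`,
#'   `ecc_hi` (ellipse eccentricity range). Default palette has distinct
#'   (colour, frequency) pairs per class.
#' @param rng_seed Integer seed; all outputs are reproducible from it alone.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 6L, n_per_class = 40L,
                           image_size = 224L, scene_size = 1024L,
                           seeds_per_scene = 12L, noise_sd = 5,
                           class_palette = default_palette(n_classes),
                           rng_seed = 1L) {
  stopifnot(n_classes >= 1L, n_per_class >= 1L, image_size >= 32L,
            nrow(class_palette) >= n_classes)
  key <- paste(class_palette$r, class_palette$g, class_palette$b,
               class_palette$freq)
  if (anyDuplicated(key[seq_len(n_classes)])) {
    stop("classes must have distinct (base colour, texture frequency) pairs",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 scene_size = as.integer(scene_size),
                 seeds_per_scene = as.integer(seeds_per_scene),
                 noise_sd = noise_sd, class_palette = class_palette,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Default class palette
#'
#' Six base colours with well-separated hues and distinct texture
#' frequencies. Hue separation matters more than brightness separation here:
#' the seed's area varies between crops, so the mean colour of a crop moves
#' radially (towards or away from the background), and classes that differ
#' only in brightness would smear into each other.
#'
#' @param n Number of classes requested.
#' @return A tibble with columns `r, g, b, freq, ecc_lo, ecc_hi`.
#' @export
default_palette <- function(n = 6L) {
  pal <- tibble::tibble(
    r = c(220, 70, 70, 220, 200, 60),
    g = c(70, 200, 90, 200, 60, 200),
    b = c(50, 70, 220, 50, 200, 200),
    freq = c(3, 5, 7, 9, 11, 13),
    ecc_lo = rep(0.55, 6),
    ecc_hi = rep(0.85, 6)
  )
  if (n > nrow(pal)) {
    extra <- n - nrow(pal)
    pal2 <- tibble::tibble(
      r = (seq_len(extra) * 97) %% 200 + 40,
      g = (seq_len(extra) * 57) %% 200 + 40,
      b = (seq_len(extra) * 31) %% 200 + 40,
      freq = 13 + 2 * seq_len(extra),
      ecc_lo = 0.55, ecc_hi = 0.85
    )
    pal <- rbind(pal, pal2)
  }
  pal
}

BG_BASE <- 12
BG_MAX <- 35

# Rasterise an ellipse: returns a logical H x W mask and the rotated major-axis
# coordinate of each inside pixel (for the texture phase).
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  r <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- (cc - cx) * cos(theta) + (r - cy) * sin(theta)
  v <- -(cc - cx) * sin(theta) + (r - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(inside = inside, u = u)
}

#' Generate one single-seed crop
#'
#' One oriented ellipse with class-dependent eccentricity, filled with the
#' class base colour modulated by a sinusoidal texture of the class frequency,
#' additive Gaussian noise, dark background (all background pixels are kept
#' below grey level 40 by construction). Uses the current RNG state, so the
#' result is deterministic given a prior `set.seed()`.
#'
#' @param class_id Class in `1..n_classes`.
#' @param spec A [synthetic_spec()].
#' @return List with `image` (`S x S x 3`, 0-255), `label`, `mask` (logical
#'   `S x S` ground-truth seed mask).
#' @export
generate_crop <- function(class_id, spec = synthetic_spec()) {
  stopifnot(class_id >= 1L, class_id <= spec$n_classes)
  S <- spec$image_size
  pal <- spec$class_palette[class_id, ]
  theta <- stats::runif(1, 0, pi)
  ecc <- stats::runif(1, pal$ecc_lo, pal$ecc_hi)
  a <- S * stats::runif(1, 0.28, 0.36)
  b <- a * sqrt(1 - ecc^2)
  cy <- S / 2 + stats::runif(1, -S * 0.05, S * 0.05)
  cx <- S / 2 + stats::runif(1, -S * 0.05, S * 0.05)
  em <- ellipse_mask(S, S, cy, cx, a, b, theta)
  phase <- stats::runif(1, 0, 2 * pi)
  tex <- 1 + 0.25 * sin(2 * pi * pal$freq * em$u / (2 * a) + phase)
  img <- array(0, dim = c(S, S, 3))
  base <- c(pal$r, pal$g, pal$b)
  for (ch in 1:3) {
    plane <- matrix(BG_BASE, S, S)
    plane[em$inside] <- pmin(255, base[ch] * tex[em$inside])
    img[, , ch] <- plane
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 255)
  # generator contract: the background stays well below grey level 40
  bg <- !em$inside
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bg] <- pmin(plane[bg], BG_MAX)
    img[, , ch] <- plane
  }
  list(image = img, label = as.integer(class_id), mask = em$inside)
}

#' Generate a balanced single-seed crop dataset
#'
#' @param spec A [synthetic_spec()]; `spec$rng_seed` fixes everything.
#' @param study_scale If `TRUE`, overrides `n_per_class` with 980.
#' @return List with `images` (list of arrays), `labels` (integer vector),
#'   `masks` (list of logical matrices), and `spec`.
#' @export
generate_crop_dataset <- function(spec = synthetic_spec(), study_scale = FALSE) {
  npc <- if (study_scale) 980L else spec$n_per_class
  n <- npc * spec$n_classes
  labels <- rep(seq_len(spec$n_classes), each = npc)
  images <- vector("list", n)
  masks <- vector("list", n)
  withr::with_seed(spec$rng_seed, {
    for (i in seq_len(n)) {
      cr <- generate_crop(labels[i], spec)
      images[[i]] <- cr$image
      masks[[i]] <- cr$mask
    }
  })
  list(images = images, labels = labels, masks = masks, spec = spec)
}

#' Generate a multi-seed scene with ground truth
#'
#' Places `seeds_per_scene` disjoint elliptical seeds on a near-uniform dark
#' background by rejection sampling (at most 1000 placement attempts in
#' total); if packing fails the scene contains fewer seeds and the returned
#' `count` is accurate. All seeds in a scene belong to one variety, mirroring
#' the acquisition protocol this emulates (each variety is photographed
#' separately, then cut into single-seed crops). Uses the current RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @param scene_class Variety of the scene's seeds; by default drawn at
#'   random.
#' @return List with `image` (`scene_size^2 x 3`), `mask` (logical), `centroids`
#'   (`count x 2` matrix, columns row/col), `count`, `classes`.
#' @export
generate_scene <- function(spec = synthetic_spec(), scene_class = NULL) {
  S <- spec$scene_size
  img <- array(BG_BASE, dim = c(S, S, 3))
  mask <- matrix(FALSE, S, S)
  centroids <- NULL
  classes <- integer(0)
  placed <- list()
  attempts <- 0L
  n_placed <- 0L
  if (is.null(scene_class)) scene_class <- sample.int(spec$n_classes, 1L)
  stopifnot(scene_class >= 1L, scene_class <= spec$n_classes)
  while (n_placed < spec$seeds_per_scene && attempts < 1000L) {
    attempts <- attempts + 1L
    cls <- scene_class
    pal <- spec$class_palette[cls, ]
    a <- S * stats::runif(1, 0.035, 0.055)
    ecc <- stats::runif(1, pal$ecc_lo, pal$ecc_hi)
    b <- a * sqrt(1 - ecc^2)
    margin <- a + 4
    cy <- stats::runif(1, margin, S - margin)
    cx <- stats::runif(1, margin, S - margin)
    # disjointness via bounding circles with a safety gap
    ok <- TRUE
    for (p in placed) {
      if ((p$cy - cy)^2 + (p$cx - cx)^2 < (p$a + a + 6)^2) { ok <- FALSE; break }
    }
    if (!ok) next
    theta <- stats::runif(1, 0, pi)
    box <- ceiling(a) + 2L
    r0 <- max(1L, floor(cy) - box); r1 <- min(S, ceiling(cy) + box)
    c0 <- max(1L, floor(cx) - box); c1 <- min(S, ceiling(cx) + box)
    em <- ellipse_mask(r1 - r0 + 1L, c1 - c0 + 1L, cy - r0 + 1, cx - c0 + 1,
                       a, b, theta)
    phase <- stats::runif(1, 0, 2 * pi)
    tex <- 1 + 0.25 * sin(2 * pi * pal$freq * em$u / (2 * a) + phase)
    base <- c(pal$r, pal$g, pal$b)
    for (ch in 1:3) {
      sub <- img[r0:r1, c0:c1, ch]
      sub[em$inside] <- pmin(255, base[ch] * tex[em$inside])
      img[r0:r1, c0:c1, ch] <- sub
    }
    mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | em$inside
    placed[[length(placed) + 1L]] <- list(cy = cy, cx = cx, a = a)
    centroids <- rbind(centroids, c(cy, cx))
    classes <- c(classes, cls)
    n_placed <- n_placed + 1L
  }
  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), sd = spec$noise_sd),
                       dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 255)
  bgpix <- !mask
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[bgpix] <- pmin(plane[bgpix], BG_MAX)
    img[, , ch] <- plane
  }
  if (n_placed > 0) colnames(centroids) <- c("row", "col")
  list(image = img, mask = mask,
       centroids = if (n_placed > 0) centroids else matrix(numeric(0), 0, 2),
       count = n_placed, classes = classes)
}
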