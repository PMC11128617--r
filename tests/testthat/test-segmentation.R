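test_that("luminance conversion uses the 0.299/0.587/0.114 weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_identical(to_grayscale(px(255, 255, 255))[1, 1], 255)
  expect_identical(to_grayscale(px(255, 0, 0))[1, 1], 76)
  for (g in c(0, 17, 128, 255)) {
    expect_identical(to_grayscale(px(g, g, g))[1, 1], g)
  }
  expect_error(to_grayscale(matrix(0, 4, 4)), "H x W x 3")
})

# independent oracle: exhaustive search of the threshold maximising
# between-class variance over all 256 grey levels
otsu_brute <- function(gray) {
  best <- -Inf; bt <- 0
  for (t in 0:254) {
    fg <- gray > t
    w1 <- mean(fg)
    if (w1 == 0 || w1 == 1) next
    bcv <- w1 * (1 - w1) * (mean(gray[fg]) - mean(gray[!fg]))^2
    if (bcv > best) { best <- bcv; bt <- t }
  }
  bt
}

test_that("automatic thresholding matches a brute-force between-class-variance search", {
  set.seed(10)
  # bimodal: half at 50, half at 200 (with a little jitter)
  g <- matrix(round(c(rnorm(500, 50, 3), rnorm(500, 200, 3))), 25, 40)
  g <- pmin(pmax(g, 0), 255)
  m <- binarize(g)
  thr <- attr(m, "threshold")
  expect_gt(thr, 50); expect_lt(thr, 200)
  expect_true(all((m == 1L) == (g > otsu_brute(g))))
  # foreground is exactly the bright mode
  expect_true(all(m[g > 150] == 1L))
  expect_identical(sum(m[g < 100]), 0L)
})

test_that("a constant image yields an empty mask with a warning", {
  expect_warning(m <- binarize(matrix(0, 10, 10)), "degenerate")
  expect_identical(sum(m), 0L)
  expect_true(is.na(attr(m, "threshold")))
})

test_that("fixed thresholding is available as an escape hatch", {
  g <- matrix(c(10, 100, 200, 240), 2, 2)
  m <- binarize(g, segmentation_params(threshold = "fixed", fixed_value = 150))
  expect_identical(as.vector(m), c(0L, 0L, 1L, 1L))
})

test_that("morphological cleaning removes speckle, fills holes, keeps large blobs", {
  p <- segmentation_params(morph_open_radius = 3, morph_close_radius = 3,
                           min_area = 50)
  m <- matrix(0L, 100, 100)
  # solid disk of radius 30
  d <- (row(m) - 50)^2 + (col(m) - 50)^2 <= 30^2
  m[d] <- 1L
  # 2-pixel speckle
  m[5, 5] <- 1L; m[5, 6] <- 1L
  cleaned <- clean_mask(m, p)
  expect_identical(sum(cleaned[1:10, 1:10]), 0L)            # speckle gone
  # opening on a discretised disk may nibble at most a boundary pixel ring
  d_inner <- (row(m) - 50)^2 + (col(m) - 50)^2 <= 28^2
  expect_true(all(cleaned[d_inner] == 1L))                  # disk intact
  expect_gte(sum(cleaned[d]), 0.98 * sum(d))
  # disk with a 3-px hole: hole filled
  m2 <- matrix(0L, 60, 60)
  d2 <- (row(m2) - 30)^2 + (col(m2) - 30)^2 <= 20^2
  m2[d2] <- 1L
  m2[29:31, 29:31] <- 0L
  cleaned2 <- clean_mask(m2, p)
  expect_identical(unname(cleaned2[30, 30]), 1L)
  d2_inner <- (row(m2) - 30)^2 + (col(m2) - 30)^2 <= 18^2
  expect_true(all(cleaned2[d2_inner] == 1L))
})

test_that("crop extraction pads border seeds and merges touching blobs", {
  p <- segmentation_params(min_area = 20, crop_size = 32, background_fill = 7)
  img <- array(200, dim = c(80, 80, 3))
  # one blob at the very corner
  m <- matrix(0L, 80, 80)
  m[1:10, 1:10] <- 1L
  crops <- extract_seeds(img, m, p)
  expect_length(crops, 1)
  expect_identical(dim(crops[[1]]$image), c(32L, 32L, 3L))
  expect_identical(unname(crops[[1]]$image[1, 1, 1]), 7)    # padded margin
  # two overlapping rectangles form one 8-connected component -> one crop
  m2 <- matrix(0L, 80, 80)
  m2[20:40, 20:40] <- 1L
  m2[40:60, 40:60] <- 1L
  expect_length(extract_seeds(img, m2, p), 1)
  # diagonal contact counts as connected (8-connectivity)
  m3 <- matrix(0L, 80, 80)
  m3[10:20, 10:20] <- 1L
  m3[21:31, 21:31] <- 1L
  expect_length(extract_seeds(img, m3, segmentation_params(min_area = 20,
                                                           crop_size = 32)), 1)
  expect_length(extract_seeds(img, matrix(0L, 80, 80), p), 0)
})

test_that("crops come back row-major by centroid with accurate records", {
  p <- segmentation_params(min_area = 20, crop_size = 32)
  img <- array(150, dim = c(100, 100, 3))
  m <- matrix(0L, 100, 100)
  m[10:20, 60:70] <- 1L   # top right
  m[12:22, 10:20] <- 1L   # top left (slightly lower but same rounded rows)
  m[70:80, 30:40] <- 1L   # bottom
  crops <- extract_seeds(img, m, p)
  man <- crop_manifest(crops)
  expect_identical(nrow(man), 3L)
  expect_true(all(diff(round(man$centroid_row)) >= 0))
  expect_identical(man$area, c(121, 121, 121))
})

test_that("the pipeline recovers generated seeds exactly, with centroids on target", {
  spec <- synthetic_spec(scene_size = 384, seeds_per_scene = 5, rng_seed = 21)
  p <- segmentation_params(min_area = 150, crop_size = 64)
  hits <- 0L
  withr::with_seed(33, {
    for (i in 1:20) {
      sc <- generate_scene(spec)
      crops <- segment_scene(sc$image, p)
      if (length(crops) == sc$count) hits <- hits + 1L
    }
  })
  expect_identical(hits, 20L)
  withr::with_seed(5, sc <- generate_scene(spec))
  crops <- segment_scene(sc$image, p)
  man <- crop_manifest(crops)
  truth <- sc$centroids[order(round(sc$centroids[, 1]),
                              round(sc$centroids[, 2])), , drop = FALSE]
  expect_identical(nrow(man), sc$count)
  expect_lt(max(abs(as.matrix(man[, c("centroid_row", "centroid_col")]) - truth)), 1)
})

test_that("the ceiling 80/20 rule reproduces the published per-class splits", {
  expect_identical(unlist(split_dataset(976)[1, c("train_n", "val_n")],
                          use.names = FALSE), c(781L, 195L))
  expect_identical(unlist(split_dataset(998)[1, c("train_n", "val_n")],
                          use.names = FALSE), c(799L, 199L))
  expect_identical(unlist(split_dataset(960)[1, c("train_n", "val_n")],
                          use.names = FALSE), c(768L, 192L))
  # totals add back up per class, and index assignment partitions 1..n
  tab <- split_dataset(c(10, 25, 40), seed = 2)
  expect_identical(tab$train_n + tab$val_n, tab$n)
  for (i in 1:3) {
    expect_identical(sort(c(tab$train_idx[[i]], tab$val_idx[[i]])),
                     seq_len(tab$n[i]))
  }
})
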