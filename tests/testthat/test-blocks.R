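block_param_total <- function(blk) {
  leaves <- c(blk$branch, blk$shortcut, blk$post)
  sum(vapply(leaves, seednet:::leaf_params, numeric(1)))
}

stage_param_total <- function(blocks) {
  sum(vapply(blocks, block_param_total, numeric(1)))
}

test_that("baseline bottleneck parameter count matches the per-layer ledger", {
  # in 64, mid 64, out 256, stride 1 with projection shortcut:
  # convs 64*64 + 9*64*64 + 64*256 + 64*256(proj) = 73728
  # norms 2*(64 + 64 + 256 + 256)                 = 1280
  b <- residual_block_spec("baseline", 64, 64)
  expect_identical(block_param_total(b), 73728 + 1280)
  # in 256: identity shortcut; convs 256*64 + 9*64^2 + 64*256 = 69632,
  # norms 2*(64+64+256) = 768
  b2 <- residual_block_spec("baseline", 256, 64)
  expect_length(b2$shortcut, 0)
  expect_identical(block_param_total(b2), 69632 + 768)
})

test_that("blocks map (H, W, C_in) to (ceil(H/stride), ., 4*mid) for every role", {
  shp_after <- function(blk, shp) {
    for (l in blk$branch) shp <- seednet:::leaf_out_shape(l, shp)
    shp
  }
  for (role in c("baseline", "start", "middle", "end", "improved")) {
    for (s in if (role == "middle") 1L else c(1L, 2L)) {
      in_ch <- if (role %in% c("middle", "end")) 32L else 16L
      blk <- residual_block_spec(role, in_ch, 8L, s)
      out <- shp_after(blk, c(in_ch, 12L, 12L))
      expect_identical(out, c(32L, as.integer(ceiling(12L / s)),
                              as.integer(ceiling(12L / s))),
                       info = paste(role, s))
    }
  }
})

test_that("a zero-weight branch reduces a block to activation(shortcut(x))", {
  set.seed(3)
  x <- array(rnorm(32 * 10 * 10 * 2), dim = c(32, 10, 10, 2))
  # baseline block with identity shortcut: out = relu(x) when branch is dead
  blk <- seednet:::init_block(residual_block_spec("baseline", 32, 8))
  blk$branch[[7]]$par$W[] <- 0  # final 1x1 conv
  r <- seednet:::block_fw(blk, x, training = TRUE)
  expect_equal(r$out, relu(x), tolerance = 1e-12)
  # improved block with mixed activation: trunk activation is swish
  blki <- seednet:::init_block(
    residual_block_spec("improved", 32, 8, mixed_activation = TRUE))
  last_conv <- max(which(vapply(blki$branch, function(l) l$kind == "conv",
                                logical(1))))
  blki$branch[[last_conv]]$par$W[] <- 0
  ri <- seednet:::block_fw(blki, x, training = TRUE)
  expect_equal(ri$out, swish(x), tolerance = 1e-12)
})

test_that("a zero-weight middle block is an exact identity mapping", {
  set.seed(4)
  x <- array(rnorm(32 * 8 * 8 * 2), dim = c(32, 8, 8, 2))
  blk <- seednet:::init_block(residual_block_spec("middle", 32, 8))
  last_conv <- length(blk$branch)
  expect_identical(blk$branch[[last_conv]]$kind, "conv")
  blk$branch[[last_conv]]$par$W[] <- 0
  r <- seednet:::block_fw(blk, x, training = TRUE)
  expect_identical(r$out, x)
})

test_that("stage reorganisation preserves the parameter count exactly", {
  for (m in c(64L, 128L)) {
    n <- if (m == 64L) 3L else 4L
    in_ch <- if (m == 64L) 64L else 256L
    s <- if (m == 64L) 1L else 2L
    cfg <- variant_config()
    base <- seednet:::stage_spec(n, in_ch, m, s, resstage = FALSE,
                                 improved = FALSE, cfg = cfg)
    rs <- seednet:::stage_spec(n, in_ch, m, s, resstage = TRUE,
                               improved = FALSE, cfg = cfg)
    expect_identical(stage_param_total(rs), stage_param_total(base))
  }
})

test_that("depthwise-separable convolution has 9*in + in*out conv parameters", {
  expect_identical(attr(make_ds_conv(256, 256), "conv_params"), 9L * 256L + 256L * 256L)
  expect_identical(attr(make_ds_conv(256, 256), "conv_params"), 67840L)
  expect_identical(attr(make_ds_conv(512, 512), "conv_params"), 266752L)
  layers <- make_ds_conv(16, 24)
  conv_p <- sum(vapply(layers, function(l) {
    if (l$kind == "conv") seednet:::leaf_params(l) else 0
  }, numeric(1)))
  expect_identical(conv_p, 9 * 16 + 16 * 24)
})

test_that("depthwise then pointwise with unit weights sums channels (hand oracle)", {
  # 3-channel constant image, all conv weights 1, norms as identity
  # (inference mode with fresh unit statistics): each interior depthwise
  # output is 9c, the pointwise output 3 * 9c.
  cval <- 0.5
  x <- array(cval, dim = c(3, 5, 5, 1))
  layers <- lapply(make_ds_conv(3, 1), seednet:::init_leaf)
  layers[[1]]$par$W[] <- 1
  layers[[4]]$par$W[] <- 1
  out <- x
  for (l in layers) out <- seednet:::leaf_fw(l, out, training = FALSE)$out
  expect_equal(out[1, 3, 3, 1], 3 * 9 * cval, tolerance = 1e-3)
  # corner sees a 2x2 window per channel
  expect_equal(out[1, 1, 1, 1], 3 * 4 * cval, tolerance = 1e-3)
})

test_that("improved block's parameter saving matches the ledger difference", {
  m <- 256L
  base <- residual_block_spec("baseline", 4L * m, m)
  imp <- residual_block_spec("improved", 4L * m, m)
  saving <- block_param_total(base) - block_param_total(imp)
  # standard 3x3 (9 m^2) replaced by depthwise (9m) + pointwise (m^2) with one
  # extra norm (2m), plus the attention kernel
  expect_identical(saving,
                   9 * m^2 - (9 * m + m^2) - 2 * m - eca_kernel_size(m))
})

test_that("improved blocks at width 512 receive a width-5 attention kernel", {
  blk <- residual_block_spec("improved", 2048, 512, stride = 2)
  eca <- Filter(function(l) l$kind == "eca", blk$branch)[[1]]
  expect_identical(eca$k, 5L)
  expect_error(residual_block_spec("bottleneck", 64, 64), "arg")
})

test_that("trunk activation count is fixed for reorganised stages, grows for baseline", {
  mk_plan <- function(depths, resstage) {
    cfg <- variant_config()
    stages <- list()
    in_ch <- 64L
    mids <- c(64L, 128L, 256L, 512L)
    for (s in seq_along(depths)) {
      stages[[s]] <- seednet:::stage_spec(depths[s], in_ch, mids[s],
                                          if (s == 1L) 1L else 2L,
                                          resstage = resstage,
                                          improved = FALSE, cfg = cfg)
      in_ch <- 4L * mids[s]
    }
    structure(list(cfg = cfg, stem = list(), stages = stages, head = list()),
              class = "network_plan")
  }
  for (depths in list(c(2L, 2L, 2L, 2L), c(3L, 4L, 6L, 3L), c(5L, 7L, 3L, 2L))) {
    rs <- mk_plan(depths, TRUE)
    expect_identical(trunk_activation_count(rs), 4L, info = paste(depths, collapse = ","))
    expect_identical(trunk_activation_count(rs, per_stage = TRUE),
                     rep(1L, 4L))
    base <- mk_plan(depths, FALSE)
    expect_identical(trunk_activation_count(base), sum(depths))
    expect_identical(trunk_activation_count(base, per_stage = TRUE), depths)
  }
})
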