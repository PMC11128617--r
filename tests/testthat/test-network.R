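test_that("all eight ablation variants build and show the published parameter pattern", {
  for (r in c(FALSE, TRUE)) for (i in c(FALSE, TRUE)) for (a in c(FALSE, TRUE)) {
    cfg <- variant_config(r, i, a)
    plan <- build_plan(cfg)
    expect_s3_class(plan, "network_plan")
    pM <- seednet:::round_half_up(count_params(plan) / 1e6, 2)
    expect_identical(pM, if (i) 14.12 else 23.52,
                     info = sprintf("R=%d I=%d A=%d", r, i, a))
  }
})

test_that("head and stem follow the 50-layer bottleneck contract", {
  plan <- build_plan(variant_config())
  expect_length(plan$stages, 4)
  expect_identical(vapply(plan$stages, length, integer(1)), c(3L, 4L, 6L, 3L))
  fc <- plan$head[[2]]
  expect_identical(fc$in_n, 2048L)
  expect_identical(fc$out_n, 6L)
  expect_error(variant_config(num_classes = 1), "num_classes")
})

test_that("swapping in the mixed activation leaves the rounded size unchanged", {
  p_relu <- count_params(variant_config(TRUE, TRUE, FALSE))
  p_mixed <- count_params(variant_config(TRUE, TRUE, TRUE))
  expect_lt(abs(p_mixed - p_relu), 100)  # a handful of shared slopes
  r2 <- seednet:::round_half_up
  expect_identical(r2(p_relu / 1e6, 2), r2(p_mixed / 1e6, 2))
})

test_that("forward pass meets the shape and determinism contract", {
  model <- build_model(variant_config(TRUE, TRUE, TRUE), seed = 2)
  set.seed(7)
  img <- array(runif(64 * 64 * 3, 0, 255), dim = c(64, 64, 3))
  logits <- forward_pass(model, list(img, img), type = "logit")
  expect_identical(dim(logits), c(2L, 6L))
  expect_true(all(is.finite(logits)))
  expect_equal(logits[1, ], logits[2, ])  # duplicated inputs, identical rows
  probs <- forward_pass(model, list(img), type = "prob")
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  # global pooling absorbs other spatial sizes
  img48 <- array(runif(48 * 48 * 3, 0, 255), dim = c(48, 48, 3))
  expect_identical(dim(forward_pass(model, list(img48), type = "logit")),
                   c(1L, 6L))
  bad <- array(0, dim = c(2L, 64L, 64L, 1L))
  expect_error(forward_pass(model, bad), "3 channels")
})

test_that("checkpoints round-trip with a JSON config sidecar", {
  model <- build_model(variant_config(num_classes = 3), seed = 4)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$num_classes, 3)
  m2 <- load_model(path)
  img <- array(runif(48 * 48 * 3, 0, 255), dim = c(48, 48, 3))
  expect_identical(forward_pass(model, list(img)),
                   forward_pass(m2, list(img)))
  unlink(c(path, paste0(path, ".json")))
})

test_that("glance reports the variant and its size", {
  g <- glance(build_model(variant_config(TRUE, TRUE, TRUE), seed = 1))
  expect_identical(g$params_M, 14.12)
  expect_true(g$resstage && g$improved_block && g$mixed_activation)
})
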