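test_that("training defaults mirror the study protocol", {
  cfg <- train_config()
  expect_identical(cfg$epochs, 150L)
  expect_identical(cfg$batch_size, 32L)
  expect_identical(cfg$learning_rate, 0.001)
  expect_identical(cfg$momentum, 0.9)
  expect_identical(cfg$weight_decay, 5e-4)
  expect_identical(cfg$optimizer, "sgd")
  expect_identical(cfg$folds, 5L)
})

test_that("stratified folds partition the data with balanced classes", {
  labels <- rep(1:6, each = 10)
  folds <- kfold_splits(labels, k = 5, rng_seed = 42)
  expect_length(folds, 5)
  val_all <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(val_all, seq_along(labels))          # exact partition
  for (f in folds) {
    expect_length(f$val, 12)
    expect_identical(as.integer(table(labels[f$val])), rep(2L, 6L))
    expect_identical(sort(c(f$train, f$val)), seq_along(labels))
  }
  expect_identical(kfold_splits(labels, 5, rng_seed = 42), folds)  # reproducible
  expect_false(identical(kfold_splits(labels, 5, rng_seed = 1), folds))
  expect_error(kfold_splits(rep(1:2, c(3, 50)), k = 5), "at least k")
})

table7 <- tibble::tribble(
  ~precision, ~recall, ~f1,
  0.868, 0.846, 0.857,
  0.822, 0.805, 0.813,
  0.917, 0.908, 0.912,
  0.797, 0.839, 0.817,
  0.800, 0.884, 0.840,
  0.854, 0.768, 0.809,
  0.925, 0.949, 0.937,
  0.870, 0.928, 0.898,
  0.952, 0.918, 0.935,
  0.929, 0.885, 0.906,
  0.883, 0.910, 0.896,
  0.921, 0.884, 0.902
)

test_that("the harmonic-mean identity reproduces all twelve published F1 values", {
  expect_equal(round(f1_score(0.925, 0.949), 3), 0.937)
  expect_equal(round(f1_score(0.870, 0.928), 3), 0.898)
  expect_equal(round(f1_score(table7$precision, table7$recall), 3), table7$f1,
               tolerance = 5e-4)
})

test_that("confusion-matrix identities hold on arbitrary matrices", {
  set.seed(6)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(1:4, 200, replace = TRUE))
  cm <- confusion_matrix(truth, pred, 4)
  expect_identical(sum(cm), 200L)
  expect_equal(unname(rowSums(cm)), as.vector(table(truth)),
               ignore_attr = TRUE)
  met <- classification_metrics(cm)
  # per-class TP + FN equals the row sum
  expect_equal(met$recall, diag(cm) / rowSums(cm))
  # micro-averaged precision equals accuracy for single-label classification
  micro_p <- sum(diag(cm)) / sum(colSums(cm))
  expect_equal(micro_p, sum(diag(cm)) / sum(cm))
})

test_that("degenerate confusion matrices are handled explicitly", {
  perfect <- diag(c(5L, 7L, 9L))
  met <- classification_metrics(perfect)
  expect_equal(met$precision, rep(1, 3))
  expect_equal(met$f1, rep(1, 3))
  # a class never predicted: precision 0, with a warning
  cm <- matrix(c(5L, 3L, 0L, 0L), 2, 2)   # class 2 never predicted
  expect_warning(met2 <- classification_metrics(cm), "no predicted")
  expect_identical(met2$precision[2], 0)
  expect_identical(f1_score(0, 0), 0)
})

test_that("a zero learning rate leaves every parameter untouched", {
  spec <- synthetic_spec(n_per_class = 2, image_size = 32, rng_seed = 31)
  ds <- generate_crop_dataset(spec)
  model <- build_model(variant_config(), seed = 8)
  cfg <- train_config(epochs = 1, batch_size = 12, learning_rate = 0,
                      weight_decay = 0, rng_seed = 2)
  fit <- train_model(model, ds, cfg, recalibrate = FALSE)
  before <- model$nodes$head2$leaf$par$W
  after <- fit$model$nodes$head2$leaf$par$W
  expect_identical(before, after)
  expect_identical(fit$model$nodes$stem1$leaf$par$W,
                   model$nodes$stem1$leaf$par$W)
  expect_identical(nrow(fit$history), 1L)
  expect_error(train_model(model, list(images = list(), labels = integer(0)),
                           cfg), "empty")
})

test_that("short training on the easy synthetic set learns (loss falls, accuracy rises)", {
  fit <- trained_fixture()
  h <- fit$history
  expect_identical(nrow(h), 5L)
  expect_lt(h$loss[5], h$loss[1])
  expect_gt(h$accuracy[5], h$accuracy[1])
  st <- synth_study_set()
  ev <- evaluate_model(fit, st$val)
  expect_identical(sum(ev$confusion), ev$n)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / ev$n)
  expect_identical(dim(ev$confusion), c(6L, 6L))
  # broom-style accessors
  expect_identical(nrow(tidy(ev)), 6L)
  expect_identical(glance(ev)$n, ev$n)
})

test_that("evaluation reports serialise to JSON", {
  st <- synth_study_set()
  ev <- evaluate_model(trained_fixture(), st$val)
  path <- tempfile(fileext = ".json")
  write_eval_report(ev, path, extra = list(seed = 9))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$accuracy, ev$accuracy)
  expect_equal(obj$seed, 9)
  unlink(path)
})
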