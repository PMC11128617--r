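# Shared fixtures. The trained model is expensive (a few minutes of CPU), so it
# is built once per test run and reused by every file that needs it.

.fixtures <- new.env(parent = emptyenv())

# The synthetic study set: 6 balanced classes x 40 crops (48 px -- the
# architecture is resolution-agnostic through global pooling, and class
# identity is carried by colour/texture, not resolution), split 80/20.
synth_study_set <- function() {
  if (is.null(.fixtures$study)) {
    spec <- synthetic_spec(n_per_class = 40, image_size = 48, noise_sd = 5,
                           rng_seed = 11)
    ds <- generate_crop_dataset(spec)
    sp <- split_dataset(rep(40L, 6L), 0.8, seed = 3)
    tr_idx <- unlist(lapply(1:6, function(cl) {
      which(ds$labels == cl)[sp$train_idx[[cl]]]
    }))
    va_idx <- setdiff(seq_along(ds$labels), tr_idx)
    .fixtures$study <- list(
      spec = spec,
      dataset = ds,
      train = list(images = ds$images[tr_idx], labels = ds$labels[tr_idx]),
      val = list(images = ds$images[va_idx], labels = ds$labels[va_idx],
                 masks = ds$masks[va_idx])
    )
  }
  .fixtures$study
}

# Short sanity-training schedule: 5 epochs of SGD, batch 16, learning rate at
# the upper end of the protocol's explored magnitude range with cosine decay
# and gradient clipping (stabilisers for a 60-step schedule), fixed seeds.
sanity_train_config <- function(epochs = 5L) {
  train_config(epochs = epochs, batch_size = 16L, learning_rate = 0.02,
               momentum = 0.9, weight_decay = 5e-4, lr_schedule = "cosine",
               clip_norm = 5, rng_seed = 9L)
}

trained_fixture <- function() {
  if (is.null(.fixtures$fit)) {
    st <- synth_study_set()
    model <- build_model(variant_config(TRUE, TRUE, TRUE), seed = 5)
    .fixtures$fit <- train_model(model, st$train, sanity_train_config())
  }
  .fixtures$fit
}

# Heatmap localisation needs feature maps with genuine spatial extent (the
# last stage is 3x3 at 96 px but degenerate at 48 px), and features trained at
# the geometry being probed -- so the localisation fixture trains its own
# model on 96 px crops under the same schedule and seeds.
gradcam_fixture <- function() {
  if (is.null(.fixtures$fit96)) {
    spec <- synthetic_spec(n_per_class = 40, image_size = 96, noise_sd = 5,
                           rng_seed = 11)
    ds <- generate_crop_dataset(spec)
    sp <- split_dataset(rep(40L, 6L), 0.8, seed = 3)
    tr_idx <- unlist(lapply(1:6, function(cl) {
      which(ds$labels == cl)[sp$train_idx[[cl]]]
    }))
    tr <- list(images = ds$images[tr_idx], labels = ds$labels[tr_idx])
    model <- build_model(variant_config(TRUE, TRUE, TRUE), seed = 5)
    cfg <- sanity_train_config()
    cfg$batch_size <- 8L  # bounds forward-cache memory at the larger crops
    .fixtures$fit96 <- train_model(model, tr, cfg)
  }
  .fixtures$fit96
}

# Independent crops at the same resolution for heatmap localisation checks.
gradcam_probe_set <- function() {
  if (is.null(.fixtures$probe)) {
    spec <- synthetic_spec(n_per_class = 4, image_size = 96, noise_sd = 5,
                           rng_seed = 77)
    .fixtures$probe <- generate_crop_dataset(spec)
  }
  .fixtures$probe
}
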