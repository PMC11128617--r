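# Model construction and inference ----------------------------------------------

#' Build a runnable model from a variant configuration
#'
#' Materialises the symbolic plan of a [variant_config()] into a numeric model:
#' He-initialised convolution and fully connected weights, unit-scale
#' normalisation layers, shared PReLU slopes at 0.25 where the variant uses
#' them. The same plan drives [count_params()] and [count_macs()], so the
#' built model's tensor sizes always sum to the reported parameter count.
#'
#' @param cfg A [variant_config()] (or a `network_plan`).
#' @param seed Integer seed for weight initialisation.
#' @return A `seednet_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  plan <- as_plan(cfg)
  nodes <- list()
  add <- function(node, name) {
    nodes[[name]] <<- node
  }
  withr::with_seed(seed, {
    for (i in seq_along(plan$stem)) {
      add(list(kind = "leaf", leaf = init_leaf(plan$stem[[i]])),
          paste0("stem", i))
    }
    for (s in seq_along(plan$stages)) {
      for (b in seq_along(plan$stages[[s]])) {
        blk <- plan$stages[[s]][[b]]
        blk$branch <- lapply(blk$branch, init_leaf)
        blk$shortcut <- lapply(blk$shortcut, init_leaf)
        blk$post <- lapply(blk$post, init_leaf)
        add(list(kind = "block", blk = blk), sprintf("s%db%d", s, b))
      }
    }
    for (i in seq_along(plan$head)) {
      add(list(kind = "leaf", leaf = init_leaf(plan$head[[i]])),
          paste0("head", i))
    }
  })
  structure(list(cfg = plan$cfg, plan = plan, nodes = nodes, vel = NULL),
            class = "seednet_model")
}

#' @export
print.seednet_model <- function(x, ...) {
  p <- count_params(x)
  cat("<seednet_model> ", variant_label(x$cfg), ", ", x$cfg$num_classes,
      " classes, ", format(p, big.mark = ","), " trainable parameters\n",
      sep = "")
  invisible(x)
}

# Full forward pass. `x` is a (3, S, S, N) batch. Returns logits (K x N),
# per-node caches, optionally the activation captured at `capture_id`
# ("<node>.<branch|shortcut|post>.<i>" for block internals), and the model
# (whose normalisation running statistics advance during training).
model_forward <- function(model, x, training = FALSE, capture_id = NULL) {
  caches <- vector("list", length(model$nodes))
  names(caches) <- names(model$nodes)
  captured <- NULL
  for (nm in names(model$nodes)) {
    node <- model$nodes[[nm]]
    if (node$kind == "leaf") {
      r <- leaf_fw(node$leaf, x, training)
      if (!is.null(r$leaf)) model$nodes[[nm]]$leaf <- r$leaf
      x <- r$out
      caches[[nm]] <- r$cache
      if (!is.null(capture_id) && identical(nm, capture_id)) {
        captured <- list(id = nm, out = x)
      }
    } else {
      r <- block_fw(node$blk, x, training, capture_id, paste0(nm, "."))
      model$nodes[[nm]]$blk <- r$blk
      x <- r$out
      caches[[nm]] <- r$cache
      if (is.null(captured)) captured <- r$captured
    }
  }
  logits <- matrix(x, nrow = model$cfg$num_classes)
  list(logits = logits, caches = caches, model = model, captured = captured)
}

model_backward <- function(model, caches, dlogits, capture_id = NULL) {
  nms <- names(model$nodes)
  grads <- vector("list", length(nms))
  names(grads) <- nms
  dout <- dlogits
  dim(dout) <- c(nrow(dlogits), 1L, 1L, ncol(dlogits))
  captured_grad <- NULL
  for (nm in rev(nms)) {
    node <- model$nodes[[nm]]
    if (node$kind == "leaf") {
      if (!is.null(capture_id) && identical(nm, capture_id)) {
        captured_grad <- dout
      }
      r <- leaf_bw(node$leaf, caches[[nm]], dout)
      dout <- r$dx
      grads[[nm]] <- r$grads
    } else {
      r <- block_bw(node$blk, caches[[nm]], dout, capture_id, paste0(nm, "."))
      dout <- r$dx
      grads[[nm]] <- r$grads
      if (is.null(captured_grad)) captured_grad <- r$captured_grad
    }
  }
  list(grads = grads, captured_grad = captured_grad)
}

# Walk (leaf, grad-or-NULL, vel-or-NULL) triples across the whole model and
# apply `f(par_name, param, grad, vel)`; used by the optimiser and by
# gradient-coverage checks.
walk_params <- function(model, grads, f) {
  visit_leaf <- function(leaf, g, path) {
    for (p in names(leaf$par)) {
      f(paste0(path, ".", p), leaf$par[[p]], if (is.null(g)) NULL else g[[p]])
    }
  }
  for (nm in names(model$nodes)) {
    node <- model$nodes[[nm]]
    g <- grads[[nm]]
    if (node$kind == "leaf") {
      visit_leaf(node$leaf, g, nm)
    } else {
      for (part in c("branch", "shortcut", "post")) {
        ls <- node$blk[[part]]
        for (i in seq_along(ls)) {
          visit_leaf(ls[[i]], g[[part]][[i]], sprintf("%s.%s.%d", nm, part, i))
        }
      }
    }
  }
  invisible(NULL)
}

# Per-tensor max absolute gradient, named by parameter path.
grad_coverage <- function(model, grads) {
  out <- new.env()
  walk_params(model, grads, function(path, param, grad) {
    assign(path, if (is.null(grad)) NA_real_ else max(abs(grad)), envir = out)
  })
  unlist(as.list(out))
}

# One SGD step with momentum and L2 weight decay, in place on the model.
sgd_step <- function(model, grads, lr, momentum = 0.9, weight_decay = 5e-4) {
  upd_leaf <- function(leaf, g, v) {
    if (is.null(v)) v <- lapply(leaf$par, function(p) p * 0)
    for (p in names(leaf$par)) {
      gr <- g[[p]] + weight_decay * leaf$par[[p]]
      v[[p]] <- momentum * v[[p]] + gr
      leaf$par[[p]] <- leaf$par[[p]] - lr * v[[p]]
    }
    list(leaf = leaf, v = v)
  }
  if (is.null(model$vel)) model$vel <- list()
  for (nm in names(model$nodes)) {
    node <- model$nodes[[nm]]
    if (node$kind == "leaf") {
      r <- upd_leaf(node$leaf, grads[[nm]], model$vel[[nm]])
      model$nodes[[nm]]$leaf <- r$leaf
      model$vel[[nm]] <- r$v
    } else {
      for (part in c("branch", "shortcut", "post")) {
        ls <- node$blk[[part]]
        for (i in seq_along(ls)) {
          key <- sprintf("%s.%s.%d", nm, part, i)
          r <- upd_leaf(ls[[i]], grads[[nm]][[part]][[i]], model$vel[[key]])
          model$nodes[[nm]]$blk[[part]][[i]] <- r$leaf
          model$vel[[key]] <- r$v
        }
      }
    }
  }
  model
}

#' Recompute normalisation statistics over a dataset
#'
#' Replaces every normalisation layer's running mean/variance with the exact
#' average of its batch statistics over the given data (a "precise" BN pass).
#' Short training schedules leave exponentially averaged running statistics
#' far from the activation distribution, which hurts inference-mode accuracy;
#' one recalibration pass fixes that without touching any trained weight.
#'
#' @param model A `seednet_model`.
#' @param dataset List with `images` (and optionally `labels`, unused).
#' @param batch_size Batch size for the statistics passes.
#' @return The model with updated normalisation buffers.
#' @export
recalibrate_bn <- function(model, dataset, batch_size = 32L) {
  reset_bn <- function(leaf) {
    if (leaf$kind == "bn") {
      leaf$buf <- list(rm = rep(0, leaf$ch), rv = rep(1, leaf$ch), n = 0L)
    }
    leaf
  }
  for (nm in names(model$nodes)) {
    node <- model$nodes[[nm]]
    if (node$kind == "leaf") {
      model$nodes[[nm]]$leaf <- reset_bn(node$leaf)
    } else {
      for (part in c("branch", "shortcut", "post")) {
        model$nodes[[nm]]$blk[[part]] <-
          lapply(node$blk[[part]], reset_bn)
      }
    }
  }
  n <- length(dataset$images)
  x_all <- images_to_batch(dataset$images)
  # class-mixed batches: deep-layer activations during the statistics pass
  # should be produced under the same batch composition regime as training
  ord <- withr::with_seed(1L, sample.int(n))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- ord[start:min(start + batch_size - 1L, n)]
    fw <- model_forward(model, x_all[, , , idx, drop = FALSE],
                        training = "cumulative")
    model <- fw$model
  }
  # finalise: rv accumulated E[x^2]; convert to population variance
  finalize <- function(leaf) {
    if (leaf$kind == "bn" && leaf$buf$n > 0) {
      leaf$buf$rv <- pmax(leaf$buf$rv - leaf$buf$rm^2, 0)
    }
    leaf
  }
  for (nm in names(model$nodes)) {
    node <- model$nodes[[nm]]
    if (node$kind == "leaf") {
      model$nodes[[nm]]$leaf <- finalize(node$leaf)
    } else {
      for (part in c("branch", "shortcut", "post")) {
        model$nodes[[nm]]$blk[[part]] <- lapply(node$blk[[part]], finalize)
      }
    }
  }
  model
}

#' Run a batch of images through a model
#'
#' @param model A `seednet_model`.
#' @param images A list of `H x W x 3` numeric arrays (0-255), or a
#'   pre-assembled `(3, S, S, N)` batch array.
#' @param type `"logit"` (N x K matrix, one row per image), `"prob"` (softmax
#'   rows), or `"class"` (integer labels 1..K).
#' @return See `type`.
#' @export
forward_pass <- function(model, images, type = c("logit", "prob", "class")) {
  type <- match.arg(type)
  x <- if (is.array(images) && length(dim(images)) == 4L) images
       else images_to_batch(images)
  if (dim(x)[1] != 3L) stop("input must have 3 channels", call. = FALSE)
  if (dim(x)[2] < 32L) stop("input size must be at least 32", call. = FALSE)
  logits <- model_forward(model, x, training = FALSE)$logits
  switch(type,
         logit = t(logits),
         prob = t(softmax_cols(logits)),
         class = apply(logits, 2, which.max))
}

#' @export
predict.seednet_model <- function(object, newdata, type = "class", ...) {
  forward_pass(object, newdata, type = type)
}

#' Assemble images into a normalised batch tensor
#'
#' Scales 0-255 RGB images to unit range and standardises with fixed centring
#' (mean 0.5, scale 0.25) -- the model family trains from scratch, so no
#' dataset-specific normalisation constants are assumed.
#'
#' @param images List of `H x W x 3` arrays with values in 0..255.
#' @return A `(3, H, W, N)` array.
#' @export
images_to_batch <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1]])
  out <- array(0, dim = c(3L, d[1], d[2], length(images)))
  for (i in seq_along(images)) {
    im <- images[[i]]
    out[, , , i] <- aperm(im, c(3, 1, 2))
  }
  (out / 255 - 0.5) / 0.25
}

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

#' Save / load a model checkpoint
#'
#' Weights go into R's native serialisation container; a JSON sidecar records
#' the variant configuration for reproducibility.
#'
#' @param model A `seednet_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$cfg
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param path Checkpoint path written by [save_model()].
#' @export
load_model <- function(path) {
  readRDS(path)
}

#' @export
glance.seednet_model <- function(x, ...) {
  tibble::tibble(
    variant = variant_label(x$cfg),
    resstage = x$cfg$use_resstage,
    improved_block = x$cfg$use_improved_block,
    mixed_activation = x$cfg$use_mixed_activation,
    num_classes = x$cfg$num_classes,
    params = count_params(x),
    params_M = round_half_up(count_params(x) / 1e6, 2)
  )
}
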