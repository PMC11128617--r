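# Symbolic network plans ------------------------------------------------------
#
# A "plan" is a declarative description of the architecture: a nested list of
# layer specs (leaves) and residual-block nodes. Both the complexity counter
# and the numeric engine are driven from the same plan, so parameter counts,
# MAC counts and the runnable model can never drift apart.

#' Variant configuration
#'
#' The three architectural switches studied in the ablation, plus the head
#' size. `(FALSE, FALSE, FALSE)` is the classic 50-layer bottleneck residual
#' network; `(TRUE, TRUE, TRUE)` is the full improved model: stage-reorganised
#' (ResStage) early stages, efficient-channel-attention plus
#' depthwise-separable later blocks, and the mixed Swish/PReLU activation
#' placement.
#'
#' @param use_resstage Rebuild the two early stages (bottleneck widths 64 and
#'   128) as Start/Middle/End ResStage blocks.
#' @param use_improved_block Rebuild the two later stages (widths 256 and 512)
#'   from improved residual blocks (channel attention after the first
#'   convolution, depthwise-separable second convolution).
#' @param use_mixed_activation Swish at the stem activation and at the
#'   post-addition activation of End and improved blocks; PReLU at every other
#'   activation site. Otherwise ReLU everywhere.
#' @param num_classes Number of output classes (>= 2).
#' @param conv2_kind Kind of second convolution inside improved blocks:
#'   `"depthwise_separable"` (default) or `"standard3x3"` (the
#'   no-DS-convolution ablation).
#' @return An object of class `variant_config`.
#' @export
variant_config <- function(use_resstage = FALSE,
                           use_improved_block = FALSE,
                           use_mixed_activation = FALSE,
                           num_classes = 6L,
                           conv2_kind = c("depthwise_separable", "standard3x3")) {
  conv2_kind <- match.arg(conv2_kind)
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("num_classes must be at least 2", call. = FALSE)
  structure(
    list(
      use_resstage = isTRUE(use_resstage),
      use_improved_block = isTRUE(use_improved_block),
      use_mixed_activation = isTRUE(use_mixed_activation),
      num_classes = num_classes,
      conv2_kind = conv2_kind
    ),
    class = "variant_config"
  )
}

#' @export
print.variant_config <- function(x, ...) {
  cat("<variant_config> resstage=", x$use_resstage,
      " improved_block=", x$use_improved_block,
      " mixed_activation=", x$use_mixed_activation,
      " classes=", x$num_classes,
      if (x$conv2_kind != "depthwise_separable") " conv2=standard3x3", "\n",
      sep = "")
  invisible(x)
}

# Leaf constructors. Every leaf carries enough to (a) count its parameters,
# (b) propagate a (C, H, W) shape, (c) materialise numeric weights.
spec_conv <- function(in_ch, out_ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      groups = 1L, bias = FALSE) {
  list(kind = "conv", in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad),
       groups = as.integer(groups), bias = bias)
}
spec_bn <- function(ch) list(kind = "bn", ch = as.integer(ch))
spec_act <- function(fun, site) list(kind = "act", fun = fun, site = site)
spec_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(kind = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}
spec_gap <- function() list(kind = "gap")
spec_fc <- function(in_n, out_n, bias = TRUE) {
  list(kind = "fc", in_n = as.integer(in_n), out_n = as.integer(out_n),
       bias = bias)
}
spec_eca <- function(ch, cfg = eca_config()) {
  list(kind = "eca", ch = as.integer(ch), k = eca_kernel_size(ch, cfg))
}

act_fun <- function(cfg, site) {
  if (!cfg$use_mixed_activation) return("relu")
  # Swish on the trunk transitions (stem activation, post-addition activation
  # of End and improved blocks); PReLU at every other site.
  if (site %in% c("stem", "post_end", "post_improved")) "swish" else "prelu"
}

# Residual blocks --------------------------------------------------------------

block_spec <- function(role, in_ch, mid_ch, stride, cfg) {
  out_ch <- 4L * mid_ch
  projection <- (in_ch != out_ch) || (stride != 1L)
  b <- switch(
    role,
    baseline = list(
      branch = list(
        spec_conv(in_ch, mid_ch, 1L), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, mid_ch, 3L, stride), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, out_ch, 1L), spec_bn(out_ch)
      ),
      post = list(spec_act(act_fun(cfg, "post_baseline"), "post_baseline"))
    ),
    start = list(
      # Branch ends in a norm so the elementwise addition receives a
      # normalised signal; no activation after the addition.
      branch = list(
        spec_conv(in_ch, mid_ch, 1L), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, mid_ch, 3L, stride), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, out_ch, 1L), spec_bn(out_ch)
      ),
      post = list()
    ),
    middle = list(
      # Pre-activation: norm + activation at branch entry, branch ends with a
      # convolution, nothing after the addition. A zero-weight middle block is
      # therefore an exact identity mapping.
      branch = list(
        spec_bn(in_ch), spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(in_ch, mid_ch, 1L), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, mid_ch, 3L, stride), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, out_ch, 1L)
      ),
      post = list()
    ),
    end = list(
      # The addition is followed by norm + activation (the stage's single
      # trunk activation). The branch's last convolution is left
      # unnormalised so the per-stage norm count matches the baseline stage
      # exactly (parameter preservation).
      branch = list(
        spec_conv(in_ch, mid_ch, 1L), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, mid_ch, 3L, stride), spec_bn(mid_ch),
        spec_act(act_fun(cfg, "branch"), "branch"),
        spec_conv(mid_ch, out_ch, 1L)
      ),
      post = list(spec_bn(out_ch),
                  spec_act(act_fun(cfg, "post_end"), "post_end"))
    ),
    improved = list(
      # 1x1 conv -> norm -> act -> channel attention -> second conv (either
      # depthwise-separable with the stride in the depthwise sub-conv, or a
      # standard 3x3) -> 1x1 conv -> norm; add; trunk activation.
      branch = c(
        list(
          spec_conv(in_ch, mid_ch, 1L), spec_bn(mid_ch),
          spec_act(act_fun(cfg, "branch"), "branch"),
          spec_eca(mid_ch)
        ),
        if (cfg$conv2_kind == "depthwise_separable") {
          list(
            spec_conv(mid_ch, mid_ch, 3L, stride, groups = mid_ch),
            spec_bn(mid_ch),
            spec_act(act_fun(cfg, "branch"), "branch"),
            spec_conv(mid_ch, mid_ch, 1L), spec_bn(mid_ch)
          )
        } else {
          list(
            spec_conv(mid_ch, mid_ch, 3L, stride), spec_bn(mid_ch),
            spec_act(act_fun(cfg, "branch"), "branch")
          )
        },
        list(spec_conv(mid_ch, out_ch, 1L), spec_bn(out_ch))
      ),
      post = list(spec_act(act_fun(cfg, "post_improved"), "post_improved"))
    ),
    stop("unknown block role: ", role, call. = FALSE)
  )
  shortcut <- if (projection) {
    list(spec_conv(in_ch, out_ch, 1L, stride), spec_bn(out_ch))
  } else {
    list()
  }
  list(kind = "block", role = role, in_ch = in_ch, mid_ch = mid_ch,
       out_ch = out_ch, stride = as.integer(stride),
       branch = b$branch, shortcut = shortcut, post = b$post)
}

#' Specify a single residual block
#'
#' Public constructor for one residual block of any role: `"baseline"` (the
#' classic bottleneck: three convolutions with a post-addition activation),
#' `"start"`/`"middle"`/`"end"` (the stage-based reorganisation: the Start
#' block's branch ends in a norm and the addition is bare; Middle blocks are
#' fully pre-activated; the End block's addition is followed by norm +
#' activation), and `"improved"` (channel attention after the first
#' convolution and, by default, a depthwise-separable second convolution, the
#' stride living in the depthwise sub-convolution). Output channels are always
#' `4 * mid_channels` (bottleneck expansion); a projection shortcut (1x1
#' strided convolution + norm) is inserted exactly when shape changes demand
#' it.
#'
#' @param role Block role (see above).
#' @param in_channels,mid_channels Input and bottleneck widths.
#' @param stride 1, or 2 for the first block of a downsampling stage.
#' @param mixed_activation Use the Swish/PReLU placement instead of ReLU.
#' @param conv2_kind For `role = "improved"`: `"depthwise_separable"` or
#'   `"standard3x3"`.
#' @return A block specification usable inside a `network_plan`.
#' @export
residual_block_spec <- function(role = c("baseline", "start", "middle", "end",
                                         "improved"),
                                in_channels, mid_channels, stride = 1L,
                                mixed_activation = FALSE,
                                conv2_kind = c("depthwise_separable",
                                               "standard3x3")) {
  role <- match.arg(role)
  conv2_kind <- match.arg(conv2_kind)
  stopifnot(in_channels >= 1L, mid_channels >= 1L, stride %in% c(1L, 2L))
  cfg <- variant_config(use_mixed_activation = mixed_activation,
                        conv2_kind = conv2_kind)
  block_spec(role, as.integer(in_channels), as.integer(mid_channels),
             as.integer(stride), cfg)
}

#' Depthwise-separable convolution pair
#'
#' A 3x3 depthwise convolution (one kernel per input channel; any stride is
#' taken here) followed by norm, activation, a 1x1 pointwise channel-mixing
#' convolution, and a final norm. Learnable convolution parameters number
#' `9 * in_ch + in_ch * out_ch`, versus `9 * in_ch * out_ch` for the standard
#' 3x3 convolution it replaces.
#'
#' @param in_ch,out_ch Channel counts.
#' @param stride 1 or 2 (applied in the depthwise stage).
#' @param activation Activation function between the two sub-convolutions.
#' @return List of layer specifications with attribute `conv_params`.
#' @export
make_ds_conv <- function(in_ch, out_ch, stride = 1L, activation = "relu") {
  stopifnot(in_ch >= 1L, out_ch >= 1L, stride %in% c(1L, 2L))
  in_ch <- as.integer(in_ch)
  out_ch <- as.integer(out_ch)
  layers <- list(
    spec_conv(in_ch, in_ch, 3L, stride, groups = as.integer(in_ch)),
    spec_bn(in_ch),
    spec_act(activation, "branch"),
    spec_conv(in_ch, out_ch, 1L),
    spec_bn(out_ch)
  )
  attr(layers, "conv_params") <- 9L * in_ch + in_ch * out_ch
  layers
}

stage_spec <- function(n_blocks, in_ch, mid_ch, first_stride, resstage, improved,
                       cfg) {
  stopifnot(n_blocks >= 2L)
  roles <- if (improved) {
    rep("improved", n_blocks)
  } else if (resstage) {
    c("start", rep("middle", n_blocks - 2L), "end")
  } else {
    rep("baseline", n_blocks)
  }
  blocks <- vector("list", n_blocks)
  cur_in <- in_ch
  for (i in seq_len(n_blocks)) {
    s <- if (i == 1L) first_stride else 1L
    blocks[[i]] <- block_spec(roles[i], cur_in, mid_ch, s, cfg)
    cur_in <- 4L * mid_ch
  }
  blocks
}

#' Build the symbolic plan for a model variant
#'
#' Returns the full architecture description (stem, four stages of residual
#' blocks, classification head) for a [variant_config()]. The plan drives both
#' [complexity_report()] and [build_model()].
#'
#' @param cfg A [variant_config()].
#' @return A `network_plan` object.
#' @export
build_plan <- function(cfg) {
  stopifnot(inherits(cfg, "variant_config"))
  depths <- c(3L, 4L, 6L, 3L)
  mids <- c(64L, 128L, 256L, 512L)
  stem <- list(
    spec_conv(3L, 64L, 7L, 2L, pad = 3L), spec_bn(64L),
    spec_act(act_fun(cfg, "stem"), "stem"), spec_maxpool()
  )
  stages <- vector("list", 4L)
  in_ch <- 64L
  for (s in 1:4) {
    early <- s <= 2L
    stages[[s]] <- stage_spec(
      depths[s], in_ch, mids[s], first_stride = if (s == 1L) 1L else 2L,
      resstage = cfg$use_resstage && early,
      improved = cfg$use_improved_block && !early,
      cfg = cfg
    )
    in_ch <- 4L * mids[s]
  }
  head <- list(spec_gap(), spec_fc(2048L, cfg$num_classes))
  structure(list(cfg = cfg, stem = stem, stages = stages, head = head),
            class = "network_plan")
}

# Flatten a plan into an ordered list of leaves, tagging each with its path.
plan_leaves <- function(plan) {
  out <- list()
  push <- function(leaf, where) {
    leaf$where <- where
    out[[length(out) + 1L]] <<- leaf
  }
  for (l in plan$stem) push(l, "stem")
  for (s in seq_along(plan$stages)) {
    for (b in seq_along(plan$stages[[s]])) {
      blk <- plan$stages[[s]][[b]]
      tag <- sprintf("stage%d.block%d", s, b)
      for (l in blk$branch) push(l, paste0(tag, ".branch"))
      for (l in blk$shortcut) push(l, paste0(tag, ".shortcut"))
      for (l in blk$post) push(l, paste0(tag, ".post"))
    }
  }
  for (l in plan$head) push(l, "head")
  out
}

#' Count activation units on the trunk of a plan
#'
#' Walks the residual trunk of the network: within a stage the trunk follows
#' the shortcut chain (the path along which block inputs are carried to the
#' elementwise additions) and picks up whatever layers sit after each
#' addition. Activations inside residual branches and projection shortcuts do
#' not lie on this path. For classic bottleneck stages the count grows with
#' depth (one post-addition activation per block); a ResStage stage
#' contributes exactly one trunk activation (after the End block) regardless
#' of depth, so a network built entirely from ResStage stages carries four
#' trunk activations in total.
#'
#' @param plan A `network_plan`.
#' @param per_stage If `TRUE`, return one count per stage instead of the
#'   network total (the stem activation is excluded in that case).
#' @param include_stem Count the stem activation in the network total.
#' @return Integer count(s) of activation layers on the trunk.
#' @export
trunk_activation_count <- function(plan, per_stage = FALSE,
                                   include_stem = FALSE) {
  stage_counts <- vapply(plan$stages, function(blocks) {
    sum(vapply(blocks, function(blk) {
      sum(vapply(blk$post, function(l) l$kind == "act", logical(1)))
    }, numeric(1)))
  }, numeric(1))
  if (per_stage) return(as.integer(stage_counts))
  total <- sum(stage_counts)
  if (include_stem) {
    total <- total + sum(vapply(plan$stem, function(l) l$kind == "act",
                                logical(1)))
  }
  as.integer(total)
}
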