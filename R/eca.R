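# Efficient channel attention ---------------------------------------------------

#' Efficient-channel-attention configuration
#'
#' Parameters of the adaptive kernel-size rule `k = |log2(C)/gamma + b/gamma|_odd`.
#' With the defaults (`gamma = 2`, `b = 1`) a 256- or 512-channel feature map
#' gets a width-5 cross-channel kernel and a 64-channel map a width-3 kernel.
#'
#' @param gamma Positive integer slope divisor (default 2).
#' @param b Integer offset (default 1).
#' @param k_override Optional odd positive integer forcing the kernel width.
#' @return An `eca_config` list.
#' @export
eca_config <- function(gamma = 2L, b = 1L, k_override = NULL) {
  gamma <- as.integer(gamma)
  b <- as.integer(b)
  if (gamma < 1L) stop("gamma must be a positive integer", call. = FALSE)
  if (!is.null(k_override)) {
    k_override <- as.integer(k_override)
    if (k_override < 1L || k_override %% 2L == 0L) {
      stop("k_override must be an odd positive integer", call. = FALSE)
    }
  }
  structure(list(gamma = gamma, b = b, k_override = k_override),
            class = "eca_config")
}

#' Adaptive kernel size for channel attention
#'
#' Maps a channel count to the width of the 1-D cross-channel convolution:
#' `t = log2(C)/gamma + b/gamma`, then `k = floor(|t|)` if that is odd, else
#' `floor(|t|) + 1` (the floor-then-increment convention of the reference
#' implementation, which differs from literal rounding to the nearest odd
#' integer at some half-integer values). Always odd and at least 1.
#'
#' @param C Positive integer channel count.
#' @param cfg An [eca_config()].
#' @return Odd positive integer kernel width.
#' @examples
#' eca_kernel_size(512) # 5
#' eca_kernel_size(64)  # 3
#' @export
eca_kernel_size <- function(C, cfg = eca_config()) {
  C <- as.integer(C)
  if (is.na(C) || C < 1L) stop("C must be a positive integer", call. = FALSE)
  if (!is.null(cfg$k_override)) return(cfg$k_override)
  t <- abs(log2(C) / cfg$gamma + cfg$b / cfg$gamma)
  k <- floor(t)
  if (k %% 2 == 0) k <- k + 1
  max(1L, as.integer(k))
}

#' Channel-attention forward pass
#'
#' Reweights the channels of a feature map: global average pooling produces a
#' per-channel descriptor, a width-`k` 1-D convolution (no bias, zero-padded
#' so all `C` positions are kept) mixes neighbouring channels, a logistic
#' sigmoid turns the result into weights in (0, 1), and each channel of the
#' input is scaled by its weight. Output shape equals input shape; the module
#' owns exactly `k` learnable parameters (the kernel).
#'
#' @param x Numeric array of dimension `(C, H, W)` with finite entries.
#' @param weights Numeric kernel of odd length `k`; by default an identity
#'   (delta) kernel of the adaptive width for `C` channels.
#' @param cfg An [eca_config()].
#' @return List with `out` (same shape as `x`) and `omega` (length-`C` channel
#'   weights).
#' @export
eca_forward <- function(x, weights = NULL, cfg = eca_config()) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!all(is.finite(x))) stop("feature map must be finite", call. = FALSE)
  C <- dim(x)[1]
  k <- if (is.null(weights)) eca_kernel_size(C, cfg) else length(weights)
  if (k %% 2L == 0L) stop("kernel width must be odd", call. = FALSE)
  if (is.null(weights)) {
    weights <- numeric(k)
    weights[(k + 1L) / 2L] <- 1
  }
  y <- rowMeans(matrix(x, nrow = C))
  z <- conv1d_same(y, weights)
  omega <- sigmoid(z)
  list(out = x * omega, omega = omega)
}

# Zero-padded same-length 1-D convolution (cross-correlation, the deep-learning
# convention), no bias.
conv1d_same <- function(y, w) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  n <- length(y)
  ypad <- c(numeric(half), y, numeric(half))
  out <- numeric(n)
  for (j in seq_len(k)) {
    out <- out + w[j] * ypad[seq_len(n) + (j - 1L)]
  }
  out
}
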