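# Activation functions ---------------------------------------------------------

#' Activation functions
#'
#' The three activations used across the model family. `relu(x) = max(0, x)`;
#' `prelu(x, alpha)` is the parametric rectifier, `x` for positive inputs and
#' `alpha * x` otherwise (the slope is a learnable scalar during training,
#' shared per activation site); `swish(x) = x * sigmoid(x)`, smooth, unbounded
#' above and bounded below.
#'
#' @param x Numeric vector (or array; shape is preserved).
#' @param alpha Negative-branch slope for `prelu`; finite scalar.
#' @return Numeric of the same shape as `x`.
#' @examples
#' relu(c(-3.5, 0, 2.25))
#' prelu(c(-2, 5), alpha = 0.25)
#' swish(1)
#' @export
relu <- function(x) {
  pmax(x, 0)
}

#' @rdname relu
#' @export
prelu <- function(x, alpha = 0.25) {
  stopifnot(is.finite(alpha), length(alpha) == 1L)
  ifelse(x > 0, x, alpha * x)
}

#' @rdname relu
#' @export
swish <- function(x) {
  x * sigmoid(x)
}

#' Logistic sigmoid
#'
#' @param x Numeric.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Describe one activation site
#'
#' A small record used by block constructors: which non-linearity a site uses
#' and, for PReLU, the initial slope. PReLU sites carry one shared learnable
#' slope each (not one per channel); the handful of extra scalars keeps the
#' activation-swapped variants at the same rounded parameter count as their
#' ReLU counterparts.
#'
#' @param kind One of `"relu"`, `"prelu"`, `"swish"`.
#' @param alpha_init Initial PReLU slope (ignored for other kinds).
#' @param shared_alpha PReLU only; a single slope shared across channels.
#' @return An `activation_spec` list.
#' @export
activation_spec <- function(kind = c("relu", "prelu", "swish"),
                            alpha_init = 0.25, shared_alpha = TRUE) {
  kind <- match.arg(kind)
  if (kind == "prelu" && !is.finite(alpha_init)) {
    stop("alpha_init must be finite for prelu", call. = FALSE)
  }
  structure(list(kind = kind, alpha_init = alpha_init,
                 shared_alpha = isTRUE(shared_alpha)),
            class = "activation_spec")
}
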