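#' Activation function specification
#'
#' Describes the pointwise nonlinearity used at every activation site of a
#' gain-modulated network. Two variants are supported:
#'
#' * `"rectifier"`: the rectified linear unit, `max(0, S)`.
#' * `"saturating"`: a biologically-motivated saturating family
#'   `g(S) = a_max * tanh(h * max(0, S - c0) / a_max)`. It is non-negative,
#'   non-decreasing, behaves like a rectifier near threshold (within 2% of
#'   `max(0, S)` on `S` in `[0, 1]` at the defaults) and saturates at the
#'   response ceiling `a_max`, mimicking the bounded firing rates of real
#'   neurons.
#'
#' Under a global gain state `delta` the effective response is
#' `delta * g(S)`, so the ceiling of the saturating variant becomes
#' `delta * a_max`.
#'
#' @param kind `"saturating"` or `"rectifier"`.
#' @param h input sensitivity (slope at threshold) of the saturating variant.
#' @param c0 activation threshold of the saturating variant.
#' @param a_max response ceiling of the saturating variant (supremum of the
#'   unscaled response).
#' @return an object of class `gain_activation`.
#' @export
#' @examples
#' spec <- activation_spec("saturating")
#' gained_activation(c(-1, 0.5, 100), spec, global_gain_state(1))
activation_spec <- function(kind = c("saturating", "rectifier"),
                            h = 1, c0 = 0, a_max = 5) {
  kind <- match.arg(kind)
  if (kind == "saturating") {
    stop_if_not_scalar_number(h, "h")
    stop_if_not_scalar_number(c0, "c0")
    stop_if_not_scalar_number(a_max, "a_max")
    if (h <= 0 || a_max <= 0) stop("`h` and `a_max` must be positive", call. = FALSE)
  }
  structure(list(kind = kind, h = h, c0 = c0, a_max = a_max),
            class = "gain_activation")
}

#' Global gain state
#'
#' A single positive scalar `delta` that multiplicatively scales the output of
#' every activation function in a network, the model's proxy for cortical
#' arousal. `delta = 1` is the neutral state in which all training happens.
#'
#' @param delta positive scalar gain.
#' @return an object of class `global_gain_state`.
#' @export
global_gain_state <- function(delta = 1) {
  stop_if_not_scalar_number(delta, "delta")
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  structure(list(delta = delta), class = "global_gain_state")
}

as_delta <- function(gain) {
  if (inherits(gain, "global_gain_state")) return(gain$delta)
  stop_if_not_scalar_number(gain, "gain")
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  gain
}

# Unscaled activation g(S).
activation_base <- function(S, spec) {
  if (spec$kind == "rectifier") return(pmax(S, 0))
  spec$a_max * tanh(spec$h * pmax(S - spec$c0, 0) / spec$a_max)
}

# Elementwise derivative g'(S) (subgradient 0 at the kink).
activation_base_grad <- function(S, spec) {
  if (spec$kind == "rectifier") return((S > 0) * 1)
  u <- spec$h * pmax(S - spec$c0, 0) / spec$a_max
  (S > spec$c0) * spec$h / cosh(u)^2
}

#' Gain-scaled activation function
#'
#' Applies the configured activation elementwise and scales the result by the
#' global gain `delta`: `f(S) = delta * g(S)`. For the rectifier this is
#' `delta * max(0, S)`; for the saturating variant the response is bounded by
#' `delta * a_max`.
#'
#' @param S numeric array of incoming activations.
#' @param spec an [activation_spec()].
#' @param gain a [global_gain_state()] or a positive scalar.
#' @return numeric array shaped like `S`.
#' @export
gained_activation <- function(S, spec, gain = global_gain_state(1)) {
  if (!inherits(spec, "gain_activation")) stop("`spec` must be an activation_spec()", call. = FALSE)
  if (!all(is.finite(S))) stop("non-finite values in `S`", call. = FALSE)
  delta <- as_delta(gain)
  out <- activation_base(S, spec)
  if (delta != 1) out <- delta * out
  out
}
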