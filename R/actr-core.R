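#' Base-level activation of the wh-element
#'
#' The base-level activation of an item encoded once, `t` seconds ago,
#' decays as a power law of time: on the activation scale
#' \deqn{BA(t) = -d \log t + \beta}
#' where `d` is the decay rate and `beta` the base-level constant. For
#' `d > 0` the function is strictly decreasing in `t`; for `d = 0` it is
#' flat at `beta`.
#'
#' @param t Time since encoding in seconds; must be positive. Vectorized.
#' @param params An [actr_params()] object.
#' @return Activation value(s), same length as `t`.
#' @export
base_activation <- function(t, params) {
  stopifnot(inherits(params, "actr_params"))
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("time since encoding t must be positive and finite", call. = FALSE)
  }
  -params$d * log(t) + params$beta
}

#' Spreading activation from the retrieval cues
#'
#' The retrieval cues at the dependency's head boost the target's
#' activation by
#' \deqn{S = W \sum_c w_c \, (MAS - \log n_c)}
#' where `W` is the source activation, `w_c` the weight of cue `c`, `MAS`
#' the maximum associative strength and `n_c` the number of memory items
#' matching cue `c` (the fan). With the default fan profile (1, 5, 5) the
#' unique +wh cue contributes `MAS - log(1) = MAS` while the shared cues
#' are penalized by `log(5)`.
#'
#' @param params An [actr_params()] object. The cue weights must sum to 1.
#' @param fan A [fan_profile()]; defaults to the study profile (1, 5, 5).
#' @return A single activation value.
#' @export
spreading_activation <- function(params, fan = fan_profile()) {
  stopifnot(inherits(params, "actr_params"), inherits(fan, "fan_profile"))
  n <- c(fan$n_wh, fan$n_anim, fan$n_NP)
  assoc <- params$MAS - log(n)
  if (any(assoc <= 0)) {
    stop("MAS - log(fan) must be positive for every cue; increase MAS ",
         "or reduce the fan", call. = FALSE)
  }
  w <- c(params$w_wh, params$w_anim, params$w_NP)
  params$W * sum(w * assoc)
}

#' Draw logistic activation noise
#'
#' Activation noise follows a logistic distribution with mean zero and
#' scale `sigma` (variance \eqn{\pi^2\sigma^2/3}). A scale of exactly zero
#' yields deterministic zeros.
#'
#' @param n Number of draws.
#' @param params An [actr_params()] object supplying `sigma`.
#' @return Numeric vector of `n` noise values.
#' @export
sample_noise <- function(n, params) {
  stopifnot(inherits(params, "actr_params"), n >= 0)
  if (params$sigma == 0) {
    return(rep(0, n))
  }
  stats::rlogis(n, location = 0, scale = params$sigma)
}

#' Total activation at retrieval
#'
#' The activation that determines the retrieval latency is the sum of the
#' base-level activation, the spreading activation from the cues, and a
#' noise draw. (The mismatch-penalty component of full ACT-R is omitted:
#' only the retrieval of the fully matching wh-element is modeled.)
#'
#' @param ba Base-level activation.
#' @param s Spreading activation.
#' @param noise Noise component; defaults to 0.
#' @return `ba + s + noise` (vectorized).
#' @export
total_activation <- function(ba, s, noise = 0) {
  ba + s + noise
}

#' Retrieval latency from activation
#'
#' Latency is an exponentially decreasing function of activation,
#' \eqn{Latency = F e^{-A}}, with the latency factor `F` in seconds.
#'
#' @param A Activation value(s).
#' @param F Latency factor in seconds; positive.
#' @return Latency in seconds, same length as `A`.
#' @export
latency_from_activation <- function(A, F) {
  stopifnot(is.numeric(F), length(F) == 1L, F > 0)
  F * exp(-A)
}

#' Maximum retrieval latency implied by the threshold
#'
#' An item needs activation of at least `tau` to be retrieved, so the
#' slowest completed retrieval takes \eqn{F e^{-\tau}} seconds. With
#' `tau = -Inf` there is no threshold and the maximum latency is infinite.
#'
#' @param params An [actr_params()] object.
#' @return Time-out in seconds (`Inf` when there is no threshold).
#' @export
max_latency <- function(params) {
  stopifnot(inherits(params, "actr_params"))
  latency_from_activation(params$tau, params$F)
}

#' Apply a capacity mapping to a parameter set
#'
#' Translates a normalized working-memory-capacity index in `[0, 1]` into
#' a concrete parameter set: exactly one parameter of `base` is replaced
#' by the linear interpolation between the mapping's endpoints. For the
#' `interference` mapping the residual weight `1 - w_wh` is split equally
#' between `w_anim` and `w_NP` so that the weights still sum to one.
#'
#' @param mapping A [capacity_mapping()].
#' @param wmc_index Normalized capacity in `[0, 1]` (0 = lowest capacity).
#' @param base An [actr_params()] object to be modified.
#' @return A new [actr_params()] object.
#' @examples
#' pre <- actr_preset("modified", "decay_rate")
#' map_wmc(pre$mapping, 0, pre$params)$d  # 0.62, the low-capacity end
#' @export
map_wmc <- function(mapping, wmc_index, base) {
  stopifnot(inherits(mapping, "capacity_mapping"),
            inherits(base, "actr_params"))
  if (!is.numeric(wmc_index) || length(wmc_index) != 1L ||
      is.na(wmc_index) || wmc_index < 0 || wmc_index > 1) {
    stop("wmc_index must be a single value in [0, 1]", call. = FALSE)
  }
  value <- mapping$low_end + wmc_index * (mapping$high_end - mapping$low_end)
  out <- unclass(base)
  switch(mapping$kind,
    decay_rate = {
      out$d <- value
    },
    source_activation = {
      out$W <- value
    },
    interference = {
      out$w_wh <- value
      out$w_anim <- out$w_NP <- (1 - value) / 2
    }
  )
  do.call(actr_params, out)
}
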