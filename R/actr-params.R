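#' Parameter set for the simplified ACT-R retrieval model
#'
#' Bundles the parameters that govern a single declarative-memory retrieval:
#' the latency factor `F` (seconds), the base-level decay rate `d`, the
#' source activation `W` and the three retrieval-cue weights (`w_wh`,
#' `w_anim`, `w_NP`, which must sum to one), the maximum associative
#' strength `MAS`, the logistic activation-noise scale `sigma`, the
#' base-level constant `beta`, and the retrieval threshold `tau`
#' (`-Inf` means "no threshold": retrievals never time out).
#'
#' @param F Latency factor in seconds; must be positive.
#' @param d Base-level decay rate; non-negative.
#' @param W Source activation shared between the retrieval cues; non-negative.
#' @param w_wh,w_anim,w_NP Cue weights for the unique wh-cue and the shared
#'   animacy and NP cues. Must be non-negative and sum to one.
#' @param MAS Maximum associative strength.
#' @param sigma Scale of the zero-mean logistic activation noise
#'   (variance \eqn{\pi^2 \sigma^2 / 3}); non-negative.
#' @param beta Base-level constant (activation units).
#' @param tau Retrieval threshold (activation units); may be `-Inf`.
#'
#' @return An object of class `actr_params` (a named list).
#' @examples
#' p <- actr_params()
#' max_latency(p)
#' @export
actr_params <- function(F = 1.6, d = 0.5, W = 1,
                        w_wh = 1 / 3, w_anim = 1 / 3, w_NP = 1 / 3,
                        MAS = 2, sigma = 0.25, beta = -1, tau = 0) {
  stopifnot(is.numeric(F), length(F) == 1L, F > 0)
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0)
  stopifnot(is.numeric(W), length(W) == 1L, W >= 0)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  stopifnot(is.numeric(MAS), is.numeric(beta), is.numeric(tau))
  w <- c(w_wh, w_anim, w_NP)
  if (any(w < 0)) {
    stop("cue weights must be non-negative", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-8) {
    stop("cue weights w_wh + w_anim + w_NP must sum to 1 (got ",
         format(sum(w)), ")", call. = FALSE)
  }
  structure(
    list(F = F, d = d, W = W, w_wh = w_wh, w_anim = w_anim, w_NP = w_NP,
         MAS = MAS, sigma = sigma, beta = beta, tau = tau),
    class = "actr_params"
  )
}

#' @export
print.actr_params <- function(x, ...) {
  cat("<actr_params>\n")
  cat(sprintf("  F = %.3g s, d = %.3g, W = %.3g, MAS = %.3g\n",
              x$F, x$d, x$W, x$MAS))
  cat(sprintf("  weights (wh, anim, NP) = (%.3g, %.3g, %.3g)\n",
              x$w_wh, x$w_anim, x$w_NP))
  cat(sprintf("  sigma = %.3g, beta = %.3g, tau = %s\n",
              x$sigma, x$beta, format(x$tau)))
  invisible(x)
}

#' Fan profile of the retrieval cues
#'
#' Counts of memory items matching each retrieval cue. In the study design
#' the wh-element is the only +wh item while five noun phrases in total
#' match the +animate and +NP cues, giving the default profile (1, 5, 5).
#' The matching-item count enters the spreading-activation equation as
#' `MAS - log(n)`.
#'
#' @param n_wh,n_anim,n_NP Number of items matching each cue (integers >= 1).
#' @return An object of class `fan_profile`.
#' @export
fan_profile <- function(n_wh = 1, n_anim = 5, n_NP = 5) {
  n <- c(n_wh, n_anim, n_NP)
  if (any(n < 1) || any(n != round(n))) {
    stop("fan counts must be integers >= 1", call. = FALSE)
  }
  structure(list(n_wh = n_wh, n_anim = n_anim, n_NP = n_NP),
            class = "fan_profile")
}

#' @export
print.fan_profile <- function(x, ...) {
  cat(sprintf("<fan_profile> wh: %d, anim: %d, NP: %d\n",
              x$n_wh, x$n_anim, x$n_NP))
  invisible(x)
}

# Published exploration ranges for the WMC-linked parameters, per variant.
.mapping_ranges <- list(
  default  = list(decay_rate = c(0.06, 1.5),
                  source_activation = c(0.5, 3.5),
                  interference = c(0.1, 1)),
  modified = list(decay_rate = c(0.33, 0.62),
                  source_activation = c(0.9, 1.2),
                  interference = c(0.2, 0.5))
)

#' Linking map from working-memory capacity to one ACT-R parameter
#'
#' A capacity mapping translates a normalized WMC index in `[0, 1]` into a
#' value of one retrieval parameter by linear interpolation between two
#' endpoints. Three linking hypotheses are supported:
#' * `"decay_rate"` — higher capacity means a *lower* decay rate `d`;
#' * `"source_activation"` — higher capacity means *more* source
#'   activation `W`;
#' * `"interference"` — higher capacity means more weight `w_wh` on the
#'   unique retrieval cue (less susceptibility to interference from the
#'   shared cues).
#'
#' @param kind One of `"decay_rate"`, `"source_activation"`,
#'   `"interference"`.
#' @param low_end Parameter value at WMC index 0 (lowest capacity).
#' @param high_end Parameter value at WMC index 1 (highest capacity).
#'
#' @details The direction of the map is enforced: for `decay_rate` the
#' value must not increase with capacity, for the other two kinds it must
#' not decrease. Endpoints outside the published exploration ranges
#' (`d` in \[0.06, 1.5\], `W` in \[0.5, 3.5\], `w_wh` in \[0.1, 1\])
#' trigger a warning, not an error.
#'
#' @return An object of class `capacity_mapping`.
#' @seealso [map_wmc()], [actr_preset()]
#' @export
capacity_mapping <- function(kind = c("decay_rate", "source_activation",
                                      "interference"),
                             low_end, high_end) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(low_end), is.numeric(high_end))
  if (kind == "decay_rate") {
    if (high_end > low_end) {
      stop("decay_rate mapping must be non-increasing in capacity ",
           "(low_end >= high_end)", call. = FALSE)
    }
  } else if (low_end > high_end) {
    stop(kind, " mapping must be non-decreasing in capacity ",
         "(low_end <= high_end)", call. = FALSE)
  }
  rng <- .mapping_ranges$default[[kind]]
  if (min(low_end, high_end) < rng[1] || max(low_end, high_end) > rng[2]) {
    warning("mapping endpoints [", format(min(low_end, high_end)), ", ",
            format(max(low_end, high_end)), "] fall outside the published ",
            kind, " range [", rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  structure(list(kind = kind, low_end = low_end, high_end = high_end),
            class = "capacity_mapping")
}

#' @export
print.capacity_mapping <- function(x, ...) {
  cat(sprintf("<capacity_mapping> %s: %.3g (WMC = 0) -> %.3g (WMC = 1)\n",
              x$kind, x$low_end, x$high_end))
  invisible(x)
}

#' Preset parameter sets for the retrieval simulations
#'
#' Returns the published parameter configuration for one of the two model
#' variants and one of the three capacity mappings. The `"default"` variant
#' is the standard ACT-R setup where sub-threshold retrievals fail at the
#' time-out `F * exp(-tau)` (with `threshold = FALSE` there is no threshold
#' at all, `tau = -Inf`); the `"modified"` variant aborts failed retrievals
#' at a uniformly distributed time before the time-out.
#'
#' @param variant `"default"` or `"modified"`.
#' @param mapping `"decay_rate"`, `"source_activation"` or `"interference"`.
#' @param threshold For the default variant only: if `FALSE`, `tau = -Inf`
#'   (no time-out). The modified variant always has `tau = 0`.
#'
#' @return A list with elements `params` (an [actr_params()] object whose
#'   WMC-linked parameter is set to the midpoint of its range) and
#'   `mapping` (a [capacity_mapping()] spanning that range in the direction
#'   fixed by the linking hypothesis).
#' @examples
#' pre <- actr_preset("modified", "decay_rate")
#' pre$params$beta  # -0.3
#' @export
actr_preset <- function(variant = c("default", "modified"),
                        mapping = c("decay_rate", "source_activation",
                                    "interference"),
                        threshold = TRUE) {
  variant <- match.arg(variant)
  mapping <- match.arg(mapping)
  rng <- .mapping_ranges[[variant]][[mapping]]
  beta <- if (variant == "modified") {
    -0.3
  } else if (mapping == "decay_rate") {
    -0.65
  } else {
    -1
  }
  tau <- if (variant == "modified" || threshold) 0 else -Inf
  base <- actr_params(F = 1.6, d = 0.5, W = 1, MAS = 2, sigma = 0.25,
                      beta = beta, tau = tau)
  mid <- mean(rng)
  base <- switch(mapping,
    decay_rate = { base$d <- mid; base },
    source_activation = { base$W <- mid; base },
    interference = {
      base$w_wh <- mid
      base$w_anim <- base$w_NP <- (1 - mid) / 2
      base
    }
  )
  map <- if (mapping == "decay_rate") {
    capacity_mapping(mapping, low_end = rng[2], high_end = rng[1])
  } else {
    capacity_mapping(mapping, low_end = rng[1], high_end = rng[2])
  }
  list(params = base, mapping = map, variant = variant)
}

#' Read retrieval-model parameters from a JSON or YAML configuration file
#'
#' The file either names a preset (`preset: "default"` or `"modified"`,
#' optionally with `mapping` and `threshold`) or gives the parameters
#' directly under the keys `F`, `d`, `W`, `w_wh`, `w_anim`, `w_NP`, `MAS`,
#' `sigma`, `beta`, `tau` (missing keys fall back to the [actr_params()]
#' defaults; `tau` may be the string `"-Inf"`).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [actr_params()] object, or the full preset list when the file
#'   names a preset.
#' @export
read_actr_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$preset)) {
    return(actr_preset(cfg$preset,
                       mapping = cfg$mapping %||% "decay_rate",
                       threshold = cfg$threshold %||% TRUE))
  }
  if (!is.null(cfg$tau) && is.character(cfg$tau)) {
    cfg$tau <- as.numeric(cfg$tau)
  }
  defaults <- formals(actr_params)
  keys <- names(defaults)
  args <- lapply(keys, function(k) cfg[[k]] %||% eval(defaults[[k]]))
  names(args) <- keys
  do.call(actr_params, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
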