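#' Closed-form locality effect on raw latencies
#'
#' The locality effect is the latency difference between the long and the
#' short dependency conditions. Because only the base-level activation
#' differs between distances while the spreading activation `S` is common,
#' it factorizes as
#' \deqn{Locality = F e^{-S} (e^{-BA_{low}} - e^{-BA_{high}})}
#' where `BA_high` is the base-level activation at the short distance and
#' `BA_low` at the long distance (decay makes `BA_low <= BA_high`). The
#' factorized form equals the direct difference of two
#' [latency_from_activation()] calls to machine precision, and is
#' non-negative whenever `BA_low <= BA_high`: on raw latencies these
#' linking models can only produce slowdowns with distance, never a
#' speedup.
#'
#' @param ba_high Base-level activation at the short distance.
#' @param ba_low Base-level activation at the long distance.
#' @param s Spreading activation (shared by both conditions).
#' @param F Latency factor in seconds.
#' @return Locality effect in seconds. Vectorized.
#' @export
locality_raw <- function(ba_high, ba_low, s, F) {
  F * exp(-s) * (exp(-ba_low) - exp(-ba_high))
}

#' Closed-form WMC-by-locality interaction on raw latencies
#'
#' When capacity affects only the spreading activation (`S` low for
#' low-capacity readers, high for high-capacity readers), the interaction
#' between locality and capacity on raw latencies is the double difference
#' \deqn{Locality \times WMC = F (e^{-S_{low}} - e^{-S_{high}})
#'   (e^{-BA_{low}} - e^{-BA_{high}})}
#' i.e. the locality effect of low-capacity minus that of high-capacity
#' readers. It vanishes iff either factor does.
#'
#' @param s_low,s_high Spreading activation for the low- and high-capacity
#'   readers.
#' @param ba_high,ba_low Base-level activation at the short and long
#'   distances.
#' @param F Latency factor in seconds.
#' @return Interaction in seconds. Vectorized.
#' @export
locality_wmc_interaction_raw <- function(s_low, s_high, ba_high, ba_low, F) {
  F * (exp(-s_low) - exp(-s_high)) * (exp(-ba_low) - exp(-ba_high))
}

#' Locality effect on the log-latency scale
#'
#' On log latencies the locality effect is
#' \deqn{\log Latency_{long} - \log Latency_{short} = BA_{high} - BA_{low}}
#' which depends on neither the spreading activation `S` nor the latency
#' factor `F`: both cancel in the difference. (The quantity is a
#' difference of log latencies, not the log of the raw-latency
#' difference.) Consequently, if capacity enters only through `S` — as in
#' the capacity-as-source-activation and capacity-as-interference linking
#' models — the WMC-by-locality interaction on log latencies is exactly
#' zero, for every parameter setting. Under the decay model,
#' `BA_high - BA_low = d * log(t_long / t_short)`.
#'
#' @param ba_high,ba_low Base-level activation at the short and long
#'   distances.
#' @return Log-latency difference (dimensionless). Vectorized.
#' @export
locality_log <- function(ba_high, ba_low) {
  ba_high - ba_low
}

#' Run the analytic identity suite
#'
#' Checks the closed-form locality algebra against brute-force latency
#' differences on randomized parameter draws, including the key
#' zero-interaction identity: with capacity linked to spreading activation
#' (source-activation or interference mapping), no noise and no threshold,
#' the WMC-by-locality interaction on log latencies is 0 to machine
#' precision.
#'
#' @param n_draws Number of random parameter draws per identity.
#' @param seed Integer seed.
#' @param tol Absolute tolerance for the machine-precision identities.
#' @return A tibble with one row per identity: `identity`, `max_abs_dev`
#'   (largest absolute deviation observed) and `pass`.
#' @export
check_identities <- function(n_draws = 100, seed = 1L, tol = 1e-12) {
  set.seed(seed)
  draw <- function() {
    list(F = stats::runif(1, 0.5, 3),
         d = stats::runif(1, 0.05, 1.5),
         beta = stats::runif(1, -1.5, 0.5),
         MAS = stats::runif(1, 1.8, 3),
         t_short = stats::runif(1, 0.5, 3),
         t_long = stats::runif(1, 3.5, 10),
         W_low = stats::runif(1, 0.5, 1),
         W_high = stats::runif(1, 1.5, 3.5),
         w_wh_low = stats::runif(1, 0.1, 0.4),
         w_wh_high = stats::runif(1, 0.5, 1))
  }
  dev_factor <- dev_inter <- dev_log_src <- dev_log_int <- dev_loglaw <-
    numeric(n_draws)
  for (i in seq_len(n_draws)) {
    g <- draw()
    mk <- function(W, w_wh) {
      actr_params(F = g$F, d = g$d, W = W, w_wh = w_wh,
                  w_anim = (1 - w_wh) / 2, w_NP = (1 - w_wh) / 2,
                  MAS = g$MAS, sigma = 0, beta = g$beta, tau = -Inf)
    }
    lat <- function(p, t) {
      latency_from_activation(
        base_activation(t, p) + spreading_activation(p), p$F)
    }
    p <- mk(g$W_low, 1 / 3)
    ba_high <- base_activation(g$t_short, p)
    ba_low <- base_activation(g$t_long, p)
    s <- spreading_activation(p)
    # factorized raw locality vs direct latency difference
    dev_factor[i] <- abs(locality_raw(ba_high, ba_low, s, g$F) -
                           (lat(p, g$t_long) - lat(p, g$t_short)))
    # factorized interaction vs four-cell double difference (W varies)
    p_hi <- mk(g$W_high, 1 / 3)
    s_hi <- spreading_activation(p_hi)
    brute <- (lat(p, g$t_long) - lat(p, g$t_short)) -
      (lat(p_hi, g$t_long) - lat(p_hi, g$t_short))
    dev_inter[i] <- abs(
      locality_wmc_interaction_raw(s, s_hi, ba_high, ba_low, g$F) - brute)
    # zero interaction on log latencies: capacity as source activation
    dev_log_src[i] <- abs(
      (log(lat(p, g$t_long)) - log(lat(p, g$t_short))) -
        (log(lat(p_hi, g$t_long)) - log(lat(p_hi, g$t_short))))
    # zero interaction on log latencies: capacity as interference
    q_lo <- mk(1, g$w_wh_low)
    q_hi <- mk(1, g$w_wh_high)
    dev_log_int[i] <- abs(
      (log(lat(q_lo, g$t_long)) - log(lat(q_lo, g$t_short))) -
        (log(lat(q_hi, g$t_long)) - log(lat(q_hi, g$t_short))))
    # log-scale locality equals d * log(t_long / t_short)
    dev_loglaw[i] <- abs(locality_log(ba_high, ba_low) -
                           g$d * log(g$t_long / g$t_short))
  }
  tibble::tibble(
    identity = c(
      "raw locality: factorized form equals direct latency difference",
      "raw interaction: factorized form equals four-cell double difference",
      "log-latency WMC x locality interaction is 0 (source activation)",
      "log-latency WMC x locality interaction is 0 (interference)",
      "log-latency locality equals d * log(t_long / t_short)"
    ),
    max_abs_dev = c(max(dev_factor), max(dev_inter), max(dev_log_src),
                    max(dev_log_int), max(dev_loglaw)),
    pass = .data$max_abs_dev <= tol
  )
}
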