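#' Simulate retrieval attempts
#'
#' Draws `n` independent retrieval attempts at `t` seconds after encoding.
#' Each attempt realizes an activation `A = BA + S + eps` with a fresh
#' logistic noise draw; the same realized activation governs both the
#' success check and the latency:
#' * `A >= tau`: the retrieval completes with latency `F * exp(-A)`;
#' * `A < tau`, `variant = "default"`: the retrieval fails at exactly the
#'   time-out `F * exp(-tau)` (the threshold acts as a time-out);
#' * `A < tau`, `variant = "modified"`: the retrieval is aborted at a
#'   uniformly distributed time on `(0, F * exp(-tau))`, so failures are
#'   faster than the time-out (and, typically, than completed retrievals).
#'
#' @param params An [actr_params()] object.
#' @param t Time since encoding of the wh-element, in seconds (> 0).
#' @param variant `"default"` (time-out failures) or `"modified"`
#'   (early-abort failures).
#' @param n Number of attempts to simulate.
#' @param fan A [fan_profile()]; defaults to (1, 5, 5).
#' @param abort_sampler For the modified variant, a function
#'   `function(n, timeout)` returning `n` abort times in
#'   `(0, timeout)`; defaults to the uniform sampler. Any distribution
#'   whose mean is below the mean completed latency reproduces the
#'   fast-failure pattern.
#' @return A tibble with columns `completed` (logical), `latency`
#'   (seconds) and `activation` (the realized, noisy `A`).
#' @export
simulate_retrieval <- function(params, t,
                               variant = c("default", "modified"),
                               n = 1, fan = fan_profile(),
                               abort_sampler = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "actr_params"), n >= 1)
  ba <- base_activation(t, params)
  s <- spreading_activation(params, fan)
  A <- total_activation(ba, s, sample_noise(n, params))
  completed <- A >= params$tau
  latency <- latency_from_activation(A, params$F)
  timeout <- max_latency(params)
  nf <- sum(!completed)
  if (nf > 0) {
    latency[!completed] <- if (variant == "default") {
      timeout
    } else if (is.null(abort_sampler)) {
      stats::runif(nf, 0, timeout)
    } else {
      abort_sampler(nf, timeout)
    }
  }
  tibble::tibble(completed = completed, latency = latency, activation = A)
}

#' Closed-form probability of retrieval failure
#'
#' With logistic noise of scale `sigma` on the activation, the probability
#' that a retrieval fails to reach the threshold is the logistic CDF
#' \deqn{P(BA + S + \epsilon < \tau) = \mathrm{logit}^{-1}\!\left(
#'   \frac{\tau - BA - S}{\sigma}\right).}
#' This is the exact oracle against which the Monte Carlo failure
#' proportions of [simulate_retrieval()] are checked. It is strictly
#' increasing in `t` (base-level activation decays) and equals the
#' degenerate 0/1 answer when `sigma = 0` or `tau = -Inf`.
#'
#' @param params An [actr_params()] object.
#' @param t Time since encoding in seconds (> 0). Vectorized.
#' @param fan A [fan_profile()].
#' @return Failure probability in `[0, 1]`, same length as `t`.
#' @export
failure_probability <- function(params, t, fan = fan_profile()) {
  stopifnot(inherits(params, "actr_params"))
  det_A <- base_activation(t, params) + spreading_activation(params, fan)
  if (params$tau == -Inf) {
    return(rep(0, length(t)))
  }
  if (params$sigma == 0) {
    return(as.numeric(det_A < params$tau))
  }
  stats::plogis((params$tau - det_A) / params$sigma)
}

#' Configuration of a WMC-by-distance simulation sweep
#'
#' @param n_trials Retrieval attempts per (WMC, distance) cell.
#' @param wmc_grid Normalized capacity indices in `[0, 1]`.
#' @param t_short,t_long Seconds since encoding for the short and long
#'   dependency conditions; `t_long > t_short > 0`. The defaults (2 s and
#'   6 s) are on the order of reading 3--4 vs. 9--10 words.
#' @param variant `"default"` or `"modified"` (see [simulate_retrieval()]).
#' @param mapping A [capacity_mapping()] linking WMC to one parameter.
#' @param base An [actr_params()] object for all remaining parameters.
#' @param fan A [fan_profile()].
#' @param seed Integer seed; the sweep is fully reproducible.
#' @return An object of class `simulation_config`.
#' @seealso [run_grid()], [actr_preset()]
#' @export
simulation_config <- function(n_trials = 5000,
                              wmc_grid = seq(0, 1, by = 0.25),
                              t_short = 2, t_long = 6,
                              variant = c("default", "modified"),
                              mapping, base, fan = fan_profile(),
                              seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(mapping, "capacity_mapping"),
            inherits(base, "actr_params"),
            n_trials >= 1, t_short > 0, t_long > t_short,
            all(wmc_grid >= 0 & wmc_grid <= 1))
  structure(
    list(n_trials = as.integer(n_trials), wmc_grid = wmc_grid,
         t_short = t_short, t_long = t_long, variant = variant,
         mapping = mapping, base = base, fan = fan,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Run a WMC-by-distance retrieval sweep
#'
#' Simulates `n_trials` retrievals in every cell of the grid
#' `wmc_grid x {t_short, t_long}` and summarizes each cell by its mean
#' latency, failure proportion, and the mean latencies of completed and
#' failed retrievals separately. The per-trial table is kept so that
#' downstream consumers (e.g. [inject_retrieval_mixture()]) can resample
#' realized latencies rather than cell means.
#'
#' @param config A [simulation_config()].
#' @return An object of class `retrieval_grid`: a list with `summary`
#'   (one row per cell: `wmc_index`, `distance`, `t`, `n`, `mean_latency`,
#'   `failure_prop`, `mean_success_latency`, `mean_failure_latency`),
#'   `trials` (per-trial tibble with `wmc_index`, `distance`, `trial`,
#'   `completed`, `latency_s`, `activation`), and `config`.
#' @export
run_grid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cells <- expand.grid(wmc_index = config$wmc_grid,
                       distance = c("short", "long"),
                       stringsAsFactors = FALSE)
  cells$t <- ifelse(cells$distance == "long", config$t_long, config$t_short)
  trials <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- map_wmc(config$mapping, cells$wmc_index[i], config$base)
    out <- simulate_retrieval(p, cells$t[i], variant = config$variant,
                              n = config$n_trials, fan = config$fan)
    trials[[i]] <- tibble::tibble(
      wmc_index = cells$wmc_index[i],
      distance = cells$distance[i],
      trial = seq_len(config$n_trials),
      completed = out$completed,
      latency_s = out$latency,
      activation = out$activation
    )
  }
  trials <- dplyr::bind_rows(trials)
  summary <- trials |>
    dplyr::group_by(.data$wmc_index, .data$distance) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_latency = mean(.data$latency_s),
      failure_prop = mean(!.data$completed),
      mean_success_latency = if (any(.data$completed)) {
        mean(.data$latency_s[.data$completed])
      } else {
        NA_real_
      },
      mean_failure_latency = if (any(!.data$completed)) {
        mean(.data$latency_s[!.data$completed])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(
      tibble::tibble(distance = c("short", "long"),
                     t = c(config$t_short, config$t_long)),
      by = "distance"
    ) |>
    dplyr::relocate("t", .after = "distance")
  structure(list(summary = summary, trials = trials, config = config),
            class = "retrieval_grid")
}

#' @export
print.retrieval_grid <- function(x, ...) {
  cat(sprintf("<retrieval_grid> %s variant, %s mapping, %d trials/cell\n",
              x$config$variant, x$config$mapping$kind, x$config$n_trials))
  print(x$summary)
  invisible(x)
}

#' Locality effect (long minus short mean latency) per WMC grid point
#'
#' @param grid A [run_grid()] result.
#' @return A tibble with `wmc_index` and `locality_s`, the difference in
#'   mean latency between the long and short distance conditions
#'   (positive = slowdown with distance, negative = speedup).
#' @export
grid_locality <- function(grid) {
  stopifnot(inherits(grid, "retrieval_grid"))
  grid$summary |>
    dplyr::select("wmc_index", "distance", "mean_latency") |>
    tidyr::pivot_wider(names_from = "distance",
                       values_from = "mean_latency") |>
    dplyr::mutate(locality_s = .data$long - .data$short) |>
    dplyr::select("wmc_index", "locality_s")
}

#' Expected reading time at the head region under the retrieval mixture
#'
#' The expected time at the critical region decomposes into a baseline
#' component plus the mixture of completed and failed retrievals:
#' \deqn{T = T_{baseline} + P \cdot T_{retrieval} + (1 - P) \cdot T_{failure}}
#' where `P` is the retrieval (success) probability.
#'
#' @param p_retrieval Probability that the retrieval completes, in `[0, 1]`.
#' @param t_retrieval Mean latency of completed retrievals (seconds).
#' @param t_failure Mean latency of failed retrievals (seconds).
#' @param t_baseline Baseline region time (seconds); default 0.
#' @return Expected total time in seconds. Vectorized; `NA` mixture
#'   components with zero weight are treated as 0.
#' @export
expected_cell_time <- function(p_retrieval, t_retrieval, t_failure,
                               t_baseline = 0) {
  if (any(p_retrieval < 0 | p_retrieval > 1, na.rm = TRUE)) {
    stop("p_retrieval must lie in [0, 1]", call. = FALSE)
  }
  t_retrieval <- ifelse(p_retrieval == 0 & is.na(t_retrieval), 0, t_retrieval)
  t_failure <- ifelse(p_retrieval == 1 & is.na(t_failure), 0, t_failure)
  t_baseline + p_retrieval * t_retrieval + (1 - p_retrieval) * t_failure
}
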