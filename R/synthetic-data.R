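#' Generate a table of participants with individual-difference covariates
#'
#' Draws working-memory-capacity scores (partial-credit-unit scale, in
#' `[0, 1]`) and reading-fluency scores (rapid-naming speed in
#' characters/second) for `n` participants. The two covariates are drawn
#' independently — in the motivating experiments they were uncorrelated
#' (r about -0.04) — from normal distributions truncated to ranges typical
#' of university-student samples (PCU roughly 0.28--0.92 around 0.63;
#' fluency roughly 1.4--3.6 around 2.5 chars/s).
#'
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed.
#' @param wmc_range,rf_range Truncation ranges for the two covariates.
#' @param wmc_mean,wmc_sd,rf_mean,rf_sd Moments of the untruncated normals.
#' @return A tibble with columns `participant`, `wmc_score`, `rf_score`.
#' @export
generate_participants <- function(n, seed = NULL,
                                  wmc_range = c(0.28, 0.92),
                                  rf_range = c(1.4, 3.6),
                                  wmc_mean = 0.63, wmc_sd = 0.13,
                                  rf_mean = 2.5, rf_sd = 0.45) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    participant = seq_len(n),
    wmc_score = rtruncnorm_(n, wmc_mean, wmc_sd, wmc_range[1], wmc_range[2]),
    rf_score = rtruncnorm_(n, rf_mean, rf_sd, rf_range[1], rf_range[2])
  )
}

# inverse-CDF draw from a normal truncated to [a, b]
rtruncnorm_ <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Specification of the synthetic self-paced-reading generator
#'
#' Defines the study design emulated by [generate_dataset()]: a 2 x 2
#' within-participant manipulation (embedded-subject length x dependency
#' type, both sum-coded -1/+1) crossed with 5 sentence regions
#' (precritical, critical1, critical2, spillover1, spillover2), crossed
#' random effects for participants, items and sentences, and reading
#' times that are shifted-lognormal with a participant-specific shift.
#'
#' True fixed effects are given on the standardized effect-size (delta)
#' scale and converted to log-RT units as `beta = delta * sigma`; the
#' defaults echo the magnitudes reported for this design (e.g. a
#' three-way length:dependency:WMC interaction of delta = 0.04).
#'
#' @param n_participants,n_items Design size; `n_items` should be a
#'   multiple of 4 so the Latin-square assignment balances conditions.
#' @param intercept Grand mean of log(RT - shift), log-ms scale.
#' @param effects Named numeric vector of true effect sizes (delta scale)
#'   with names among `length`, `dependency`, `wmc`, `rf`,
#'   `length:dependency`, `length:dependency:wmc`, `length:dependency:rf`.
#' @param region_coefs Four coefficients (log-RT scale) for the Helmert
#'   region contrasts; default all zero (flat region profile).
#' @param sigma Residual SD on the log scale.
#' @param re_sd Named list of random-effect SDs (log scale):
#'   `participant`, `item`, `sentence` intercept SDs, and optional
#'   length-3 vectors `participant_slopes`, `item_slopes` for the
#'   (length, dependency, length:dependency) slopes.
#' @param re_cor Optional list with 4 x 4 correlation matrices
#'   `participant`, `item` for (intercept, slopes); default identity.
#' @param shift_range Range (ms) of the uniform participant shift
#'   distribution; the shift is the minimal time to read a word and press
#'   the button, typically 150--250 ms.
#' @param seed Integer seed used by [generate_dataset()].
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_participants = 40, n_items = 16,
                           intercept = log(300),
                           effects = c(
                             "length" = 0.03, "dependency" = -0.01,
                             "wmc" = -0.02, "rf" = -0.16,
                             "length:dependency" = 0.01,
                             "length:dependency:wmc" = 0.04,
                             "length:dependency:rf" = -0.01),
                           region_coefs = c(0, 0, 0, 0),
                           sigma = 0.4,
                           re_sd = list(participant = 0.15, item = 0.05,
                                        sentence = 0.05,
                                        participant_slopes = c(0, 0, 0),
                                        item_slopes = c(0, 0, 0)),
                           re_cor = NULL,
                           shift_range = c(100, 250),
                           seed = 1L) {
  known <- c("length", "dependency", "wmc", "rf", "length:dependency",
             "length:dependency:wmc", "length:dependency:rf")
  eff <- stats::setNames(numeric(length(known)), known)
  if (length(effects)) {
    bad <- setdiff(names(effects), known)
    if (length(bad)) {
      stop("unknown effect name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    eff[names(effects)] <- effects
  }
  stopifnot(n_participants >= 1, n_items >= 1, sigma >= 0,
            length(region_coefs) == 4,
            shift_range[1] >= 0, shift_range[2] >= shift_range[1])
  re_sd$participant_slopes <- re_sd$participant_slopes %||% c(0, 0, 0)
  re_sd$item_slopes <- re_sd$item_slopes %||% c(0, 0, 0)
  if (any(unlist(re_sd) < 0)) stop("random-effect SDs must be >= 0",
                                   call. = FALSE)
  structure(
    list(n_participants = as.integer(n_participants),
         n_items = as.integer(n_items),
         intercept = intercept, effects = eff,
         region_coefs = region_coefs, sigma = sigma,
         re_sd = re_sd, re_cor = re_cor,
         shift_range = shift_range, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

.regions <- c("precritical", "critical1", "critical2",
              "spillover1", "spillover2")

# draw (intercept, slope_len, slope_dep, slope_ld) effects for n groups
.draw_group_effects <- function(n, sd_int, sd_slopes, cor_mat = NULL) {
  sds <- c(sd_int, sd_slopes)
  if (all(sds == 0)) return(matrix(0, n, 4))
  if (is.null(cor_mat)) cor_mat <- diag(4)
  sigma <- diag(sds) %*% cor_mat %*% diag(sds)
  MASS::mvrnorm(n, mu = rep(0, 4), Sigma = sigma)
}

#' Generate a synthetic self-paced-reading dataset
#'
#' Simulates trial-level reading times region by region. Each participant
#' reads every item once; the four length-by-dependency conditions are
#' rotated over items in a Latin square so each participant sees each
#' condition equally often (when `n_items` is a multiple of 4). Each
#' trial (participant x item) is one sentence with its own random
#' intercept; a reading time is
#' `RT = shift_participant + LogNormal(mu, sigma)` with
#' `mu = intercept + design effects + random effects`, the covariates
#' entering scaled and centered.
#'
#' @param spec A [generator_spec()].
#' @param participants Optional participant table from
#'   [generate_participants()]; generated under the spec seed otherwise.
#' @return A tibble of trial records: `participant`, `item`, `sentence`,
#'   `region`, `length` (-1 short / +1 long embedded subject),
#'   `dependency` (-1 baseline / +1 unbounded), `wmc_score`, `rf_score`,
#'   `shift_ms` (the true generating shift, kept for validation) and
#'   `rt_ms`.
#' @export
generate_dataset <- function(spec, participants = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  np <- spec$n_participants
  ni <- spec$n_items
  if (is.null(participants)) {
    participants <- generate_participants(np)
  }
  stopifnot(nrow(participants) == np)
  shift <- stats::runif(np, spec$shift_range[1], spec$shift_range[2])
  u_p <- .draw_group_effects(np, spec$re_sd$participant,
                             spec$re_sd$participant_slopes,
                             spec$re_cor$participant)
  u_i <- .draw_group_effects(ni, spec$re_sd$item, spec$re_sd$item_slopes,
                             spec$re_cor$item)
  wmc_s <- scale_or_zero(participants$wmc_score)
  rf_s <- scale_or_zero(participants$rf_score)

  # Latin-square condition rotation: condition of (participant p, item i)
  grid <- expand.grid(participant = seq_len(np), item = seq_len(ni))
  cond <- (grid$participant + grid$item) %% 4
  grid$length <- ifelse(cond >= 2, 1, -1)
  grid$dependency <- ifelse(cond %% 2 == 1, 1, -1)
  grid$sentence <- seq_len(nrow(grid))
  v_s <- stats::rnorm(nrow(grid), 0, spec$re_sd$sentence)

  helm <- helmert_regions()
  rec <- grid[rep(seq_len(nrow(grid)), each = 5), ]
  rec$region <- rep(.regions, nrow(grid))
  p <- rec$participant
  i <- rec$item
  s <- rec$sentence
  len <- rec$length
  dep <- rec$dependency
  ld <- len * dep
  b <- spec$effects * spec$sigma
  mu <- spec$intercept +
    b["length"] * len + b["dependency"] * dep +
    b["wmc"] * wmc_s[p] + b["rf"] * rf_s[p] +
    b["length:dependency"] * ld +
    b["length:dependency:wmc"] * ld * wmc_s[p] +
    b["length:dependency:rf"] * ld * rf_s[p] +
    drop(helm[rec$region, , drop = FALSE] %*% spec$region_coefs) +
    u_p[p, 1] + u_p[p, 2] * len + u_p[p, 3] * dep + u_p[p, 4] * ld +
    u_i[i, 1] + u_i[i, 2] * len + u_i[i, 3] * dep + u_i[i, 4] * ld +
    v_s[s]
  rt <- shift[p] + stats::rlnorm(length(mu), meanlog = mu,
                                 sdlog = spec$sigma)
  tibble::tibble(
    participant = p, item = i, sentence = s,
    region = factor(rec$region, levels = .regions),
    length = len, dependency = dep,
    wmc_score = participants$wmc_score[p],
    rf_score = participants$rf_score[p],
    shift_ms = shift[p],
    rt_ms = rt
  )
}

scale_or_zero <- function(x) {
  if (stats::sd(x) == 0) return(rep(0, length(x)))
  as.numeric(scale(x))
}

#' Inject simulated retrieval latencies into the critical region
#'
#' Adds a retrieval component, drawn from a [run_grid()] simulation, to
#' the reading time of the critical region in unbounded-dependency trials
#' (`dependency == +1`): the generated RT plays the role of the baseline
#' time and the realized retrieval latency (a completed retrieval or a
#' fast failure) is added on top,
#' `RT = T_baseline + latency`. Each participant's WMC score is mapped to
#' the nearest simulated WMC grid point (after normalizing the observed
#' score range to `[0, 1]`), and the distance condition selects the short
#' or long simulation cell via the trial's `length` code. With a
#' modified-variant (early-abort) simulation this produces the crossover
#' pattern: locality effects for high-capacity readers, antilocality for
#' low-capacity readers.
#'
#' @param records Trial table from [generate_dataset()].
#' @param grid A [run_grid()] result, or `NULL` to leave the records
#'   unchanged (mixture disabled).
#' @param region Region receiving the retrieval component; one of the five
#'   region labels (default `"critical1"`).
#' @param seed Optional integer seed for the latency resampling.
#' @return The records with modified `rt_ms` in the targeted rows.
#' @export
inject_retrieval_mixture <- function(records, grid, region = "critical1",
                                     seed = NULL) {
  if (is.null(grid)) {
    return(records)
  }
  stopifnot(inherits(grid, "retrieval_grid"))
  if (!region %in% .regions) {
    stop("unknown region '", region, "'; must be one of: ",
         paste(.regions, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- which(records$region == region & records$dependency == 1)
  if (!length(idx)) return(records)
  wmc <- records$wmc_score[idx]
  rng <- range(records$wmc_score)
  wmc01 <- if (diff(rng) == 0) rep(0.5, length(wmc)) else {
    (wmc - rng[1]) / diff(rng)
  }
  gridpts <- sort(unique(grid$trials$wmc_index))
  nearest <- gridpts[vapply(wmc01, function(x) {
    which.min(abs(gridpts - x))
  }, integer(1))]
  dist <- ifelse(records$length[idx] == 1, "long", "short")
  lat <- numeric(length(idx))
  for (cell in split(seq_along(idx),
                     paste(nearest, dist, sep = "/"))) {
    pool <- grid$trials$latency_s[
      grid$trials$wmc_index == nearest[cell[1]] &
        grid$trials$distance == dist[cell[1]]]
    lat[cell] <- sample(pool, length(cell), replace = TRUE)
  }
  records$rt_ms[idx] <- records$rt_ms[idx] + 1000 * lat
  records
}

#' Trim implausible reading times
#'
#' Removes reading times under 150 ms (too fast to be real reading;
#' likely accidental key presses that would corrupt the shift estimates)
#' and above 5000 ms. Boundary values are retained, since only values
#' strictly under/above the bounds are excluded.
#'
#' @param records A trial table with an `rt_ms` column.
#' @param lower,upper Bounds in ms (defaults 150 and 5000).
#' @return A list with `records` (the kept rows) and `removed_fraction`.
#' @examples
#' apply_rt_filter(tibble::tibble(rt_ms = c(100, 200, 6000, 300)))
#' @export
apply_rt_filter <- function(records, lower = 150, upper = 5000) {
  if (!nrow(records)) {
    return(list(records = records, removed_fraction = 0))
  }
  keep <- records$rt_ms >= lower & records$rt_ms <= upper
  list(records = records[keep, , drop = FALSE],
       removed_fraction = mean(!keep))
}
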