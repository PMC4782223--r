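#' Fit a Bayesian (shifted-)lognormal hierarchical model of reading times
#'
#' Fits the reading-time model
#' `rt - psi_participant ~ LogNormal(mu, sigma)` with
#' `mu = X beta + random effects`, by MCMC in JAGS. The shift `psi` varies
#' by participant and is constrained below that participant's minimum
#' observed RT (its natural upper bound under the likelihood); with
#' `shift = FALSE` the model reduces to a plain lognormal on the RTs,
#' which serves as the comparison model for WAIC ranking. Priors are
#' weakly informative: zero-centered normals for the fixed effects on the
#' log scale, half-normals for the SDs, and a uniform over the feasible
#' range for each shift.
#'
#' @param records Trial table (see [generate_dataset()]); RTs must already
#'   be trimmed with [apply_rt_filter()].
#' @param regions Optional region subset passed to [build_design()]
#'   (a single region gives a nested per-region fit).
#' @param shift Participant-varying shift (`TRUE`, the default) or an
#'   unshifted lognormal (`FALSE`).
#' @param random Grouping factors receiving random intercepts, a subset
#'   of `c("participant", "item", "sentence")`. A grouping with as many
#'   levels as observations (e.g. sentences in a single-region fit) is
#'   dropped with a message, as it is not identifiable.
#' @param chains Number of MCMC chains (>= 2 for convergence checks).
#' @param iter Post-warmup iterations per chain.
#' @param warmup Burn-in iterations.
#' @param adapt Adaptation steps for JAGS.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @param thin Thinning interval.
#' @return An object of class `rt_fit` with elements `draws` (a
#'   [coda::mcmc.list] of beta, sigma, SD and shift draws), `beta_names`,
#'   `design`, `loglik` (draws x observations matrix of pointwise
#'   log-likelihoods), `waic` (see [waic()]), `shifts` (per-participant
#'   posterior shift summaries, shifted model only), `shift` and
#'   `mcmc_info`.
#' @seealso [effect_sizes()], [check_convergence()], [compare_waic()]
#' @export
fit_shifted_lognormal <- function(records, regions = NULL, shift = TRUE,
                                  random = c("participant", "item",
                                             "sentence"),
                                  chains = 4, iter = 1000, warmup = 1000,
                                  adapt = 500, seed = 1L, thin = 1) {
  design <- build_design(records, regions = regions)
  if (chains < 2) stop("at least 2 chains are required", call. = FALSE)
  random <- match.arg(random, several.ok = TRUE)
  y <- design$y
  N <- length(y)
  keep_random <- character(0)
  for (g in random) {
    if (max(design$groups[[g]]) >= N) {
      message("dropping random intercept for '", g,
              "': one level per observation")
    } else {
      keep_random <- c(keep_random, g)
    }
  }
  X <- design$X
  K <- ncol(X)
  part <- design$groups$participant
  NP <- max(part)
  miny <- as.numeric(tapply(y, part, min))

  re_decl <- re_terms <- re_priors <- character(0)
  for (g in keep_random) {
    nm <- substr(g, 1, 1)  # u/i/s blocks: p -> participant etc.
    re_terms <- c(re_terms, sprintf("re_%s[g_%s[i]]", g, g))
    re_decl <- c(re_decl, sprintf(
      "  for (j in 1:N_%s) { re_%s[j] ~ dnorm(0, tau_%s) }", g, g, g))
    re_priors <- c(re_priors, sprintf(
      "  sd_%s ~ dnorm(0, 4) T(0,)\n  tau_%s <- pow(sd_%s, -2)", g, g, g))
  }
  mu_line <- paste(c("inprod(X[i,], beta)", re_terms), collapse = " + ")
  psi_block <- if (shift) {
    "  for (j in 1:NP) { psi[j] ~ dunif(0, miny[j] - 0.1) }"
  } else {
    "  for (j in 1:NP) { psi[j] <- 0 }"
  }
  model_str <- sprintf("
model {
  C <- 10000
  for (i in 1:N) {
    mu[i] <- %s
    z[i] <- log(y[i] - psi[part[i]])
    loglik[i] <- -z[i] - log(sigma) - 0.918938533204673
                 - 0.5 * pow((z[i] - mu[i]) / sigma, 2)
    zeros[i] ~ dpois(C - loglik[i])
  }
%s
%s
%s
  beta[1] ~ dnorm(6, 0.16)
  for (b in 2:K) { beta[b] ~ dnorm(0, 1) }
  sigma ~ dnorm(0, 1) T(0,)
}", mu_line, psi_block, paste(re_decl, collapse = "\n"),
      paste(re_priors, collapse = "\n"))

  data <- list(N = N, NP = NP, K = K, y = y, X = X, part = part,
               zeros = rep(0, N))
  if (shift) data$miny <- miny
  for (g in keep_random) {
    data[[paste0("g_", g)]] <- design$groups[[g]]
    data[[paste0("N_", g)]] <- max(design$groups[[g]])
  }
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed) * 100 + ch,
                beta = c(log(max(mean(y) / 2, 50)), rep(0, K - 1)),
                sigma = 0.5)
    if (shift) ini$psi <- miny * 0.5
    ini
  })
  monitors <- c("beta", "sigma", "mu",
                paste0("sd_", keep_random))
  if (shift) monitors <- c(monitors, "psi")

  model <- rjags::jags.model(textConnection(model_str), data = data,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  stats::update(model, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, monitors, n.iter = iter, thin = thin,
                              progress.bar = "none")

  all_names <- colnames(samp[[1]])
  mu_cols <- grep("^mu\\[", all_names)
  psi_cols <- grep("^psi\\[", all_names)
  par_cols <- setdiff(seq_along(all_names), c(mu_cols, psi_cols))
  mat <- do.call(rbind, lapply(samp, as.matrix))
  mu_draws <- mat[, mu_cols, drop = FALSE]
  mu_draws <- mu_draws[, order(index_of(colnames(mu_draws))), drop = FALSE]
  sigma_draws <- mat[, "sigma"]
  if (shift) {
    psi_draws <- mat[, psi_cols, drop = FALSE]
    psi_draws <- psi_draws[, order(index_of(colnames(psi_draws))),
                           drop = FALSE]
  } else {
    psi_draws <- matrix(0, nrow(mat), NP)
  }
  shifted_y <- outer(rep(1, nrow(mat)), y) - psi_draws[, part, drop = FALSE]
  loglik <- stats::dlnorm(shifted_y,
                          meanlog = mu_draws,
                          sdlog = matrix(sigma_draws, nrow(mat), N),
                          log = TRUE)

  keep_names <- all_names[par_cols]
  if (shift) keep_names <- c(keep_names, all_names[psi_cols])
  draws <- coda::as.mcmc.list(lapply(samp, function(s) {
    coda::as.mcmc(as.matrix(s)[, keep_names, drop = FALSE])
  }))
  shifts <- NULL
  if (shift) {
    shifts <- tibble::tibble(
      participant = sort(unique(design$records$participant)),
      shift_mean = colMeans(psi_draws),
      shift_l95 = apply(psi_draws, 2, stats::quantile, 0.025),
      shift_u95 = apply(psi_draws, 2, stats::quantile, 0.975),
      min_rt = miny
    )
  }
  structure(
    list(draws = draws,
         beta_names = colnames(X),
         design = design,
         loglik = loglik,
         waic = waic(loglik),
         shifts = shifts,
         shift = shift,
         mcmc_info = list(chains = chains, iter = iter, warmup = warmup,
                          thin = thin, seed = seed)),
    class = "rt_fit"
  )
}

index_of <- function(x) as.integer(sub("^[a-z]+\\[(\\d+)\\]$", "\\1", x))

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> %s lognormal, %d obs, %d chains x %d iter\n",
              if (x$shift) "shifted" else "unshifted",
              length(x$design$y), x$mcmc_info$chains, x$mcmc_info$iter))
  print(effect_sizes(x))
  cat(sprintf("WAIC: %.1f (p_waic %.1f)\n", x$waic$waic, x$waic$p_waic))
  invisible(x)
}

#' Posterior effect sizes of the fixed effects
#'
#' Standardizes each fixed-effect coefficient by the residual scale,
#' draw by draw: `delta_k = beta_k / sigma`. Summaries are the posterior
#' mean, the 95% credible interval, the posterior probability that the
#' effect is positive (the fraction of positive draws), and the split
#' R-hat of the underlying coefficient.
#'
#' @param fit An `rt_fit` object, or a [coda::mcmc.list] containing
#'   columns `beta[k]` and `sigma` (then supply `beta_names`).
#' @param beta_names Optional coefficient labels.
#' @return A tibble with columns `parameter`, `beta_mean`, `delta_mean`,
#'   `delta_l95`, `delta_u95`, `p_gt_0`, `rhat`.
#' @export
effect_sizes <- function(fit, beta_names = NULL) {
  if (inherits(fit, "rt_fit")) {
    draws <- fit$draws
    beta_names <- beta_names %||% fit$beta_names
  } else {
    draws <- fit
  }
  mat <- do.call(rbind, lapply(draws, as.matrix))
  bcols <- grep("^beta\\[", colnames(mat), value = TRUE)
  bcols <- bcols[order(index_of(bcols))]
  if (is.null(beta_names)) beta_names <- bcols
  sigma <- mat[, "sigma"]
  rhat_tab <- check_convergence(draws, flag_above = Inf)
  out <- lapply(seq_along(bcols), function(k) {
    b <- mat[, bcols[k]]
    delta <- b / sigma
    tibble::tibble(
      parameter = beta_names[k],
      beta_mean = mean(b),
      delta_mean = mean(delta),
      delta_l95 = stats::quantile(delta, 0.025, names = FALSE),
      delta_u95 = stats::quantile(delta, 0.975, names = FALSE),
      p_gt_0 = mean(delta > 0),
      rhat = rhat_tab$rhat[match(bcols[k], rhat_tab$parameter)]
    )
  })
  dplyr::bind_rows(out)
}

#' Split R-hat convergence diagnostics
#'
#' Computes the split potential-scale-reduction statistic for every
#' monitored parameter: each chain is split in half and the usual
#' between/within variance ratio is computed over the half-chains, which
#' also detects non-stationarity within chains. Parameters with
#' `rhat > 1.01` are flagged (a strict, operational version of "close to
#' one").
#'
#' @param fit An `rt_fit` object or a [coda::mcmc.list] with >= 2 chains.
#' @param flag_above Flagging threshold; default 1.01.
#' @return A tibble with `parameter`, `rhat`, `flagged`, sorted by
#'   decreasing `rhat`. Constant parameters get `rhat = 1`.
#' @export
check_convergence <- function(fit, flag_above = 1.01) {
  draws <- if (inherits(fit, "rt_fit")) fit$draws else fit
  if (!inherits(draws, "mcmc.list")) {
    draws <- coda::as.mcmc.list(lapply(draws, coda::as.mcmc))
  }
  if (length(draws) < 2) {
    stop("split R-hat needs at least 2 chains", call. = FALSE)
  }
  mats <- lapply(draws, as.matrix)
  n <- nrow(mats[[1]])
  half <- floor(n / 2)
  halves <- unlist(lapply(mats, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  params <- colnames(mats[[1]])
  rhat <- vapply(params, function(p) {
    ch <- vapply(halves, function(h) c(mean(h[, p]), stats::var(h[, p])),
                 numeric(2))
    W <- mean(ch[2, ])
    B <- half * stats::var(ch[1, ])
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  out <- tibble::tibble(parameter = params, rhat = unname(rhat),
                        flagged = unname(rhat) > flag_above)
  dplyr::arrange(out, dplyr::desc(.data$rhat))
}

#' Watanabe-Akaike information criterion from pointwise log-likelihoods
#'
#' `WAIC = -2 (lppd - p_waic)` on the deviance scale (lower is better),
#' with the log pointwise predictive density
#' `lppd = sum_i log mean_s p(y_i | theta_s)` and the effective number of
#' parameters `p_waic = sum_i var_s log p(y_i | theta_s)`.
#'
#' @param loglik A draws x observations matrix of log-likelihood values.
#' @return A list with `waic`, `lppd`, `p_waic` and `elpd` (= lppd -
#'   p_waic).
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik))
  # column-wise log-mean-exp, stabilized
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       elpd = lppd - p_waic)
}

#' Rank fitted models by WAIC
#'
#' @param fits A named list of `rt_fit` objects fitted to the same
#'   observations.
#' @return A tibble with one row per model (`model`, `waic`, `p_waic`,
#'   `delta_waic` relative to the best), sorted best first.
#' @export
compare_waic <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  nobs <- vapply(fits, function(f) ncol(f$loglik), integer(1))
  if (length(unique(nobs)) != 1) {
    stop("models were fitted to different numbers of observations: ",
         paste(nobs, collapse = ", "), call. = FALSE)
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  out <- tibble::tibble(
    model = nm,
    waic = unname(vapply(fits, function(f) f$waic$waic, numeric(1))),
    p_waic = unname(vapply(fits, function(f) f$waic$p_waic, numeric(1)))
  )
  out <- dplyr::arrange(out, .data$waic)
  out$delta_waic <- out$waic - out$waic[1]
  out
}
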