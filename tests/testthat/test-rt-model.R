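test_that("the region contrast matrix is the published Helmert scheme", {
  h <- helmert_regions()
  expect_equal(unname(h["precritical", ]), c(-1, -1, -1, -1))
  expect_equal(unname(h["critical1", ]), c(1, -1, -1, -1))
  expect_equal(unname(h["critical2", ]), c(0, 2, -1, -1))
  expect_equal(unname(h["spillover1", ]), c(0, 0, 3, -1))
  expect_equal(unname(h["spillover2", ]), c(0, 0, 0, 4))
  # pairwise orthogonal, zero-sum columns
  expect_equal(unname(crossprod(h) - diag(diag(crossprod(h)))),
               matrix(0, 4, 4))
  expect_equal(unname(colSums(h)), rep(0, 4))
})

test_that("the design matrix scales covariates and codes the interactions", {
  d <- generate_dataset(small_spec(seed = 51))
  des <- build_design(d)
  X <- des$X
  for (v in c("wmc", "rf")) {
    expect_lt(abs(mean(X[, v])), 1e-10)
    expect_equal(sd(X[, v]), 1, tolerance = 1e-10)
  }
  expect_setequal(unique(X[, "length"]), c(-1, 1))
  expect_equal(X[, "length:dependency"], X[, "length"] * X[, "dependency"])
  expect_equal(X[, "length:dependency:wmc"],
               X[, "length"] * X[, "dependency"] * X[, "wmc"])
  expect_true(all(paste0("region_c", 1:4) %in% colnames(X)))
  # single-region designs drop the region contrasts
  des1 <- build_design(d, regions = "critical1")
  expect_false(any(grepl("region_c", colnames(des1$X))))
  expect_equal(nrow(des1$X), nrow(d) / 5)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- generate_dataset(small_spec(seed = 52))
  expect_error(build_design(d, regions = "verb"), "unknown region")
  d_bad <- d
  d_bad$wmc_score <- 0.5
  expect_error(build_design(d_bad), "constant")
  d_one <- d[d$dependency == 1, ]
  expect_error(build_design(d_one), "both levels")
  expect_error(build_design(d[, -1]), "missing column")
})

fake_draws <- function(beta2, sigma = 1, n = 400, chains = 2, jitter = 0) {
  coda::as.mcmc.list(lapply(seq_len(chains), function(ch) {
    coda::as.mcmc(cbind(
      "beta[1]" = rnorm(n, 5, 0.1),
      "beta[2]" = beta2(n) + jitter * (ch - 1),
      sigma = rep(sigma, n) + abs(rnorm(n, 0, 1e-6))
    ))
  }))
}

test_that("effect sizes standardize coefficients draw by draw", {
  set.seed(53)
  dr <- fake_draws(function(n) rnorm(n))
  es <- effect_sizes(dr, beta_names = c("(Intercept)", "slope"))
  row <- es[es$parameter == "slope", ]
  expect_lt(abs(row$delta_mean), 0.15)
  expect_gt(row$p_gt_0, 0.4); expect_lt(row$p_gt_0, 0.6)
  expect_lte(row$delta_l95, row$delta_mean)
  expect_gte(row$delta_u95, row$delta_mean)
  # beta = sigma constant: delta exactly 1
  dr1 <- fake_draws(function(n) rep(2, n), sigma = 2)
  es1 <- effect_sizes(dr1)
  expect_equal(es1$delta_mean[2], 1, tolerance = 1e-5)
  # P(delta > 0) equals the brute-force fraction of positive draws
  mat <- do.call(rbind, lapply(dr, as.matrix))
  expect_equal(es$p_gt_0[2], mean(mat[, "beta[2]"] / mat[, "sigma"] > 0))
})

test_that("split R-hat is 1 for identical chains and flags divergent ones", {
  set.seed(540)
  x <- matrix(rnorm(600), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  same <- coda::as.mcmc.list(list(coda::as.mcmc(x), coda::as.mcmc(x)))
  r_same <- check_convergence(same)
  expect_true(all(abs(r_same$rhat - 1) < 0.02))
  # constant parameter: R-hat defined as 1, not NaN
  cst <- matrix(1, 100, 1, dimnames = list(NULL, "c"))
  r_cst <- check_convergence(coda::as.mcmc.list(
    list(coda::as.mcmc(cst), coda::as.mcmc(cst))))
  expect_equal(r_cst$rhat, 1)
  # chains around different means must be flagged by name
  set.seed(54)
  shifted <- coda::as.mcmc.list(list(
    coda::as.mcmc(cbind(a = rnorm(300, 0, 0.1), b = rnorm(300))),
    coda::as.mcmc(cbind(a = rnorm(300, 2, 0.1), b = rnorm(300)))))
  r_shift <- check_convergence(shifted)
  expect_true(r_shift$flagged[r_shift$parameter == "a"])
  expect_false(r_shift$flagged[r_shift$parameter == "b"])
  expect_error(check_convergence(coda::as.mcmc.list(
    list(coda::as.mcmc(x)))), "2 chains")
})

test_that("WAIC matches an independent small-fixture computation", {
  set.seed(55)
  ll <- matrix(rnorm(50 * 10, -3, 0.5), nrow = 50)  # 50 draws, 10 obs
  got <- waic(ll)
  # hand-rolled, loop-based oracle
  lppd <- 0; pw <- 0
  for (i in 1:10) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    pw <- pw + var(ll[, i])
  }
  expect_equal(got$lppd, lppd, tolerance = 1e-6)
  expect_equal(got$p_waic, pw, tolerance = 1e-6)
  expect_equal(got$waic, -2 * (lppd - pw), tolerance = 1e-6)
})

test_that("the hierarchical shifted-lognormal fit returns coherent posteriors", {
  spec <- small_spec(seed = 56, effects = c("length" = 0.3))
  filt <- apply_rt_filter(generate_dataset(spec))
  fit <- fast_fit(filt$records, seed = 56)
  expect_s3_class(fit, "rt_fit")
  expect_equal(length(fit$beta_names), ncol(fit$design$X))
  es <- effect_sizes(fit)
  expect_equal(nrow(es), length(fit$beta_names))
  expect_true(all(es$delta_l95 <= es$delta_mean &
                    es$delta_mean <= es$delta_u95))
  expect_true(all(es$p_gt_0 >= 0 & es$p_gt_0 <= 1))
  # likelihood support: every shift below that participant's minimum RT
  expect_true(all(fit$shifts$shift_u95 < fit$shifts$min_rt))
  expect_true(all(fit$shifts$shift_mean > 0))
  # pointwise log-likelihoods are finite and match the data size
  expect_equal(ncol(fit$loglik), nrow(fit$design$records))
  expect_true(all(is.finite(fit$loglik)))
  # delta summaries invariant to chain relabeling
  rev_draws <- coda::as.mcmc.list(rev(fit$draws))
  expect_equal(effect_sizes(rev_draws, fit$beta_names)$delta_mean,
               es$delta_mean)
})

test_that("null data yield credible intervals that cover zero", {
  hits <- 0L; total <- 0L
  for (rep in 1:4) {
    spec <- small_spec(seed = 560 + rep, effects = numeric(0))
    filt <- apply_rt_filter(generate_dataset(spec))
    fit <- fast_fit(filt$records, seed = 560 + rep)
    es <- effect_sizes(fit)
    es <- es[es$parameter != "(Intercept)", ]
    hits <- hits + sum(es$delta_l95 <= 0 & es$delta_u95 >= 0)
    total <- total + nrow(es)
  }
  expect_gte(hits / total, 0.9)
})

test_that("WAIC comparison requires matched observations and ties with itself", {
  spec <- small_spec(seed = 57)
  filt <- apply_rt_filter(generate_dataset(spec))
  fit <- fast_fit(filt$records, seed = 57)
  cmp <- compare_waic(list(a = fit, b = fit))
  expect_equal(cmp$waic[1], cmp$waic[2])
  expect_equal(cmp$delta_waic, c(0, 0))
  fit_sub <- fast_fit(filt$records[filt$records$participant <= 8, ],
                      seed = 57)
  expect_error(compare_waic(list(fit, fit_sub)), "different numbers")
})
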