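test_that("base-level activation follows the single-encoding decay law", {
  p <- actr_params(d = 0.7, beta = -0.3, sigma = 0, tau = -Inf)
  expect_equal(base_activation(1, p), -0.3)  # log(1) = 0 forces BA = beta
  p2 <- actr_params(d = 0.5, beta = -0.3, sigma = 0, tau = -Inf)
  expect_equal(base_activation(exp(2), p2), -1.3)
  expect_lt(base_activation(6, p2), base_activation(2, p2))
  # flat when there is no decay
  p0 <- actr_params(d = 0, beta = 0.2)
  expect_equal(base_activation(c(0.5, 2, 100), p0), rep(0.2, 3))
  expect_error(base_activation(0, p), "positive")
  expect_error(base_activation(-1, p), "positive")
})

test_that("base activation is continuous and strictly decreasing for d > 0", {
  p <- actr_params(d = 0.4, beta = -1)
  t <- sort(runif(50, 0.01, 20))
  ba <- base_activation(t, p)
  expect_true(all(diff(ba) < 0))
})

test_that("spreading activation implements the weighted fan equation", {
  p0 <- actr_params(W = 0)
  expect_equal(spreading_activation(p0), 0)
  p1 <- actr_params(W = 1, w_wh = 1, w_anim = 0, w_NP = 0, MAS = 2)
  expect_equal(spreading_activation(p1), 2)  # MAS - log(1) = MAS
  p3 <- actr_params(W = 1, MAS = 2)
  hand <- (2 + 2 * (2 - log(5))) / 3  # direct evaluation, fan (1, 5, 5)
  expect_equal(spreading_activation(p3), hand, tolerance = 1e-12)
})

test_that("invalid cue weights and excessive fan are rejected", {
  expect_error(actr_params(w_wh = 0.5, w_anim = 0.5, w_NP = 0.5),
               "sum to 1")
  expect_error(actr_params(w_wh = -0.2, w_anim = 0.6, w_NP = 0.6),
               "non-negative")
  p <- actr_params(MAS = 1)
  expect_error(spreading_activation(p, fan_profile(1, 5, 5)), "positive")
})

test_that("spreading activation is permutation-invariant for equal weights", {
  p <- actr_params(W = 1.3, MAS = 3)
  fans <- list(fan_profile(1, 5, 5), fan_profile(5, 1, 5),
               fan_profile(5, 5, 1))
  s <- vapply(fans, function(f) spreading_activation(p, f), numeric(1))
  expect_equal(s, rep(s[1], 3))
})

test_that("logistic noise has mean zero and variance pi^2 sigma^2 / 3", {
  p0 <- actr_params(sigma = 0)
  expect_identical(sample_noise(10, p0), rep(0, 10))
  p <- actr_params(sigma = 0.25)
  set.seed(99)
  x <- sample_noise(1e5, p)
  se_mean <- sqrt(pi^2 * 0.25^2 / 3 / 1e5)
  expect_lt(abs(mean(x)), 3 * se_mean)
  expect_equal(var(x), pi^2 * 0.25^2 / 3, tolerance = 0.05)
})

test_that("total activation is the additive sum of its components", {
  expect_equal(total_activation(0, 0, 0), 0)
  expect_equal(total_activation(-1.3, (2 + 2 * (2 - log(5))) / 3, 0),
               -0.3729, tolerance = 1e-3)
  eps <- rnorm(20)
  expect_equal(total_activation(-0.5, 0.9, eps) -
                 total_activation(-0.5, 0.9, 0), eps)
})

test_that("latency is an exponentially decreasing function of activation", {
  expect_equal(latency_from_activation(0, 1.6), 1.6)
  expect_equal(latency_from_activation(log(2), 1.6), 0.8)
  A <- sort(rnorm(20))
  lat <- latency_from_activation(A, 1.6)
  expect_true(all(diff(lat) < 0))
  expect_error(latency_from_activation(0, -1))
})

test_that("the threshold sets the maximum retrieval latency", {
  expect_equal(max_latency(actr_params(F = 1.6, tau = 0)), 1.6)
  expect_equal(max_latency(actr_params(F = 1.6, tau = log(1.6))), 1.0)
  expect_identical(max_latency(actr_params(tau = -Inf)), Inf)
  expect_gt(max_latency(actr_params(tau = -1)),
            max_latency(actr_params(tau = 0)))
})

test_that("capacity mappings interpolate one parameter with the stated direction", {
  pre <- actr_preset("modified", "decay_rate")
  expect_equal(map_wmc(pre$mapping, 0, pre$params)$d, 0.62)
  expect_equal(map_wmc(pre$mapping, 1, pre$params)$d, 0.33)
  pre_w <- actr_preset("modified", "source_activation")
  expect_equal(map_wmc(pre_w$mapping, 0.5, pre_w$params)$W, 1.05)
  # interference: residual weight split equally
  m <- capacity_mapping("interference", 0.2, 0.5)
  p <- map_wmc(m, 1, actr_params())
  expect_equal(p$w_wh, 0.5)
  expect_equal(p$w_anim, 0.25)
  expect_equal(p$w_NP, 0.25)
  expect_error(map_wmc(m, 1.2, actr_params()), "\\[0, 1\\]")
  expect_error(map_wmc(m, -0.1, actr_params()), "\\[0, 1\\]")
})

test_that("mapping endpoints outside the published ranges warn but work", {
  expect_warning(capacity_mapping("decay_rate", 2, 0.1), "outside")
  expect_warning(capacity_mapping("source_activation", 0.1, 4), "outside")
  expect_silent(capacity_mapping("source_activation", 0.9, 1.2))
  expect_error(capacity_mapping("decay_rate", 0.3, 0.6), "non-increasing")
  expect_error(capacity_mapping("interference", 0.5, 0.2),
               "non-decreasing")
})

test_that("every mapping output preserves weight normalization", {
  base <- actr_params()
  maps <- list(capacity_mapping("decay_rate", 0.62, 0.33),
               capacity_mapping("source_activation", 0.9, 1.2),
               capacity_mapping("interference", 0.1, 1))
  set.seed(4)
  for (m in maps) {
    for (idx in runif(10)) {
      p <- map_wmc(m, idx, base)
      expect_equal(p$w_wh + p$w_anim + p$w_NP, 1, tolerance = 1e-12)
    }
  }
})

test_that("presets expose the published parameter configurations", {
  d6 <- actr_preset("default", "decay_rate", threshold = FALSE)
  expect_equal(d6$params$beta, -0.65)
  expect_identical(d6$params$tau, -Inf)
  expect_equal(d6$mapping$low_end, 1.5)
  expect_equal(d6$mapping$high_end, 0.06)
  s6 <- actr_preset("default", "source_activation")
  expect_equal(s6$params$beta, -1)
  expect_equal(s6$params$tau, 0)
  expect_equal(c(s6$mapping$low_end, s6$mapping$high_end), c(0.5, 3.5))
  m7 <- actr_preset("modified", "interference")
  expect_equal(m7$params$beta, -0.3)
  expect_equal(m7$params$tau, 0)
  expect_equal(c(m7$mapping$low_end, m7$mapping$high_end), c(0.2, 0.5))
  expect_equal(m7$params$F, 1.6)
  expect_equal(m7$params$MAS, 2)
  expect_equal(m7$params$sigma, 0.25)
})

test_that("parameter configs round-trip through JSON and YAML", {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(F = 2, d = 0.4, sigma = 0.1, tau = "-Inf"),
                       tmp, auto_unbox = TRUE)
  p <- read_actr_config(tmp)
  expect_equal(p$F, 2)
  expect_equal(p$d, 0.4)
  expect_identical(p$tau, -Inf)
  expect_equal(p$w_wh, 1 / 3)  # unspecified keys fall back to defaults
  tmp2 <- tempfile(fileext = ".yaml")
  writeLines(c("preset: modified", "mapping: interference"), tmp2)
  pre <- read_actr_config(tmp2)
  expect_equal(pre$params$beta, -0.3)
  expect_equal(pre$mapping$kind, "interference")
  expect_error(read_actr_config(tempfile()), "not found")
})
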