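test_that("dog_basis matches its closed-form extremum", {
  expect_equal(dog_basis(0, 30), 0)
  d <- seq(-90, 90, by = 0.5)
  expect_equal(dog_basis(-d, 30), -dog_basis(d, 30))
  grid <- seq(0, 90, by = 0.001)
  expect_equal(grid[which.max(dog_basis(grid, 30))], 30, tolerance = 1e-3)
  expect_equal(max(dog_basis(grid, 30)), 30 * exp(-0.5), tolerance = 1e-9)
  expect_error(dog_basis(10, -1), "width")
})

test_that("bic_gaussian matches an independent likelihood computation", {
  # 5-point toy regression, fit by lm; oracle = full Gaussian ML BIC
  x <- c(-2, -1, 0, 1, 2)
  y <- c(0.8, 1.1, 2.2, 2.8, 4.1)
  full_bic <- function(fit, k_mean) {
    n <- length(y)
    rss <- sum(residuals(fit)^2)
    sigma2 <- rss / n
    loglik <- sum(dnorm(y, fitted(fit), sqrt(sigma2), log = TRUE))
    -2 * loglik + (k_mean + 1) * log(n)  # +1 for sigma
  }
  f1 <- lm(y ~ 1); f2 <- lm(y ~ x)
  d_ours <- bic_gaussian(sum(residuals(f2)^2), 5, 2) -
    bic_gaussian(sum(residuals(f1)^2), 5, 1)
  d_oracle <- full_bic(f2, 2) - full_bic(f1, 1)
  expect_equal(d_ours, d_oracle, tolerance = 1e-9)
})

test_that("bic_gaussian obeys its algebraic identities", {
  expect_equal(bic_gaussian(10, 100, 3) - bic_gaussian(10, 100, 2), log(100))
  expect_equal(bic_gaussian(20, 50, 2) - bic_gaussian(10, 50, 2), 50 * log(2))
  expect_error(bic_gaussian(0, 10, 1), "positive")
  expect_error(bic_gaussian(5, 3, 3), "n_obs")
})

test_that("the width search equals exhaustive enumeration by lm (brute-force oracle)", {
  set.seed(51)
  d <- gen_triples(3000, attract_peak = 1.5, attract_width = 30, noise_sd = 6)
  grid <- seq(10, 80, by = 5)
  fit <- fit_dog_model(d, "d1", width_grid = grid)
  oracle <- sapply(grid, function(w)
    summary(lm(error ~ dog_basis(delta, w), data = d))$r.squared)
  expect_equal(unname(fit$widths["dog1"]), grid[which.max(oracle)])
  expect_equal(fit$r_squared, max(oracle), tolerance = 1e-10)
  best_lm <- lm(error ~ dog_basis(delta, fit$widths["dog1"]), data = d)
  expect_equal(fit$coefficients$estimate,
               unname(coef(best_lm)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(coef(summary(best_lm))[, 2]), tolerance = 1e-6)
})

test_that("two-component search equals the enumerated lm oracle on a coarse grid", {
  set.seed(52)
  d <- gen_triples(4000, attract_peak = 1.5, attract_width = 20,
                   repulse_peak = -1, repulse_width = 60, noise_sd = 6)
  grid <- seq(10, 80, by = 10)
  fit <- fit_dog_model(d, "d2", width_grid = grid, min_width_separation = 15)
  pairs <- expand.grid(w1 = grid, w2 = grid)
  pairs <- pairs[pairs$w2 - pairs$w1 >= 15, ]
  oracle <- apply(pairs, 1, function(p)
    summary(lm(error ~ dog_basis(delta, p[1]) + dog_basis(delta, p[2]),
               data = d))$r.squared)
  expect_equal(unname(fit$widths),
               unname(unlist(pairs[which.max(oracle), ])))
  expect_equal(fit$r_squared, max(oracle), tolerance = 1e-10)
})

test_that("interaction models reproduce lm with product terms", {
  set.seed(53)
  d <- gen_triples(4000, attract_peak = 1, attract_width = 30, noise_sd = 5)
  d$error <- d$error + d$loc * dog_kernel(d$delta, 0.8, 30)
  fit <- fit_dog_model(d, "d1xloc", width_grid = c(20, 30, 40))
  w <- fit$widths["dog1"]
  ref <- lm(error ~ b + b:loc, data = transform(d, b = dog_basis(delta, w)))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$n_params, 3)
})

test_that("degenerate and invalid fits are handled", {
  d <- data.frame(delta = runif(50, -90, 90), error = 0)
  fit <- fit_dog_model(d, "d1", width_grid = c(20, 40))
  expect_equal(fit$coefficients$estimate, c(0, 0))
  expect_equal(fit$r_squared, 0)
  expect_error(fit_dog_model(d[1:2, ], "d2"), "fewer observations")
  expect_error(fit_dog_model(d, "d1", width_grid = numeric(0)), "width_grid")
  expect_error(fit_dog_model(d[, "delta", drop = FALSE], "d1"), "error")
  expect_error(fit_dog_model(d, "d1xloc"), "loc")
})

test_that("r^2 is monotone over the nested family", {
  set.seed(54)
  d <- gen_triples(6000, attract_peak = 1.2, attract_width = 25,
                   repulse_peak = -0.6, repulse_width = 60, noise_sd = 8)
  r2 <- vapply(c("d0", "d1", "d2"), function(m)
    fit_dog_model(d, m, width_grid = seq(10, 80, 5))$r_squared, numeric(1))
  expect_true(r2["d2"] >= r2["d1"])
  expect_true(r2["d1"] >= r2["d0"])
})

test_that("fitted kernel sign tracks the generative direction", {
  set.seed(55)
  signs <- sapply(1:20, function(i) {
    attract <- gen_triples(3000, attract_peak = 1, noise_sd = 8)
    repulse <- gen_triples(3000, attract_peak = -1, noise_sd = 8)
    c(fit_dog_model(attract, "d1", seq(10, 80, 5))$coefficients$estimate[2] > 0,
      fit_dog_model(repulse, "d1", seq(10, 80, 5))$coefficients$estimate[2] < 0)
  })
  expect_gte(mean(signs), 0.95)
})

test_that("compare_models reports delta BIC on the worst-model-zero scale", {
  mk <- function(bic, name) {
    f <- structure(list(spec = model_spec(name), widths = numeric(0),
                        coefficients = data.frame(), r_squared = 0,
                        rss = 1, n_obs = 100, n_params = 1, bic = bic),
                   class = "dog_fit")
    f
  }
  cmp <- compare_models(list(a = mk(100, "d0"), b = mk(98, "d1"),
                             c = mk(104, "d2")))
  expect_equal(cmp$delta_bic, c(4, 6, 0))
  expect_equal(attr(cmp, "best_model"), "b")
  expect_equal(cmp$evidence_vs_worst, c("positive", "strong", "weak"))
  bad <- mk(90, "d1"); bad$n_obs <- 99
  expect_error(compare_models(list(mk(100, "d0"), bad)), "not comparable")
})

test_that("delta BIC is invariant to a shared likelihood constant", {
  set.seed(56)
  d <- gen_triples(2000, attract_peak = 1, noise_sd = 6)
  fits <- lapply(c("d0", "d1", "d2"), fit_dog_model, data = d,
                 width_grid = seq(10, 80, 10))
  cmp1 <- compare_models(fits)
  shifted <- lapply(fits, function(f) { f$bic <- f$bic + 123.4; f })
  cmp2 <- compare_models(shifted)
  expect_equal(cmp1$delta_bic, cmp2$delta_bic)
  expect_identical(attr(cmp1, "best_model"), attr(cmp2, "best_model"))
})

test_that("peak_bias matches a brute-force maximization of the fitted curve", {
  expect_equal(peak_bias(0, 30)$peak, 0)
  b <- 1 / (30 * exp(-0.5))
  expect_equal(peak_bias(b, 30)$peak, 1)
  set.seed(57)
  for (i in 1:5) {
    co <- runif(1, -2, 2); w <- runif(1, 10, 80)
    grid <- seq(-90, 90, by = 1e-3)
    curve <- co * dog_basis(grid, w)
    idx <- which.max(abs(curve))
    pk <- peak_bias(co, w)
    expect_equal(abs(pk$peak), abs(curve[idx]), tolerance = 1e-9)
    expect_equal(pk$location, abs(grid[idx]), tolerance = 1e-2)
  }
})

test_that("compare_coefficients implements the two-sample z-test", {
  mkfit <- function(est, se) {
    structure(list(coefficients = data.frame(term = "dog2", estimate = est,
                                             se = se)), class = "dog_fit")
  }
  eq <- compare_coefficients(mkfit(0.5, 0.1), mkfit(0.5, 0.2), "dog2")
  expect_equal(eq$z, 0); expect_equal(eq$p, 1)
  shifted <- compare_coefficients(mkfit(1.96 * sqrt(0.02), 0.1),
                                  mkfit(0, 0.1), "dog2")
  expect_equal(shifted$p, 0.05, tolerance = 1e-3)
  expect_error(compare_coefficients(mkfit(1, 1), mkfit(1, 1), "dog9"),
               "dog9")
})

test_that("split_by_similarity partitions eligible trials exhaustively", {
  tr <- data.frame(prev_probe_distractor_delta = c(10, -80, 44.9, 45, NA, 60))
  sp <- split_by_similarity(tr)
  expect_equal(sp$similar$prev_probe_distractor_delta, c(10, 44.9))
  expect_equal(sp$dissimilar$prev_probe_distractor_delta, c(-80, 45, 60))
  expect_equal(nrow(sp$similar) + nrow(sp$dissimilar), 5)
  expect_warning(split_by_similarity(
    data.frame(prev_probe_distractor_delta = c(1, 2))), "empty")
})

test_that("smooth_curve averages within its wrapped moving window", {
  d <- rep(seq(-89, 90), 2)
  flat <- smooth_curve(d, rep(2.5, length(d)))
  expect_true(all(flat$mean == 2.5))
  expect_true(all(flat$sd == 0))
  # window 1 reduces to per-degree bins
  bins <- smooth_curve(c(-10, -10, 40), c(1, 3, 5), window = 1)
  expect_equal(bins$mean, c(2, 5))
  expect_equal(bins$delta, c(-10, 40))
  # the window wraps across the +/-90 boundary of delta space
  wrap <- smooth_curve(c(-89, 90), c(1, 3), window = 5)
  expect_equal(wrap$mean[wrap$delta == 90], 2)
  expect_error(smooth_curve(1, 1, window = 4), "odd")
})

test_that("smoothing commutes with averaging on a balanced grid", {
  deltas <- seq(-89, 90)
  e1 <- dog_kernel(deltas, 2, 30)
  e2 <- dog_kernel(deltas, 1, 30)
  s_then_a <- (smooth_curve(deltas, e1)$mean + smooth_curve(deltas, e2)$mean) / 2
  a_then_s <- smooth_curve(deltas, (e1 + e2) / 2)$mean
  expect_equal(s_then_a, a_then_s)
})
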