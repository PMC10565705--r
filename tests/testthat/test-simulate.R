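test_that("dog_kernel has unit-peak normalization and odd symmetry", {
  expect_equal(dog_kernel(0, 3, 20), 0)
  expect_equal(dog_kernel(30, 1, 30), 1)        # peak at delta = width
  expect_equal(dog_kernel(25, -2.5, 25), -2.5)
  expect_equal(dog_kernel(60, 1, 30), 2 * exp(0.5 - 2))
  d <- seq(-90, 90, by = 3)
  expect_equal(dog_kernel(-d, 1.3, 40), -dog_kernel(d, 1.3, 40))
  expect_error(dog_kernel(10, 1, 0), "width")
  expect_error(dog_kernel(10, 1, -5), "width")
})

test_that("parameter constructors validate their arguments", {
  expect_error(design_params(p_distractor = 1.4), "p_distractor")
  expect_error(design_params(distractor_orientations = c(0, 190)), "180")
  expect_error(design_params(trials_per_session = 0), ">= 1")
  expect_error(observer_params(motor_noise_sd = 0), "motor_noise_sd")
  expect_error(observer_params(lapse_rate = 1), "lapse_rate")
  expect_error(observer_params(rt_base = -5), "positive")
})

test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  des <- design_params(n_participants = 2, trials_per_session = 50)
  obs <- observer_params()
  a <- simulate_experiment(des, obs, seed = 5)
  b <- simulate_experiment(des, obs, seed = 5)
  c <- simulate_experiment(des, obs, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("simulated marginals match the design", {
  des <- design_params(n_participants = 1, n_sessions = 1,
                       trials_per_session = 10000)
  tr <- simulate_experiment(des, observer_params(), seed = 31)
  expect_lt(abs(mean(tr$distractor_present) - 0.5), 0.02)
  oris <- unique(tr$distractor_orientation[tr$distractor_present])
  expect_true(all(oris %in% seq(0, 160, by = 20)))
  an <- annotate_trials(tr)
  dd <- an$delta_distractor[an$distractor_present]
  expect_true(all(abs(dd) <= 65))
  # both location conditions present in equal-size blocks
  expect_equal(unname(table(tr$location_condition)["fixed"]), 5000)
  # fixed blocks use one distractor location, random blocks several
  fixed_locs <- unique(tr$distractor_location[tr$distractor_present &
                                              tr$location_condition == "fixed"])
  expect_length(fixed_locs, 1)
  random_locs <- unique(tr$distractor_location[tr$distractor_present &
                                               tr$location_condition == "random"])
  expect_gt(length(random_locs), 1)
})

test_that("an unbiased near-noiseless observer reports the probe", {
  obs <- observer_params(attract_amp_prev_probe = 0, repulse_amp_prev_probe = 0,
                         repulse_amp_distractor = 0, motor_noise_sd = 1e-6,
                         lapse_rate = 0)
  tr <- simulate_experiment(design_params(n_participants = 1,
                                          trials_per_session = 200), obs, seed = 32)
  an <- annotate_trials(tr)
  expect_lt(max(abs(an$adjustment_error)), 1e-4)
})

test_that("the generative bias matches the kernel at its peak", {
  obs <- observer_params(attract_amp_prev_probe = 2, attract_width_prev_probe = 25,
                         repulse_amp_prev_probe = 0, repulse_amp_distractor = 0,
                         motor_noise_sd = 8, lapse_rate = 0)
  tr <- simulate_experiment(design_params(n_participants = 5,
                                          trials_per_session = 5000), obs, seed = 33)
  an <- annotate_trials(tr)
  sel <- !is.na(an$delta_prev_probe) & abs(an$delta_prev_probe - 25) <= 3
  mc_se <- 8 / sqrt(sum(sel))
  expect_lt(abs(mean(an$adjustment_error[sel]) - 2), 4 * mc_se + 0.02)
})

test_that("discrimination RT means follow the condition structure", {
  obs <- observer_params(rt_base = 500, rt_location_effect = 30,
                         rt_distractor_effect = 40, rt_interaction = 0,
                         rt_shape = 1e6)
  tr <- simulate_experiment(design_params(n_participants = 4,
                                          trials_per_session = 2000), obs, seed = 34)
  cell <- function(lc, pres)
    mean(tr$discrimination_rt[tr$location_condition == lc &
                              tr$distractor_present == pres])
  expect_lt(abs(cell("random", FALSE) - 500), 2)
  expect_lt(abs(cell("fixed", FALSE) - 530), 2)
  expect_lt(abs(cell("random", TRUE) - 540), 2)
  expect_lt(abs(cell("fixed", TRUE) - 570), 2)
})

test_that("sample_cohort varies only the RT baseline", {
  coh <- sample_cohort(8, rt_base_sd = 50, seed = 9)
  expect_length(coh, 8)
  bases <- vapply(coh, function(o) o$rt_base, numeric(1))
  expect_gt(stats::sd(bases), 10)
  amps <- vapply(coh, function(o) o$attract_amp_prev_probe, numeric(1))
  expect_equal(amps, rep(observer_params()$attract_amp_prev_probe, 8))
})
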