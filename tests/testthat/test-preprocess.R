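test_that("each trial-exclusion rule fires on its hand-built case", {
  tr <- make_trials(20)
  tr$discrimination_rt[1] <- 150    # too fast
  tr$discrimination_rt[2] <- 1200   # too slow
  tr$reported_orientation[3] <- (tr$probe_orientation[3] + 50) %% 180  # |error| > 45
  tr$adjustment_rt[4] <- 12000      # adjustment slower than 10 s
  an <- annotate_trials(tr)
  res <- exclude_trials(an)
  fl <- res$report$trial_flags
  expect_true(fl$rt_out_of_range[1] && fl$rt_out_of_range[2])
  expect_true(fl$error_gt_45[3])
  expect_true(fl$adjustment_too_slow[4])
  expect_equal(which(res$report$removed), 1:4)
  expect_equal(nrow(res$clean) + sum(res$report$removed), nrow(tr))
})

test_that("the two-step error rule removes only the gross outlier from {0,1,-1,2,-2,50}", {
  errors <- c(0, 1, -1, 2, -2, 50)
  tr <- make_trials(6, probe_orientation = rep(90, 6),
                    reported_orientation = (90 + errors) %% 180)
  res <- exclude_trials(annotate_trials(tr))
  # 50 exceeds +/-45; survivors {0,1,-1,2,-2} have Q1=-1, Q3=1, fence [-4,4]
  expect_equal(res$report$counts[["error_gt_45"]], 1)
  expect_equal(res$report$counts[["error_iqr_outlier"]], 0)
  expect_equal(res$report$counts[["total_removed"]], 1)
})

test_that("the IQR fence is applied after the +/-45 step, per participant", {
  # errors: tight cluster plus one moderate outlier inside +/-45
  errors <- c(rep(c(-1, 0, 1), 6), 30, -2)
  tr <- make_trials(20, probe_orientation = rep(90, 20),
                    reported_orientation = (90 + errors) %% 180)
  res <- exclude_trials(annotate_trials(tr))
  expect_equal(res$report$counts[["error_gt_45"]], 0)
  expect_equal(res$report$counts[["error_iqr_outlier"]], 1)
  expect_true(res$report$trial_flags$error_iqr_outlier[19])
})

test_that("a clean table yields zero removals", {
  set.seed(41)
  tr <- make_trials(30, probe_orientation = runif(30, 0, 180))
  tr$reported_orientation <- (tr$probe_orientation + rnorm(30, 0, 2)) %% 180
  res <- exclude_trials(annotate_trials(tr))
  expect_equal(unname(res$report$counts["total_removed"]), 0L)
  expect_equal(res$report$overall_retained_fraction, 1)
})

test_that("trial exclusion is idempotent on simulated data", {
  tr <- simulate_experiment(design_params(n_participants = 3,
                                          trials_per_session = 500),
                            observer_params(), seed = 42)
  first <- exclude_trials(annotate_trials(tr))
  second <- exclude_trials(first$clean)
  expect_equal(unname(second$report$counts["total_removed"]), 0L)
})

test_that("participant exclusion flags each rule", {
  set.seed(43)
  n <- 200
  good <- function(p) {
    tr <- make_trials(n, participant = p, probe_orientation = runif(n, 0, 180))
    tr$reported_orientation <- (tr$probe_orientation + rnorm(n, 0, 8)) %% 180
    tr
  }
  # P04 answers uniformly at random -> circular correlation near 0
  uniform_responder <- good("P04")
  uniform_responder$reported_orientation <- runif(n, 0, 180)
  # P05 has >25% of trials flagged (fast discrimination RTs)
  many_outliers <- good("P05")
  many_outliers$discrimination_rt[1:80] <- 100
  trials <- rbind(good("P01"), good("P02"), good("P03"),
                  uniform_responder, many_outliers)
  an <- annotate_trials(trials)
  res <- exclude_trials(an)
  part <- exclude_participants(an, res$report)
  flags <- part$report$participants
  expect_true(flags$low_circular_correlation[flags$participant_id == "P04"])
  expect_true(flags$too_many_outliers[flags$participant_id == "P05"])
  expect_setequal(part$kept, c("P01", "P02", "P03"))
})

test_that("group-SD rule removes a discrimination outlier, not clean cohorts", {
  set.seed(44)
  n <- 150
  mk <- function(p, acc = 0.97, rt = 500) {
    tr <- make_trials(n, participant = p, probe_orientation = runif(n, 0, 180),
                      discrimination_correct = runif(n) < acc,
                      discrimination_rt = rnorm(n, rt, 20))
    tr$reported_orientation <- (tr$probe_orientation + rnorm(n, 0, 8)) %% 180
    tr
  }
  # a 50%-accuracy participant in a 15-strong cohort sits ~3.6 group SDs out
  cohort <- do.call(rbind, c(lapply(sprintf("P%02d", 1:14), mk),
                             list(mk("P15", acc = 0.50))))
  an <- annotate_trials(cohort)
  part <- exclude_participants(an, exclude_trials(an)$report)
  flags <- part$report$participants
  expect_true(flags$discrimination_outlier[flags$participant_id == "P15"])
  expect_setequal(part$kept, sprintf("P%02d", 1:14))

  clean_only <- do.call(rbind, lapply(sprintf("P%02d", 1:6), mk))
  an2 <- annotate_trials(clean_only)
  part2 <- exclude_participants(an2, exclude_trials(an2)$report)
  expect_setequal(part2$kept, sprintf("P%02d", 1:6))
})

test_that("single-participant input skips the group-SD rule with a warning", {
  set.seed(45)
  tr <- make_trials(50, probe_orientation = runif(50, 0, 180))
  tr$reported_orientation <- (tr$probe_orientation + rnorm(50, 0, 5)) %% 180
  an <- annotate_trials(tr)
  expect_warning(part <- exclude_participants(an, exclude_trials(an)$report),
                 "group-SD")
  expect_equal(part$kept, "P01")
})
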