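# Synthetic observer: generates trial tables with the experimental design
# (interleaved discrimination + adjustment, 50% distractors in 20-degree
# steps, random vs. fixed distractor location blocks) and a parameterized
# response model, so every inference stage has ground truth.

#' Derivative-of-Gaussian bias kernel (peak-normalized)
#'
#' The canonical serial-dependence bias shape: an odd function of the
#' orientation difference `delta`, here normalized so that its extremum
#' equals `amplitude` (in degrees of bias), attained at `delta = +/-width`:
#' `amplitude * (delta/width) * exp(1/2 - delta^2 / (2 width^2))`.
#' Positive amplitude biases responses toward the inducing stimulus
#' (attraction); negative amplitude away from it (repulsion).
#'
#' @param delta Orientation difference(s) in degrees.
#' @param amplitude Peak bias in degrees (signed).
#' @param width Gaussian width (standard deviation) in degrees, > 0.
#' @return Bias in degrees, same length as `delta`.
#' @export
dog_kernel <- function(delta, amplitude, width) {
  if (!is.numeric(width) || length(width) != 1 || !is.finite(width) || width <= 0)
    stop("dog_kernel(): width must be a single positive number")
  amplitude * (delta / width) * exp(0.5 - delta^2 / (2 * width^2))
}

#' Experimental design parameters
#'
#' Defaults reproduce the reference design: two sessions of 1000 trials,
#' distractor on 50% of trials at orientations 0-160 in 20-degree steps at
#' one of four locations, probe orientation within +/-65 degrees of the
#' distractor on distractor-present trials, and each session split into one
#' "random" and one "fixed" location block of equal size.
#'
#' @param n_participants Number of simulated observers.
#' @param n_sessions Sessions per observer (separate days; previous-trial
#'   linkage never crosses sessions).
#' @param trials_per_session Trials per session.
#' @param p_distractor Probability a trial contains a distractor.
#' @param distractor_orientations Degree set the distractor is drawn from.
#' @param probe_delta_range Maximal |probe - distractor| difference in
#'   degrees on distractor-present trials.
#' @param n_locations Number of possible distractor locations.
#' @param block_order `"counterbalanced"` (odd-numbered participants see the
#'   random block first, even-numbered the fixed block first),
#'   `"random_first"` or `"fixed_first"`.
#' @return An object of class `design_params`.
#' @export
design_params <- function(n_participants = 1L,
                          n_sessions = 2L,
                          trials_per_session = 1000L,
                          p_distractor = 0.5,
                          distractor_orientations = seq(0, 160, by = 20),
                          probe_delta_range = 65,
                          n_locations = 4L,
                          block_order = c("counterbalanced", "random_first",
                                          "fixed_first")) {
  block_order <- match.arg(block_order)
  d <- list(n_participants = as.integer(n_participants),
            n_sessions = as.integer(n_sessions),
            trials_per_session = as.integer(trials_per_session),
            p_distractor = p_distractor,
            distractor_orientations = distractor_orientations,
            probe_delta_range = probe_delta_range,
            n_locations = as.integer(n_locations),
            block_order = block_order)
  if (d$n_participants < 1 || d$n_sessions < 1 || d$trials_per_session < 1)
    stop("design_params(): counts must be >= 1")
  if (d$p_distractor < 0 || d$p_distractor > 1)
    stop("design_params(): p_distractor must lie in [0,1]")
  if (any(d$distractor_orientations < 0 | d$distractor_orientations >= 180))
    stop("design_params(): distractor orientations must lie in [0,180)")
  if (d$probe_delta_range <= 0 || d$probe_delta_range > 90)
    stop("design_params(): probe_delta_range must lie in (0,90]")
  structure(d, class = "design_params")
}

#' Generative parameters of a simulated observer
#'
#' The response model: the reported orientation is the probe orientation
#' plus an attractive kernel of the previous probe, a repulsive (tail)
#' kernel of the previous probe, a repulsive kernel of the current
#' distractor (all peak-normalized [dog_kernel()]s), and Gaussian motor
#' noise, wrapped into `[0,180)`; with probability `lapse_rate` the response
#' is instead uniform. Discrimination RTs are inverse-Gaussian with mean
#' `rt_base + rt_location_effect*[fixed] + rt_distractor_effect*[present] +
#' rt_interaction*[fixed & present]` and shape `rt_shape`
#' (variance = mean^3 / rt_shape). Discrimination correctness is Bernoulli.
#'
#' Defaults are anchored to the second reference experiment: attraction
#' peaking at 1.42 degrees (width 25), a repulsive previous-probe tail of
#' -0.53 degrees (width 60), no distractor kernel, and the reported RT
#' fixed-effect pattern. Repulsive amplitudes are signed (<= 0).
#'
#' @param attract_amp_prev_probe,attract_width_prev_probe Attractive
#'   previous-probe kernel: peak bias (deg) and width (deg).
#' @param repulse_amp_prev_probe,repulse_width_prev_probe Repulsive
#'   previous-probe tail kernel: peak bias (deg, <= 0) and width (deg).
#' @param repulse_amp_distractor,repulse_width_distractor Repulsive kernel
#'   of the current distractor: peak bias (deg, <= 0) and width (deg).
#' @param motor_noise_sd Motor/readout noise SD in degrees.
#' @param lapse_rate Probability of a uniform random response.
#' @param rt_base,rt_location_effect,rt_distractor_effect,rt_interaction
#'   Fixed effects of the discrimination RT mean structure, in ms
#'   (random-location, distractor-absent baseline; `fixed` and `present`
#'   increments; their interaction).
#' @param rt_shape Inverse-Gaussian shape parameter lambda of the
#'   discrimination RT distribution (variance = mean^3/lambda).
#' @param adjust_rt_mean,adjust_rt_sd Mean and SD (ms) of the
#'   inverse-Gaussian adjustment response times.
#' @param p_correct_discrimination Probability of a correct discrimination
#'   response.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(attract_amp_prev_probe = 1.42,
                            attract_width_prev_probe = 25,
                            repulse_amp_prev_probe = -0.53,
                            repulse_width_prev_probe = 60,
                            repulse_amp_distractor = 0,
                            repulse_width_distractor = 30,
                            motor_noise_sd = 10,
                            lapse_rate = 0.02,
                            rt_base = 489.29,
                            rt_location_effect = 4.128,
                            rt_distractor_effect = 18.53,
                            rt_interaction = -10.97,
                            rt_shape = 12500,
                            adjust_rt_mean = 1630,
                            adjust_rt_sd = 310,
                            p_correct_discrimination = 0.97) {
  o <- as.list(environment())
  if (o$attract_width_prev_probe <= 0 || o$repulse_width_prev_probe <= 0 ||
      o$repulse_width_distractor <= 0)
    stop("observer_params(): kernel widths must be positive")
  if (o$motor_noise_sd <= 0) stop("observer_params(): motor_noise_sd must be positive")
  if (o$lapse_rate < 0 || o$lapse_rate >= 1)
    stop("observer_params(): lapse_rate must lie in [0,1)")
  if (o$rt_base <= 0 || o$rt_shape <= 0 || o$adjust_rt_mean <= 0)
    stop("observer_params(): RT parameters must be positive")
  if (o$p_correct_discrimination < 0 || o$p_correct_discrimination > 1)
    stop("observer_params(): p_correct_discrimination must lie in [0,1]")
  structure(o, class = "observer_params")
}

#' Observer preset mimicking the first reference experiment
#'
#' High-contrast probe: weaker previous-probe attraction (peak 0.76 deg),
#' previous-probe repulsive tail and a repulsive distractor kernel of
#' -0.49 degrees.
#'
#' @param ... Overrides passed on to [observer_params()].
#' @return An `observer_params` object.
#' @export
observer_params_exp1 <- function(...) {
  args <- list(attract_amp_prev_probe = 0.76,
               repulse_amp_prev_probe = -0.49,
               repulse_amp_distractor = -0.49,
               repulse_width_distractor = 30)
  args[names(list(...))] <- list(...)
  do.call(observer_params, args)
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976 transformation
# with the ratio acceptance step). mean mu > 0, shape lambda > 0;
# variance = mu^3 / lambda.
rinv_gaussian <- function(n, mean, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  z <- stats::runif(n)
  ifelse(z <= mean / (mean + x), x, mean^2 / x)
}

#' Simulate a full experiment
#'
#' Generates a trial table under the design of [design_params()] and the
#' response model of [observer_params()]. On distractor-present trials the
#' probe orientation is the distractor plus a uniform offset in
#' `[-probe_delta_range, probe_delta_range]` wrapped into `[0,180)` (the
#' distribution of rejection-sampling a uniform probe until it falls within
#' the range); on absent trials it is uniform in `[0,180)`. Reproducible:
#' the same seed yields an identical table.
#'
#' @param design A `design_params` object.
#' @param observers A single `observer_params` shared by all participants,
#'   or a list of length `design$n_participants`.
#' @param seed Integer seed for all randomness.
#' @return A validated trial table with participants `"P01"`, `"P02"`, ...
#' @export
simulate_experiment <- function(design, observers, seed) {
  if (!inherits(design, "design_params")) stop("design must be design_params()")
  if (inherits(observers, "observer_params"))
    observers <- rep(list(observers), design$n_participants)
  if (!is.list(observers) || length(observers) != design$n_participants ||
      !all(vapply(observers, inherits, logical(1), "observer_params")))
    stop("observers must be one observer_params or a list of length n_participants")
  if (length(seed) != 1 || !is.finite(seed)) stop("seed must be a single integer")
  set.seed(as.integer(seed))

  per_participant <- function(p, obs) {
    n_sess <- design$n_sessions
    nt <- design$trials_per_session
    out <- vector("list", n_sess)
    random_first <- switch(design$block_order,
                           counterbalanced = (p %% 2L) == 1L,
                           random_first = TRUE,
                           fixed_first = FALSE)
    for (s in seq_len(n_sess)) {
      half <- ceiling(nt / 2)
      blocks <- if (random_first) c(rep("random", half), rep("fixed", nt - half))
                else c(rep("fixed", half), rep("random", nt - half))
      present <- stats::runif(nt) < design$p_distractor
      dist_ori <- rep(NA_real_, nt)
      dist_ori[present] <- sample(design$distractor_orientations,
                                  sum(present), replace = TRUE)
      dist_loc <- rep(NA_integer_, nt)
      fixed_loc <- sample.int(design$n_locations, 1)
      in_random <- present & blocks == "random"
      dist_loc[in_random] <- sample.int(design$n_locations, sum(in_random),
                                        replace = TRUE)
      dist_loc[present & blocks == "fixed"] <- fixed_loc
      probe <- stats::runif(nt, 0, 180)
      probe[present] <- (dist_ori[present] +
                         stats::runif(sum(present), -design$probe_delta_range,
                                      design$probe_delta_range)) %% 180

      prev_probe <- c(NA_real_, probe[-nt])
      dprev <- wrap_diff_na(prev_probe, probe)
      ddist <- wrap_diff_na(dist_ori, probe)
      bias <- dog_na(dprev, obs$attract_amp_prev_probe, obs$attract_width_prev_probe) +
        dog_na(dprev, obs$repulse_amp_prev_probe, obs$repulse_width_prev_probe) +
        dog_na(ddist, obs$repulse_amp_distractor, obs$repulse_width_distractor)
      reported <- (probe + bias + stats::rnorm(nt, 0, obs$motor_noise_sd)) %% 180
      lapse <- stats::runif(nt) < obs$lapse_rate
      reported[lapse] <- stats::runif(sum(lapse), 0, 180)

      mu <- obs$rt_base +
        obs$rt_location_effect * (blocks == "fixed") +
        obs$rt_distractor_effect * present +
        obs$rt_interaction * ((blocks == "fixed") & present)
      drt <- rinv_gaussian(nt, mu, obs$rt_shape)
      art <- rinv_gaussian(nt, obs$adjust_rt_mean,
                           obs$adjust_rt_mean^3 / obs$adjust_rt_sd^2)
      correct <- stats::runif(nt) < obs$p_correct_discrimination

      out[[s]] <- data.frame(
        participant_id = sprintf("P%02d", p),
        session = s,
        trial_index = seq_len(nt),
        location_condition = blocks,
        distractor_present = present,
        distractor_orientation = dist_ori,
        distractor_location = dist_loc,
        probe_orientation = probe,
        reported_orientation = reported,
        discrimination_correct = correct,
        discrimination_rt = drt,
        adjustment_rt = art,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  trials <- do.call(rbind, lapply(seq_len(design$n_participants),
                                  function(p) per_participant(p, observers[[p]])))
  rownames(trials) <- NULL
  validate_trials(trials)
}

wrap_diff_na <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

dog_na <- function(delta, amplitude, width) {
  if (amplitude == 0) return(ifelse(is.na(delta), 0, 0))
  v <- dog_kernel(delta, amplitude, width)
  ifelse(is.na(v), 0, v)
}

#' Sample a cohort of observers with between-participant RT variability
#'
#' Real participants differ in overall discrimination speed; the
#' mixed-effects RT model estimates exactly that participant-level
#' intercept spread. This helper returns a list of observers sharing the
#' bias/noise parameters of `base` but with `rt_base` drawn from a normal
#' distribution centred on `base$rt_base`.
#'
#' @param n Number of observers.
#' @param base An [observer_params()] template.
#' @param rt_base_sd Between-participant SD of `rt_base` in ms (default 50,
#'   the scale of between-subject mean-RT spread in this paradigm).
#' @param seed Integer seed.
#' @return A list of `observer_params` of length `n`.
#' @export
sample_cohort <- function(n, base = observer_params(), rt_base_sd = 50,
                          seed = 1) {
  set.seed(as.integer(seed))
  shifts <- stats::rnorm(n, 0, rt_base_sd)
  lapply(seq_len(n), function(i) {
    o <- unclass(base)
    o$rt_base <- max(base$rt_base + shifts[i], 100)
    do.call(observer_params, o)
  })
}
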