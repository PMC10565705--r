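# Shared setup for the numbered analysis scripts. Each script can be run
# on its own from the repository root; intermediate trial tables live in
# scratch/ (bulky, regenerated on demand), summaries in results/.

suppressMessages(library(serialdep))

SEED <- 20260923
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

# Two simulated cohorts mirroring the two experiments: the first with a
# high-contrast probe (weak attraction, a repulsive distractor kernel),
# the second with a low-contrast probe (strong attraction, no measurable
# distractor kernel). Between-observer RT baseline spread 50 ms.
cohort_exp1 <- function() sample_cohort(14, observer_params_exp1(),
                                        rt_base_sd = 50, seed = SEED + 1)
cohort_exp2 <- function() sample_cohort(18, observer_params(),
                                        rt_base_sd = 50, seed = SEED + 2)

trials_path <- function(exp) sprintf("scratch/trials_exp%d.csv", exp)
clean_path <- function(exp) sprintf("scratch/clean_exp%d.csv", exp)

ensure_trials <- function(exp) {
  if (!file.exists(trials_path(exp))) {
    message("trial table for experiment ", exp,
            " not found; running analysis/01_simulate.R first")
    source("analysis/01_simulate.R")
  }
  read_trials(trials_path(exp))
}

ensure_clean <- function(exp) {
  if (!file.exists(clean_path(exp))) {
    message("cleaned table for experiment ", exp,
            " not found; running analysis/02_preprocess.R first")
    source("analysis/02_preprocess.R")
  }
  read_trials(clean_path(exp))
}

sd_data <- function(trials, predictor = c("prev_probe", "distractor")) {
  predictor <- match.arg(predictor)
  delta <- if (predictor == "prev_probe") trials$delta_prev_probe
           else trials$delta_distractor
  data.frame(delta = delta, error = trials$adjustment_error,
             loc = as.numeric(trials$location_condition == "fixed"))
}
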