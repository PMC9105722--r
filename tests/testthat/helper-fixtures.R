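# Small shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# analytic noise-free linear-mode steps: 3 subjects x 4 conditions x 2 feet
tiny_steps <- function() memo("tiny_steps", function() {
  simulate_steps(sim_config(
    n_subjects = 3, conditions = graded_conditions()[c(1, 3, 5, 8), ],
    steps_per_trial = 5, seed = 301))
})

# one raw linear-mode trial with a known lag, default (2 N / 0.5 kPa) noise
tiny_trial <- function() memo("tiny_trial", function() {
  simulate_cohort(sim_config(
    n_subjects = 1, conditions = graded_conditions()[1, ],
    steps_per_trial = 6, seed = 302, lag_samples = 13))$trials[[1]]
})

# the same trial without any noise
tiny_trial_clean <- function() memo("tiny_trial_clean", function() {
  simulate_cohort(sim_config(
    n_subjects = 1, conditions = graded_conditions()[1, ],
    steps_per_trial = 6, seed = 302, lag_samples = 13,
    noise_sd_pressure = 0, noise_sd_grf = 0))$trials[[1]]
})

phase101 <- seq(0, 1, length.out = 101)
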