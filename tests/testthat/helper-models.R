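# Small models and shortcuts shared across test files.

# 1-state linear decay x' = -r x, closed form x(t) = x0 exp(-r t).
decay_model <- function(x0 = 1, horizon = 10, grid_size = 101) {
  dynamical_model(
    name = "decay",
    state_names = "x",
    parameter_names = "r",
    initial_state = c(x = x0),
    rhs = function(t, x, p, u) -p[["r"]] * x,
    default_sim = sim_control(horizon = horizon,
                              grid_size = grid_size))
}

# Model whose rhs emits NaN whenever p1 exceeds a threshold, to
# exercise the failed-sample masking path.
fragile_model <- function(threshold = 0.5) {
  dynamical_model(
    name = "fragile",
    state_names = "x",
    parameter_names = "p1",
    initial_state = c(x = 1),
    rhs = function(t, x, p, u)
      if (p[["p1"]] > threshold) NaN else -x,
    default_sim = sim_control(horizon = 1, grid_size = 11))
}

# Manual trajectory for evaluation-function tests.
make_traj <- function(times, trace, state = "Y") {
  structure(list(times = times,
                 states = matrix(trace, ncol = 1,
                                 dimnames = list(NULL, state))),
            class = "cra_trajectory")
}

pulse_objectives <- function() {
  list(area = evaluation_function("area", "Y", "maximize"),
       maximum = evaluation_function("maximum", "Y", "maximize"),
       time_to_maximum = evaluation_function("time_to_maximum", "Y",
                                             "minimize"))
}

# Tail-conditioned density estimates warn below 1000 values; tests at
# deliberately small N expect that and silence it.
quiet <- function(expr) suppressWarnings(expr)
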