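#' The incoherent-feedforward pulse generator
#'
#' Two-state synthetic gene circuit in which an inducing signal S1
#' activates both the output Y (through a multi-input promoter) and a
#' repressor R2 of that promoter, so a sustained input yields a pulse
#' of Y.  Activation and repression follow Hill kinetics with both
#' exponents fixed at 3 (they are structural constants of the circuit
#' and are not part of the sampled parameter space):
#'
#' \deqn{\dot R_2 = k_1 \frac{(S_1/K_1)^3}{1+(S_1/K_1)^3} - \lambda_2 R_2}
#' \deqn{\dot Y = \frac{k_{12}}{1+(R_2/K_2)^3}
#'               \frac{(S_1/K_1)^3}{1+(S_1/K_1)^3} - \lambda Y}
#'
#' Nominal values: k1 = 5, k12 = 20 nM/min, lambda2 = 0.01,
#' lambda = 0.04 /min, K1 = 1, K2 = 100 nM.  The canonical stimulus is
#' a rectangular S1 pulse of 470 nM held for 50 min and then released;
#' both states start at zero.
#'
#' The default simulation horizon is 500 min: at the nominal decay rate
#' lambda = 0.04/min the output pulse is negligible well before then,
#' so area readouts are effectively horizon-independent.
#'
#' @param input_amplitude S1 level during stimulation, nM.
#' @param input_duration stimulation length, minutes.
#' @param horizon,grid_size simulation settings (see [sim_control()]).
#' @return a [dynamical_model()] with states `R2`, `Y` and sampled
#'   parameters `k1, K1, k12, K2, lambda2, lambda`.
#' @export
pulse_generator_model <- function(input_amplitude = 470,
                                  input_duration = 50,
                                  horizon = 500, grid_size = 1001) {
  pars <- c("k1", "K1", "k12", "K2", "lambda2", "lambda")
  dynamical_model(
    name = "pulse_generator",
    state_names = c("R2", "Y"),
    parameter_names = pars,
    initial_state = c(R2 = 0, Y = 0),
    compiled = list(
      func = "pulse_derivs", initfunc = "pulse_init",
      dllname = "condrob",
      parms_fn = function(params, inputs) {
        c(params[pars], inputs[["S1"]])
      }),
    input_names = "S1",
    input_schedule = list(breaks = input_duration,
                          values = matrix(c(input_amplitude, 0),
                                          ncol = 1)),
    default_sim = sim_control(horizon = horizon, grid_size = grid_size))
}

#' Nominal pulse-generator parameters
#' @return named vector of the six wild-type kinetic values.
#' @export
pulse_nominal_parameters <- function() {
  c(k1 = 5, K1 = 1, k12 = 20, K2 = 100, lambda2 = 0.01, lambda = 0.04)
}

#' Default pulse-generator sampling space
#'
#' Factor-10 multiplicative bounds either side of the nominal values,
#' the standard two-orders-of-magnitude box for this circuit.
#' @inheritParams build_parameter_space
#' @return a `parameter_space` over the six kinetic parameters.
#' @export
pulse_parameter_space <- function(lower_factor = 0.1, upper_factor = 10,
                                  scale = "linear") {
  build_parameter_space(pulse_nominal_parameters(), lower_factor,
                        upper_factor, scale = scale)
}
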