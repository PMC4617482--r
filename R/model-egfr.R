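#' The EGFR-IGF1R signalling cascade
#'
#' Ten-state ODE model of the EGFR / IGF1R network driving the MAPK
#' cascade in non-small-cell lung cancer.  Receptor activities x1
#' (EGFR) and x2 (IGF1R) decay and drive a cascade of
#' activation/deactivation cycles; every downstream species i = 3..10
#' obeys a conservation law (active form x_i plus inactive form
#' x_i^T - x_i), so its Michaelis-Menten activation acts on the
#' inactive pool x_i^T - x_i.  The readout state is x7, active ERK
#' (ERK*): the area under its trace over a 30-minute horizon is the
#' proliferation indicator.
#'
#' The model has 39 kinetic parameters p1..p39, three constant inputs
#' u1..u3, eight conserved totals x3T..x10T, and two sampled-or-fixed
#' receptor initial conditions.  Non-receptor states start at zero
#' (inactive forms), the standard initial condition for an
#' activation-cascade model driven by ligand-bound receptors.
#'
#' Two transcription quirks of the source equations are handled
#' explicitly rather than silently repaired:
#' \itemize{
#'   \item the x3 balance removes flux through a species `x13` that is
#'     not among the ten states; it is treated as a named constant
#'     (`x13_constant`, default 1);
#'   \item the x5 balance contains a removal term driven by x7 rather
#'     than x5; the verbatim form is the default, and
#'     `x5_feedback = "x5"` substitutes x5 for sensitivity checks.  In
#'     the verbatim form the term is suppressed once x5 is exhausted so
#'     concentrations stay within their conservation bounds.
#' }
#'
#' Canonical wild-type values for parameters, totals and inputs live in
#' the model's supplementary material and must be supplied by the user
#' (see [load_parameter_table()]); the built-in defaults of 1.0 are
#' synthetic placeholders, clearly non-canonical, that exercise the
#' model structure only.
#'
#' @param parameter_values named or ordered vector of 39 positive
#'   kinetics p1..p39.
#' @param totals vector of 8 conserved totals x3T..x10T (> 0).
#' @param initial_receptors length-2 vector (x1_0, x2_0) >= 0.
#' @param inputs length-3 vector (u1, u2, u3) >= 0.
#' @param x13_constant positive constant standing in for the
#'   unresolved x13 species.
#' @param x5_feedback `"x7"` (verbatim equations) or `"x5"`.
#' @param horizon,grid_size simulation settings; the canonical study
#'   window is 30 min on a 1000-point grid.
#' @return a [dynamical_model()] with states `x1..x10`, output state
#'   `x7`.
#' @export
egfr_igf1r_model <- function(parameter_values = egfr_placeholder_values()$p,
                             totals = egfr_placeholder_values()$totals,
                             initial_receptors = egfr_placeholder_values()$x0,
                             inputs = egfr_placeholder_values()$u,
                             x13_constant = 1,
                             x5_feedback = c("x7", "x5"),
                             horizon = 30, grid_size = 1000) {
  x5_feedback <- match.arg(x5_feedback)
  if (length(parameter_values) != 39)
    stop("expected 39 parameters p1..p39")
  if (length(totals) != 8) stop("expected 8 totals x3T..x10T")
  if (length(initial_receptors) != 2)
    stop("expected 2 receptor initial values")
  if (length(inputs) != 3) stop("expected 3 inputs u1..u3")
  if (any(parameter_values <= 0) || any(totals <= 0) ||
      any(initial_receptors < 0) || any(inputs < 0) ||
      x13_constant <= 0)
    stop("parameters, totals and x13 must be > 0; ",
         "receptors and inputs >= 0")

  pars <- paste0("p", 1:39)
  states <- paste0("x", 1:10)
  totals <- stats::setNames(as.numeric(totals), paste0("x", 3:10, "T"))
  inputs <- stats::setNames(as.numeric(inputs), c("u1", "u2", "u3"))
  x0 <- stats::setNames(c(as.numeric(initial_receptors), rep(0, 8)),
                        states)
  fixed_block <- c(totals, inputs, x13_constant,
                   if (x5_feedback == "x5") 1 else 0)

  mdl <- dynamical_model(
    name = "egfr_igf1r",
    state_names = states,
    parameter_names = pars,
    initial_state = x0,
    compiled = list(
      func = "egfr_derivs", initfunc = "egfr_init",
      dllname = "condrob",
      parms_fn = function(params, inputs) {
        # inputs are constant; the full fixed block is baked in
        c(params[pars], fixed_block)
      }),
    input_names = character(),
    input_schedule = NULL,
    conserved_totals = totals,
    default_sim = sim_control(horizon = horizon, grid_size = grid_size))
  attr(mdl, "nominal") <- stats::setNames(as.numeric(parameter_values),
                                          pars)
  mdl
}

#' Synthetic placeholder values for the EGFR-IGF1R model
#'
#' All-ones placeholders (receptors at 1 nM) standing in for the
#' canonical supplementary-table values, which users supply via
#' [load_parameter_table()].  Suitable only for structural and
#' directional analyses; results under these values are not the
#' published ones.
#' @return list with `p` (39), `totals` (8), `x0` (2), `u` (3).
#' @export
egfr_placeholder_values <- function() {
  list(p = stats::setNames(rep(1, 39), paste0("p", 1:39)),
       totals = stats::setNames(rep(1, 8), paste0("x", 3:10, "T")),
       x0 = c(x1_0 = 1, x2_0 = 1),
       u = c(u1 = 1, u2 = 1, u3 = 1))
}

#' Build the EGFR-IGF1R model from a name/value table
#'
#' Accepts the flat named map produced by [load_parameter_table()]
#' (names p1..p39, x3T..x10T, x1_0, x2_0, u1..u3) and instantiates the
#' model.
#' @param values named numeric map covering all required names.
#' @param ... passed to [egfr_igf1r_model()].
#' @return a [dynamical_model()].
#' @export
egfr_model_from_table <- function(values, ...) {
  need <- c(paste0("p", 1:39), paste0("x", 3:10, "T"),
            "x1_0", "x2_0", paste0("u", 1:3))
  missing <- setdiff(need, names(values))
  if (length(missing))
    stop("missing required entries: ", paste(missing, collapse = ", "))
  egfr_igf1r_model(parameter_values = values[paste0("p", 1:39)],
                   totals = values[paste0("x", 3:10, "T")],
                   initial_receptors = values[c("x1_0", "x2_0")],
                   inputs = values[paste0("u", 1:3)], ...)
}
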