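#' Construct a dynamical model
#'
#' A `dynamical_model` bundles everything needed to simulate a parametric
#' ODE system x' = f(x, u, p) and score its trajectories: state names,
#' parameter names, constant (piecewise-constant) inputs, initial
#' conditions and the right-hand side.  The right-hand side is either a
#' plain R function `rhs(t, state, params, inputs)` returning the state
#' derivative, or a reference to a compiled deSolve routine (used by the
#' built-in models, where simulation cost dominates the analysis).
#'
#' @param name model identifier.
#' @param state_names character vector of state identifiers.
#' @param parameter_names character vector of the q sampled parameters.
#' @param initial_state named numeric vector x0 (concentrations, nM),
#'   one entry per state; all finite and >= 0.
#' @param rhs R function `(t, state, params, inputs) -> derivative`, or
#'   `NULL` when `compiled` is given.
#' @param compiled optional list with entries `func`, `initfunc`,
#'   `dllname` (deSolve compiled-code interface) and `parms_fn`, a
#'   function `(params, inputs) -> numeric` assembling the parameter
#'   block handed to the compiled routine for one integration segment.
#' @param input_names character vector of input identifiers (may be
#'   empty).
#' @param input_schedule piecewise-constant input description: a list
#'   with `breaks` (strictly increasing interior switch times, minutes)
#'   and `values`, a matrix with `length(breaks) + 1` rows and one
#'   column per input: row s holds the input levels on segment s.
#'   `NULL` means no inputs.
#' @param conserved_totals optional named vector of conserved totals
#'   x_i^T (same units as states) for states obeying a conservation
#'   law.
#' @param default_sim a [sim_control()] holding the model's canonical
#'   horizon and solver settings.
#'
#' @return an object of class `dynamical_model`.
#' @seealso [pulse_generator_model()], [egfr_igf1r_model()],
#'   [integrate_model()]
#' @export
dynamical_model <- function(name, state_names, parameter_names,
                            initial_state, rhs = NULL, compiled = NULL,
                            input_names = character(),
                            input_schedule = NULL,
                            conserved_totals = NULL,
                            default_sim = sim_control()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(state_names), length(state_names) >= 1L,
            is.character(parameter_names))
  if (is.null(rhs) && is.null(compiled))
    stop("a dynamical model needs either an R `rhs` or a `compiled` spec")
  if (!all(is.finite(initial_state)) || any(initial_state < 0))
    stop("initial state must be finite and non-negative")
  if (length(initial_state) != length(state_names))
    stop("initial_state length must match state_names")
  names(initial_state) <- state_names
  if (!is.null(conserved_totals)) {
    if (!all(is.finite(conserved_totals)) || any(conserved_totals < 0))
      stop("conserved totals must be finite and non-negative")
  }
  if (!is.null(input_schedule)) {
    stopifnot(is.matrix(input_schedule$values),
              ncol(input_schedule$values) == length(input_names),
              nrow(input_schedule$values) ==
                length(input_schedule$breaks) + 1L)
    if (is.unsorted(input_schedule$breaks, strictly = TRUE))
      stop("input switch times must be strictly increasing")
    if (any(input_schedule$values < 0))
      stop("inputs must be non-negative")
    colnames(input_schedule$values) <- input_names
  }
  structure(
    list(name = name,
         state_names = state_names,
         parameter_names = parameter_names,
         input_names = input_names,
         rhs = rhs,
         compiled = compiled,
         initial_state = initial_state,
         input_schedule = input_schedule,
         conserved_totals = conserved_totals,
         default_sim = default_sim),
    class = "dynamical_model")
}

#' @export
print.dynamical_model <- function(x, ...) {
  cat("<dynamical_model> ", x$name, "\n",
      "  states:     ", paste(x$state_names, collapse = ", "), "\n",
      "  parameters: ", length(x$parameter_names), "\n",
      "  inputs:     ", if (length(x$input_names))
        paste(x$input_names, collapse = ", ") else "(none)", "\n",
      "  rhs:        ", if (is.null(x$compiled)) "R function"
      else paste0("compiled (", x$compiled$func, ")"), "\n", sep = "")
  invisible(x)
}

#' Simulation control settings
#'
#' @param horizon simulation horizon, minutes.
#' @param grid_size number of points of the uniform output grid
#'   (>= 2; `grid_size = 2` returns exactly start and end).
#' @param rtol,atol relative/absolute solver tolerances passed to the
#'   stiff-capable `deSolve::lsoda` integrator.
#' @param clamp_tol relative negative-concentration tolerance: state
#'   values in `(-clamp_tol * s, 0)`, with s the trajectory's state
#'   scale `max(1, max|x|)`, are clipped to zero as solver round-off;
#'   more negative values mark the sample as a failed integration.
#' @return a list of class `sim_control`.
#' @export
sim_control <- function(horizon = 500, grid_size = 1001,
                        rtol = 1e-6, atol = 1e-9, clamp_tol = 1e-4) {
  stopifnot(horizon > 0, grid_size >= 2)
  structure(list(horizon = horizon, grid_size = grid_size,
                 rtol = rtol, atol = atol, clamp_tol = clamp_tol),
            class = "sim_control")
}

#' Define an evaluation function
#'
#' An evaluation function maps a simulated trajectory to the scalar
#' output z that the robustness analysis distributes, partitions and
#' conditions.  Three standard choices cover the usual readouts of a
#' signalling pulse: the area under the target trace (trapezoidal rule
#' over the full grid), its maximum, and the time at which the maximum
#' first occurs.
#'
#' @param name one of `"area"`, `"maximum"`, `"time_to_maximum"`,
#'   `"custom"`.
#' @param target_state state identifier whose trace is scored.
#' @param direction `"maximize"` or `"minimize"`; not used by the
#'   scoring itself but by downstream conditioning (which tail of the
#'   output distribution is the desirable one).
#' @param fn for `name = "custom"`: a function `(times, trace) -> z`.
#' @return an object of class `evaluation_function`.
#' @export
evaluation_function <- function(name, target_state,
                                direction = c("maximize", "minimize"),
                                fn = NULL) {
  name <- match.arg(name, c("area", "maximum", "time_to_maximum",
                            "custom"))
  direction <- match.arg(direction)
  if (name == "custom" && !is.function(fn))
    stop("custom evaluation needs `fn(times, trace)`")
  structure(list(name = name, target_state = target_state,
                 direction = direction, fn = fn),
            class = "evaluation_function")
}

#' Score a trajectory with an evaluation function
#'
#' @param traj a trajectory as returned by [integrate_model()].
#' @param fn an [evaluation_function()].
#' @return scalar z.  `time_to_maximum` returns the grid time of the
#'   first maximal value (an all-constant trace therefore scores 0).
#' @export
evaluate <- function(traj, fn) {
  stopifnot(inherits(traj, "cra_trajectory"),
            inherits(fn, "evaluation_function"))
  if (!fn$target_state %in% colnames(traj$states))
    stop("target state `", fn$target_state, "` not in trajectory")
  tr <- traj$states[, fn$target_state]
  switch(fn$name,
         area = pracma::trapz(traj$times, tr),
         maximum = max(tr),
         time_to_maximum = traj$times[which.max(tr)],
         custom = fn$fn(traj$times, tr))
}
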