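#' Integrate a dynamical model onto a uniform grid
#'
#' Stiff-capable adaptive integration (`deSolve::lsoda`) of a
#' [dynamical_model()], sampled onto a uniform time grid.  Models with
#' piecewise-constant inputs are integrated segment by segment, the
#' integration restarting at every input switch time so the solver never
#' steps across a discontinuity.
#'
#' @param model a [dynamical_model()].
#' @param params named (or model-ordered) numeric vector of parameter
#'   values, all positive and finite.
#' @param sim a [sim_control()]; defaults to the model's own.
#' @param initial_state optional replacement initial state (used when
#'   initial conditions are sampled jointly with the parameters).
#' @return an object of class `cra_trajectory`: a list with `times`
#'   (uniform grid from 0 to the horizon) and `states` (grid x state
#'   matrix, named columns).  Returns `NULL` when the solver fails or
#'   produces non-finite values / negatives beyond the clamp tolerance;
#'   callers treat `NULL` as a flagged failed sample.
#' @export
integrate_model <- function(model, params, sim = NULL,
                            initial_state = NULL) {
  stopifnot(inherits(model, "dynamical_model"))
  sim <- sim %||% model$default_sim
  if (length(params) != length(model$parameter_names))
    stop("expected ", length(model$parameter_names), " parameters")
  if (!all(is.finite(params)) || any(params <= 0))
    stop("parameters must be finite and > 0")
  params <- stats::setNames(as.numeric(params), model$parameter_names)
  x0 <- initial_state %||% model$initial_state

  grid <- seq(0, sim$horizon, length.out = sim$grid_size)
  breaks <- model$input_schedule$breaks
  breaks <- breaks[breaks > 0 & breaks < sim$horizon]
  seg_bounds <- c(0, breaks, sim$horizon)
  n_seg <- length(seg_bounds) - 1L

  inputs_for <- function(s) {
    if (is.null(model$input_schedule)) return(numeric())
    model$input_schedule$values[min(s, nrow(model$input_schedule$values)), ]
  }

  out <- matrix(NA_real_, length(grid), length(model$state_names))
  out[1, ] <- x0
  state <- x0
  ok <- TRUE

  for (s in seq_len(n_seg)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    inner <- grid[grid > t0 & grid < t1]
    seg_times <- c(t0, inner, t1)
    u <- inputs_for(s)
    sol <- tryCatch(
      if (is.null(model$compiled)) {
        deSolve::ode(y = state, times = seg_times,
                     func = function(t, y, p) {
                       list(model$rhs(t, y, p, u))
                     },
                     parms = params, method = "lsoda",
                     rtol = sim$rtol, atol = sim$atol,
                     maxsteps = 20000)
      } else {
        deSolve::ode(y = state, times = seg_times,
                     func = model$compiled$func,
                     initfunc = model$compiled$initfunc,
                     dllname = model$compiled$dllname,
                     parms = model$compiled$parms_fn(params, u),
                     method = "lsoda",
                     rtol = sim$rtol, atol = sim$atol,
                     maxsteps = 20000)
      },
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(seg_times) ||
        !all(is.finite(sol[, -1]))) {
      ok <- FALSE; break
    }
    vals <- sol[, -1, drop = FALSE]
    # negatives within clamp_tol of the trajectory scale are solver
    # round-off and are clipped; larger excursions fail the sample
    scale <- max(1, abs(vals))
    if (min(vals) < -sim$clamp_tol * scale) { ok <- FALSE; break }
    vals[vals < 0] <- 0
    keep <- seg_times %in% grid
    out[match(seg_times[keep], grid), ] <- vals[keep, , drop = FALSE]
    state <- vals[nrow(vals), ]
    names(state) <- model$state_names
  }

  if (!ok || anyNA(out)) return(NULL)
  colnames(out) <- model$state_names
  structure(list(times = grid, states = out), class = "cra_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
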