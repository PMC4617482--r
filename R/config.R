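#' Assemble a run configuration
#'
#' Validates and normalizes the four classes of configuration the
#' analysis needs: the multiplicative perturbation factors defining the
#' parameter space, the sample count N, the tail probability alpha, and
#' the conditioning-set size k — plus model choice, objectives, seeds
#' and solver settings.
#'
#' @param model model name (`"pulse_generator"`, `"egfr_igf1r"`,
#'   `"identity_fixture"`, `"linear_fixture"`) or a ready model object.
#' @param objectives list of objective specs, each a list with `name`
#'   (evaluation name), `target` (state) and `direction`; ignored for
#'   fixtures.
#' @param N sample count (>= 2; a warning is issued when
#'   `N < 1000 / alpha`).
#' @param alpha tail probability in (0, 0.5].
#' @param n_realizations replicate count for the MIRI box statistics.
#' @param k conditioning-set size (checked against the space later).
#' @param base_seed integer base seed; realization r uses
#'   `base_seed + r`.
#' @param lower_factor,upper_factor sampling-box factors.
#' @param horizon,grid_size,rtol,atol solver settings (`NULL` keeps
#'   the model defaults).
#' @param workers parallel worker count.
#' @param outdir results directory for [run_cra()].
#' @param parameter_table optional CSV path of model constants (see
#'   [load_parameter_table()]); used by the EGFR-IGF1R model.
#' @param model_args extra arguments for the model constructor.
#' @return validated list of class `cra_config`.
#' @export
cra_config <- function(model = "pulse_generator",
                       objectives = list(list(name = "area",
                                              target = "Y",
                                              direction = "maximize")),
                       N = 10000, alpha = 0.1, n_realizations = 1,
                       k = 3, base_seed = 0L,
                       lower_factor = 0.1, upper_factor = 10,
                       horizon = NULL, grid_size = NULL,
                       rtol = 1e-6, atol = 1e-9,
                       workers = 1L, outdir = NULL,
                       parameter_table = NULL, model_args = list()) {
  check_n_alpha(N, alpha)
  stopifnot(n_realizations >= 1, k >= 0, workers >= 1)
  cfg <- list(model = model, objectives = objectives, N = as.integer(N),
              alpha = alpha, n_realizations = as.integer(n_realizations),
              k = as.integer(k), base_seed = as.integer(base_seed),
              lower_factor = lower_factor, upper_factor = upper_factor,
              horizon = horizon, grid_size = grid_size,
              rtol = rtol, atol = atol, workers = as.integer(workers),
              outdir = outdir, parameter_table = parameter_table,
              model_args = model_args)
  class(cfg) <- "cra_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Flat key/value file mirroring the arguments of [cra_config()];
#' unknown keys are rejected.  The sample count may be written as
#' `n_samples` (an alias for `N`): YAML 1.1 parsers read an unquoted
#' `N:` key as a boolean, so the alias — or a quoted `"N":` — avoids
#' that pitfall.
#' @param path YAML file.
#' @param ... overrides applied after reading (e.g. from CLI flags).
#' @return a `cra_config`.
#' @export
read_cra_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  # an unquoted `N:` key arrives as the boolean name "FALSE"
  names(raw)[names(raw) %in% c("n_samples", "FALSE")] <- "N"
  allowed <- names(formals(cra_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  over <- list(...)
  raw[names(over)] <- over
  do.call(cra_config, raw)
}

#' Load a name/value parameter table
#'
#' Reads a two-column CSV (`name,value`) carrying model constants:
#' kinetic parameters `p1..p39`, conserved totals `x3T..x10T`,
#' receptor initial conditions `x1_0`, `x2_0` and inputs `u1..u3` for
#' the EGFR-IGF1R model, or any parameter map for custom models.
#' Rates (`p*` names) must be strictly positive; initial conditions and
#' inputs non-negative.
#'
#' @param path CSV path.
#' @param required optional character vector of names that must all be
#'   present; the full missing set is reported.
#' @return named numeric vector.
#' @export
load_parameter_table <- function(path, required = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "value") %in% names(df)))
    stop("parameter table needs columns `name` and `value`")
  if (anyDuplicated(df$name))
    stop("duplicate parameter names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  if (!is.numeric(df$value) || any(!is.finite(df$value)))
    stop("non-numeric or non-finite values in parameter table")
  vals <- stats::setNames(df$value, df$name)
  is_rate <- grepl("^p[0-9]+$", names(vals))
  if (any(vals[is_rate] <= 0))
    stop("non-positive rate values: ",
         paste(names(vals)[is_rate & vals <= 0], collapse = ", "))
  if (any(vals < 0))
    stop("negative values: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  if (!is.null(required)) {
    missing <- setdiff(required, names(vals))
    if (length(missing))
      stop("missing required names: ", paste(missing, collapse = ", "))
  }
  vals
}

#' Instantiate a model and its sampling space from a configuration
#' @param cfg a `cra_config`.
#' @return list with `model`, `space` and `fn` (evaluation functions,
#'   `NULL` for fixtures).
#' @export
build_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "cra_config"))
  if (inherits(cfg$model, c("dynamical_model", "fixture_model"))) {
    model <- cfg$model
  } else {
    model <- switch(
      cfg$model,
      pulse_generator = do.call(pulse_generator_model, cfg$model_args),
      egfr_igf1r = {
        if (!is.null(cfg$parameter_table)) {
          vals <- load_parameter_table(cfg$parameter_table)
          do.call(egfr_model_from_table,
                  c(list(values = vals), cfg$model_args))
        } else {
          warning("EGFR-IGF1R model instantiated with synthetic ",
                  "placeholder values; supply `parameter_table` for ",
                  "canonical constants", call. = FALSE)
          do.call(egfr_igf1r_model, cfg$model_args)
        }
      },
      identity_fixture = do.call(make_identity_fixture, cfg$model_args),
      linear_fixture = do.call(make_linear_fixture, cfg$model_args),
      stop("unknown model: ", cfg$model))
  }

  if (inherits(model, "fixture_model")) {
    space <- model$space
    fn <- NULL
  } else if (model$name == "pulse_generator") {
    space <- pulse_parameter_space(cfg$lower_factor, cfg$upper_factor)
    fn <- objectives_to_fns(cfg$objectives)
  } else if (model$name == "egfr_igf1r") {
    nominal <- attr(model, "nominal") %||%
      stats::setNames(rep(1, 39), paste0("p", 1:39))
    space <- build_parameter_space(nominal, cfg$lower_factor,
                                   cfg$upper_factor)
    fn <- objectives_to_fns(cfg$objectives)
  } else {
    stop("no sampling space known for model `", model$name,
         "`; pass a model name from the registry")
  }
  if (cfg$k > length(space$names))
    stop("k exceeds the number of sampled parameters")
  list(model = model, space = space, fn = fn)
}

objectives_to_fns <- function(objectives) {
  fns <- lapply(objectives, function(o)
    evaluation_function(o$name, o$target, o$direction))
  names(fns) <- vapply(objectives, function(o)
    o$label %||% o$name, "")
  fns
}
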