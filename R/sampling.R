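#' Build a parameter space with multiplicative bounds
#'
#' The sampling box is defined per parameter by a nominal (wild-type)
#' value and two multiplicative factors: bounds are
#' `lower_factor * nominal` and `upper_factor * nominal`.  The implied
#' prior over the box is uniform.  The conventional choice in global
#' analyses of biochemical networks — and the default here — spans one
#' order of magnitude either side of the wild type (factors 0.1 and
#' 10).
#'
#' @param nominal named positive numeric vector of wild-type values.
#' @param lower_factor,upper_factor positive scalars or per-parameter
#'   vectors with `0 < lower_factor < upper_factor`.
#' @param scale `"linear"` (default) or `"log"`, scalar or
#'   per-parameter: controls whether Latin hypercube strata are equal
#'   width on the linear or the log axis.
#' @param names parameter names (defaults to `names(nominal)`).
#' @return object of class `parameter_space` with fields `names`,
#'   `nominal`, `lower`, `upper`, `scale`.
#' @export
build_parameter_space <- function(nominal, lower_factor = 0.1,
                                  upper_factor = 10,
                                  scale = "linear", names = NULL) {
  names <- names %||% base::names(nominal)
  if (is.null(names))
    names <- paste0("p", seq_along(nominal))
  q <- length(nominal)
  if (any(!is.finite(nominal)) || any(nominal <= 0))
    stop("nominal values must be finite and > 0")
  lower_factor <- rep_len(lower_factor, q)
  upper_factor <- rep_len(upper_factor, q)
  if (any(lower_factor <= 0) || any(lower_factor >= upper_factor))
    stop("need 0 < lower_factor < upper_factor for every parameter ",
         "(equal factors give a degenerate box)")
  scale <- rep_len(match.arg(scale, c("linear", "log"), several.ok = TRUE),
                   q)
  new_parameter_space(names, nominal, nominal * lower_factor,
                      nominal * upper_factor, scale)
}

#' Parameter space from explicit bounds
#'
#' Used by fixture models whose boxes (e.g. the unit cube) are not
#' naturally multiplicative.
#' @param names parameter names.
#' @param lower,upper bound vectors, `0 <= lower < upper`.
#' @param nominal optional nominal vector (defaults to box midpoints).
#' @param scale `"linear"` or `"log"` per parameter.
#' @return a `parameter_space`.
#' @export
parameter_space_bounds <- function(names, lower, upper, nominal = NULL,
                                   scale = "linear") {
  q <- length(names)
  lower <- rep_len(lower, q); upper <- rep_len(upper, q)
  if (any(lower < 0) || any(lower >= upper))
    stop("need 0 <= lower < upper")
  nominal <- nominal %||% (lower + upper) / 2
  scale <- rep_len(match.arg(scale, c("linear", "log"), several.ok = TRUE),
                   q)
  new_parameter_space(names, nominal, lower, upper, scale)
}

new_parameter_space <- function(names, nominal, lower, upper, scale) {
  if (anyDuplicated(names)) stop("duplicate parameter names")
  if (any(scale == "log" & lower <= 0))
    stop("log-scaled parameters need strictly positive lower bounds")
  structure(list(names = names,
                 nominal = stats::setNames(as.numeric(nominal), names),
                 lower = stats::setNames(as.numeric(lower), names),
                 upper = stats::setNames(as.numeric(upper), names),
                 scale = stats::setNames(scale, names)),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space> ", length(x$names), " parameters\n", sep = "")
  print(data.frame(nominal = x$nominal, lower = x$lower,
                   upper = x$upper, scale = x$scale))
  invisible(x)
}

#' Latin hypercube sample of a parameter space
#'
#' Draws N points by Latin hypercube sampling with linearly spaced
#' strata: each bound interval is split into N equal-width strata
#' (equal width on the log axis for log-scaled parameters), the strata
#' are permuted independently per dimension, and one point is placed
#' uniformly at random inside each stratum.  The draw is reproducible
#' from `seed` and leaves the caller's RNG state untouched.
#'
#' @param space a `parameter_space`.
#' @param N number of samples (>= 2); one stratum per sample.
#' @param seed integer seed.
#' @param midpoint if `TRUE`, place each point at its stratum midpoint
#'   instead of uniformly at random (debugging aid).
#' @return object of class `cra_samples`: list with `samples` (N x q
#'   matrix, named columns), `seed`, `method`, `space`.
#' @export
sample_l2hs <- function(space, N, seed, midpoint = FALSE) {
  stopifnot(inherits(space, "parameter_space"), N >= 2)
  q <- length(space$names)
  u <- with_seed(as.integer(seed), {
    if (midpoint) {
      apply(matrix(seq_len(N), N, q), 2,
            function(col) (sample(col) - 0.5) / N)
    } else {
      lhs::randomLHS(N, q)
    }
  })
  m <- matrix(NA_real_, N, q, dimnames = list(NULL, space$names))
  for (j in seq_len(q)) {
    lo <- space$lower[j]; hi <- space$upper[j]
    m[, j] <- if (space$scale[j] == "log")
      exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    else
      lo + u[, j] * (hi - lo)
  }
  structure(list(samples = m, seed = as.integer(seed),
                 method = if (midpoint) "l2hs-midpoint" else "l2hs",
                 space = space),
            class = "cra_samples")
}

#' Append jointly sampled initial conditions to a parameter space
#'
#' Initial conditions (e.g. receptor abundances) are perturbed jointly
#' with the kinetic parameters by appending them as extra dimensions of
#' the sampling box; downstream evaluation routes columns named
#' `<state>_0` to the model's initial state.
#'
#' @param space a `parameter_space`.
#' @param ic_names names for the appended dimensions (conventionally
#'   `<state>_0`); must not already be in the space.
#' @param ic_nominal positive nominal initial values.
#' @param lower_factor,upper_factor multiplicative factors as in
#'   [build_parameter_space()].
#' @param scale stratification scale for the new dimensions.
#' @return the extended `parameter_space`.
#' @export
extend_with_initial_conditions <- function(space, ic_names, ic_nominal,
                                           lower_factor = 0.1,
                                           upper_factor = 10,
                                           scale = "linear") {
  stopifnot(inherits(space, "parameter_space"))
  if (any(ic_names %in% space$names))
    stop("duplicate names: ",
         paste(intersect(ic_names, space$names), collapse = ", "))
  ext <- build_parameter_space(ic_nominal, lower_factor, upper_factor,
                               scale = scale, names = ic_names)
  new_parameter_space(c(space$names, ext$names),
                      c(space$nominal, ext$nominal),
                      c(space$lower, ext$lower),
                      c(space$upper, ext$upper),
                      c(space$scale, ext$scale))
}

#' Write a sample set to CSV
#' @param samples a `cra_samples`.
#' @param path output file; header = parameter names, N rows.
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot(inherits(samples, "cra_samples"))
  utils::write.csv(as.data.frame(samples$samples), path,
                   row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
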