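#' Evaluate a model over a sample set
#'
#' Simulates the model once per sample row and scores each trajectory
#' with one or several evaluation functions.  Columns of the sample
#' matrix named after model parameters set the parameter vector; extra
#' columns named `<state>_0` override that state's initial condition
#' (jointly sampled initial conditions).  Work is embarrassingly
#' parallel and the result is independent of worker count and
#' scheduling order (no randomness enters the evaluation).
#'
#' Failed integrations are masked, never silently dropped: the result
#' carries a logical failure mask and the effective sample count.  If
#' 5\% or more of the samples fail the run aborts — the sampling box is
#' then almost certainly ill-posed for the model.
#'
#' @param model a [dynamical_model()] or fixture model.
#' @param samples a `cra_samples` (or bare matrix with named columns).
#' @param fn an [evaluation_function()], or a named list of them to
#'   score several readouts from one set of simulations.  Ignored by
#'   closed-form fixture models, which carry their own map.
#' @param sim a [sim_control()]; defaults to the model's own.
#' @param workers parallel worker count (forked; 1 = serial).
#' @return a `cra_output` (list with `values`, `fn_name`, `failed`,
#'   `n_effective`), or a named list of `cra_output` when `fn` is a
#'   list.
#' @export
evaluate_batch <- function(model, samples, fn = NULL, sim = NULL,
                           workers = 1L) {
  m <- if (inherits(samples, "cra_samples")) samples$samples else samples
  stopifnot(is.matrix(m), !is.null(colnames(m)))

  if (inherits(model, "fixture_model")) {
    z <- model$map(m)
    return(new_output(z, model$name, failed = !is.finite(z)))
  }

  stopifnot(inherits(model, "dynamical_model"))
  sim <- sim %||% model$default_sim
  multi <- is.list(fn) && !inherits(fn, "evaluation_function")
  fns <- if (multi) fn else list(fn)
  if (any(!vapply(fns, inherits, TRUE, "evaluation_function")))
    stop("`fn` must be evaluation_function(s)")
  if (multi && is.null(names(fns)))
    names(fns) <- vapply(fns, `[[`, "", "name")

  par_cols <- intersect(colnames(m), model$parameter_names)
  if (!setequal(par_cols, model$parameter_names))
    stop("samples lack parameter columns: ",
         paste(setdiff(model$parameter_names, colnames(m)),
               collapse = ", "))
  ic_cols <- setdiff(colnames(m), model$parameter_names)
  ic_states <- sub("_0$", "", ic_cols)
  if (length(ic_cols) && !all(ic_states %in% model$state_names))
    stop("unrecognised sample columns: ",
         paste(ic_cols[!ic_states %in% model$state_names],
               collapse = ", "))

  one <- function(i) {
    x0 <- model$initial_state
    if (length(ic_cols)) x0[ic_states] <- m[i, ic_cols]
    traj <- integrate_model(model, m[i, model$parameter_names],
                            sim = sim, initial_state = x0)
    if (is.null(traj)) return(rep(NA_real_, length(fns)))
    vapply(fns, function(f) evaluate(traj, f), numeric(1))
  }

  rows <- seq_len(nrow(m))
  res <- if (workers > 1L) {
    parallel::mclapply(rows, one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(rows, one)
  }
  zmat <- do.call(rbind, res)
  failed <- !stats::complete.cases(zmat)
  if (mean(failed) >= 0.05)
    stop(sprintf(
      "%.1f%% of %d samples failed to integrate; the sampling box is ",
      100 * mean(failed), nrow(m)),
      "likely ill-posed for this model")
  if (any(failed))
    message(sum(failed), " of ", nrow(m),
            " samples failed integration and were masked")

  outs <- lapply(seq_along(fns), function(j)
    new_output(zmat[, j], fns[[j]]$name, failed))
  if (multi) stats::setNames(outs, names(fns)) else outs[[1]]
}

new_output <- function(values, fn_name, failed) {
  values[failed] <- NA_real_
  structure(list(values = values, fn_name = fn_name, failed = failed,
                 n_effective = sum(!failed)),
            class = "cra_output")
}

#' @export
print.cra_output <- function(x, ...) {
  cat("<cra_output> ", x$fn_name, ": ", x$n_effective, " values",
      if (any(x$failed)) paste0(" (", sum(x$failed), " failed)"), "\n",
      sep = "")
  print(summary(x$values[!x$failed]))
  invisible(x)
}

#' Partition an output sample set into its extreme tails
#'
#' Realizes the lower and upper probability-alpha tail sets of the
#' output distribution by empirical order statistics: L holds the
#' indices of the `round(alpha * N)` smallest values, U of the equally
#' many largest.  Ties at a threshold are resolved by ascending
#' original sample index (one deterministic, replayable rule), which
#' also guarantees L and U are disjoint whenever alpha <= 0.5.
#'
#' @param out a `cra_output` (or bare numeric vector).
#' @param alpha tail probability, `0 < alpha <= 0.5`, with
#'   `round(alpha * N) >= 1`.
#' @return object of class `cra_partition`: `alpha`, index vectors
#'   `lower_idx`, `upper_idx`, thresholds `a_L` (largest value in L)
#'   and `a_U` (smallest value in U), and `n_effective`.
#' @export
partition_output <- function(out, alpha) {
  v <- if (inherits(out, "cra_output")) out$values else out
  stopifnot(alpha > 0, alpha <= 0.5)
  ok <- which(!is.na(v))
  n_eff <- length(ok)
  n_tail <- round(alpha * n_eff)
  if (n_tail < 1)
    stop("alpha * N < 0.5: no samples in the tails")
  ord <- ok[order(v[ok], ok)]
  lower_idx <- ord[seq_len(n_tail)]
  upper_idx <- ord[seq.int(n_eff - n_tail + 1L, n_eff)]
  structure(list(alpha = alpha,
                 lower_idx = lower_idx, upper_idx = upper_idx,
                 a_L = v[lower_idx[n_tail]], a_U = v[upper_idx[1L]],
                 n_effective = n_eff),
            class = "cra_partition")
}

#' Interval subset of an output sample set
#'
#' Indices of samples with output strictly inside (a, b), together
#' with the empirical probability of the interval.
#' @param out a `cra_output` or numeric vector.
#' @param a,b interval bounds, `a < b`.
#' @return list with `indices` and `probability`.
#' @export
partition_interval <- function(out, a, b) {
  v <- if (inherits(out, "cra_output")) out$values else out
  stopifnot(a < b)
  ok <- which(!is.na(v))
  idx <- ok[v[ok] > a & v[ok] < b]
  list(indices = idx, probability = length(idx) / length(ok))
}

#' Tail-conditioned parameter subsets
#'
#' Aggregates the rows of the sample matrix whose outputs fell in the
#' upper / lower tail: P_U and P_L.
#' @param samples the `cra_samples` the outputs were computed from.
#' @param part a `cra_partition` built from the aligned outputs.
#' @return list with matrices `P_U` and `P_L` (row subsets).
#' @export
conditional_parameter_sets <- function(samples, part) {
  m <- if (inherits(samples, "cra_samples")) samples$samples else samples
  stopifnot(inherits(part, "cra_partition"))
  if (max(part$upper_idx, part$lower_idx) > nrow(m))
    stop("partition indices exceed the sample matrix: misaligned inputs")
  if (!length(part$upper_idx) || !length(part$lower_idx))
    stop("empty partition")
  list(P_U = m[part$upper_idx, , drop = FALSE],
       P_L = m[part$lower_idx, , drop = FALSE])
}

#' Gaussian kernel density on a fixed grid
#'
#' One-dimensional Gaussian-kernel estimate evaluated on a uniform grid
#' spanning the parameter's sampling bounds, so that densities from
#' different realizations and tails are directly comparable (and
#' integrable against each other).  The bandwidth follows Silverman's
#' rule of thumb with a positive floor of one grid cell, which keeps
#' degenerate (zero-variance) inputs well-defined.  Kernel mass falling
#' outside the bounds is not reflected back: the grid integral may
#' therefore fall below 1 for edge-concentrated samples.
#'
#' @param values numeric sample (>= 10 values; a warning is issued
#'   below 1000, the practical floor for a trustworthy tail-conditioned
#'   estimate).
#' @param bounds length-2 vector `c(lower, upper)` for the grid span.
#' @param grid_size number of grid points (default 1024).
#' @param name parameter name carried along for bookkeeping.
#' @param source which conditioning produced `values` (`"U"`, `"L"` or
#'   `"unconditional"`).
#' @return object of class `cra_density`: `parameter`, `x` (grid), `y`
#'   (density), `bw`, `source`.
#' @export
estimate_density <- function(values, bounds, grid_size = 1024,
                             name = "", source = "unconditional") {
  values <- values[!is.na(values)]
  if (length(values) < 10)
    stop("need at least 10 values for a density estimate")
  if (length(values) < 1000)
    warning("density estimated from ", length(values),
            " values; at least 1000 are recommended", call. = FALSE)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  floor_bw <- diff(bounds) / grid_size
  bw <- tryCatch(stats::bw.nrd0(values), error = function(e) 0)
  bw <- max(bw, floor_bw)
  d <- stats::density(values, bw = bw, kernel = "gaussian",
                      from = bounds[1], to = bounds[2], n = grid_size)
  structure(list(parameter = name, x = d$x, y = d$y, bw = bw,
                 source = source),
            class = "cra_density")
}

#' Moment-independent robustness indicator
#'
#' The L1 distance between a parameter's upper- and lower-tail
#' conditional densities,
#' \deqn{\mu_i = \int | f_{P_i|U}(p_i) - f_{P_i|L}(p_i) | \, dp_i,}
#' computed by the trapezoidal rule on the shared evaluation grid.
#' mu ranges from 0 (the tails do not constrain the parameter at all)
#' to 2 (completely separated conditional densities), is symmetric in
#' its arguments, and needs no moments of either density.
#'
#' @param fU,fL `cra_density` objects on the same grid.
#' @return scalar mu in \[0, 2\].
#' @export
miri <- function(fU, fL) {
  stopifnot(inherits(fU, "cra_density"), inherits(fL, "cra_density"))
  if (length(fU$x) != length(fL$x) ||
      any(abs(fU$x - fL$x) > 1e-12 * max(abs(fU$x))))
    stop("densities are on different grids")
  pracma::trapz(fU$x, abs(fU$y - fL$y))
}

#' Rank parameters by MIRI
#'
#' @param table a `miri_table` (see [cra_realization()]).
#' @param k how many top parameters to return (`k <= q`).
#' @return character vector of the k parameter names in descending-mu
#'   order; ties broken by parameter declaration order.
#' @export
rank_parameters <- function(table, k) {
  stopifnot(inherits(table, "miri_table"), k <= nrow(table))
  table$parameter[order(-table$miri, seq_len(nrow(table)))][seq_len(k)]
}

#' Monte-Carlo robustness estimate
#'
#' The robustness of a capability over a parameter space is the
#' prior-weighted integral of its evaluation function; under the
#' uniform sampling prior its Monte-Carlo estimate is simply the mean
#' of the output samples (failed samples masked).
#' @param out a `cra_output` or numeric vector.
#' @return scalar robustness estimate.
#' @export
kitano_robustness <- function(out) {
  v <- if (inherits(out, "cra_output")) out$values else out
  if (!length(v) || all(is.na(v))) stop("no output samples")
  mean(v, na.rm = TRUE)
}

#' One full MIRI realization
#'
#' Runs sampling, simulation, tail partitioning, conditional density
#' estimation and MIRI computation for one seed, for one or several
#' evaluation functions sharing the same simulations.
#'
#' @param model a [dynamical_model()] or fixture model.
#' @param space the `parameter_space` to sample.
#' @param fn evaluation function(s); `NULL` for fixtures.
#' @param N number of Latin hypercube samples.
#' @param alpha tail probability.
#' @param seed realization seed.
#' @param sim optional [sim_control()].
#' @param workers parallel workers for the simulation batch.
#' @param density_grid grid size for the conditional densities.
#' @return a `cra_realization`: list with `samples`, and per objective
#'   an entry holding `outputs`, `partition`, `densities` (per
#'   parameter: list of `U`/`L` `cra_density`) and `miri` (a
#'   `miri_table` data frame: parameter, miri, rank).
#' @export
cra_realization <- function(model, space, fn = NULL, N, alpha, seed,
                            sim = NULL, workers = 1L,
                            density_grid = 1024) {
  check_n_alpha(N, alpha)
  samples <- sample_l2hs(space, N, seed)
  outs <- evaluate_batch(model, samples, fn, sim = sim,
                         workers = workers)
  single <- inherits(outs, "cra_output")
  outs_list <- if (single) list(output = outs) else outs

  per_obj <- lapply(outs_list, function(out) {
    part <- partition_output(out, alpha)
    ps <- conditional_parameter_sets(samples, part)
    dens <- lapply(space$names, function(nm) {
      b <- c(space$lower[nm], space$upper[nm])
      list(U = estimate_density(ps$P_U[, nm], b, density_grid, nm, "U"),
           L = estimate_density(ps$P_L[, nm], b, density_grid, nm, "L"))
    })
    names(dens) <- space$names
    mu <- vapply(dens, function(d) miri(d$U, d$L), numeric(1))
    tab <- data.frame(parameter = space$names, miri = unname(mu))
    tab$rank <- rank(-tab$miri, ties.method = "first")
    attr(tab, "alpha") <- alpha
    attr(tab, "seed") <- seed
    class(tab) <- c("miri_table", "data.frame")
    list(outputs = out, partition = part, densities = dens, miri = tab)
  })

  structure(c(list(samples = samples, seed = seed, alpha = alpha),
              if (single) per_obj$output else list(objectives = per_obj)),
            class = "cra_realization")
}

check_n_alpha <- function(N, alpha) {
  stopifnot(N >= 2, alpha > 0, alpha <= 0.5)
  if (N < 1000 / alpha)
    warning(sprintf(
      "N = %d is below the recommended floor 1000/alpha = %.0f ", N,
      1000 / alpha),
      "for trustworthy tail-conditioned densities", call. = FALSE)
  invisible(TRUE)
}
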