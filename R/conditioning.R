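#' Select a conditioning set
#'
#' Picks the top-k MIRI-ranked parameters and fixes each at the mode
#' (grid argmax) of the tail-conditioned density matching the
#' objective: the upper-tail density when the objective is to maximize
#' the output, the lower-tail density when it is to minimize it.
#' Argmax ties resolve to the smallest grid value.
#'
#' @param densities per-parameter list of `U`/`L` `cra_density` pairs
#'   (as produced by [cra_realization()]).
#' @param ranking a `miri_table` or a character vector of parameter
#'   names already in descending-mu order.
#' @param k number of parameters to condition (`k = 0` gives an empty
#'   set; downstream analysis is then unconditional).
#' @param direction `"maximize"` or `"minimize"`.
#' @param objective objective label recorded with each entry.
#' @return object of class `conditioning_set`: a data frame with
#'   columns `parameter`, `value`, `source` (`"U"`/`"L"`),
#'   `objective`.
#' @export
select_conditioning_set <- function(densities, ranking, k,
                                    direction = c("maximize",
                                                  "minimize"),
                                    objective = "") {
  direction <- match.arg(direction)
  nms <- if (inherits(ranking, "miri_table"))
    rank_parameters(ranking, min(k, nrow(ranking))) else ranking
  if (k > length(nms) || k > length(densities))
    stop("k exceeds the number of ranked parameters")
  nms <- nms[seq_len(k)]
  src <- if (direction == "maximize") "U" else "L"
  vals <- vapply(nms, function(nm) {
    d <- densities[[nm]][[src]]
    if (is.null(d)) stop("no ", src, " density for ", nm)
    density_mode(d)
  }, numeric(1))
  new_conditioning_set(nms, vals, rep(src, k), rep(objective, k))
}

density_mode <- function(d) d$x[which.max(d$y)]

new_conditioning_set <- function(parameter, value, source, objective) {
  df <- data.frame(parameter = as.character(parameter),
                   value = as.numeric(value),
                   source = as.character(source),
                   objective = as.character(objective),
                   stringsAsFactors = FALSE)
  class(df) <- c("conditioning_set", "data.frame")
  df
}

#' Conditional re-analysis under a conditioning set
#'
#' Re-samples the parameter space with the conditioning set's
#' dimensions pinned to their fixed values — a fresh Latin hypercube
#' over the free dimensions, pinned columns exactly constant — then
#' re-evaluates the model, yielding samples of the conditional output
#' density together with its summary statistics.
#'
#' @param model model to simulate.
#' @param space full `parameter_space` (conditioned dimensions
#'   included).
#' @param K a `conditioning_set` (possibly empty).
#' @param fn evaluation function (`NULL` for fixtures).
#' @param N number of fresh samples.
#' @param seed sampling seed.
#' @param sim optional [sim_control()].
#' @param workers parallel workers.
#' @return list with `samples`, `outputs` (a `cra_output`) and `stats`
#'   (a [density_stats()] result).
#' @export
conditional_analysis <- function(model, space, K, fn = NULL, N, seed,
                                 sim = NULL, workers = 1L) {
  stopifnot(inherits(space, "parameter_space"))
  pin <- if (is.null(K) || nrow(K) == 0) character() else K$parameter
  if (!all(pin %in% space$names))
    stop("conditioning parameters not in the space: ",
         paste(setdiff(pin, space$names), collapse = ", "))
  if (length(pin)) {
    lo <- space$lower[pin]; hi <- space$upper[pin]
    bad <- K$value < lo | K$value > hi
    if (any(bad))
      stop("fixed values outside bounds: ",
           paste(pin[bad], collapse = ", "))
  }

  free <- setdiff(space$names, pin)
  if (length(free)) {
    sub <- new_parameter_space(free, space$nominal[free],
                               space$lower[free], space$upper[free],
                               space$scale[free])
    draw <- sample_l2hs(sub, N, seed)
    m <- matrix(NA_real_, N, length(space$names),
                dimnames = list(NULL, space$names))
    m[, free] <- draw$samples
  } else {
    m <- matrix(NA_real_, N, length(space$names),
                dimnames = list(NULL, space$names))
  }
  for (j in seq_along(pin)) m[, pin[j]] <- K$value[j]
  samples <- structure(list(samples = m, seed = as.integer(seed),
                            method = "l2hs-conditional", space = space),
                       class = "cra_samples")
  out <- evaluate_batch(model, samples, fn, sim = sim,
                        workers = workers)
  list(samples = samples, outputs = out, stats = density_stats(out))
}

#' Summary statistics of an output density
#'
#' Sample mean, unbiased sample variance and the mode of the Gaussian
#' kernel density estimate (grid argmax over the observed output
#' range).
#' @param out a `cra_output` or numeric vector (>= 10 values).
#' @param grid_size KDE grid size.
#' @return list of class `density_stats` with `mean`, `variance`,
#'   `mode`.
#' @export
density_stats <- function(out, grid_size = 1024) {
  v <- if (inherits(out, "cra_output")) out$values else out
  v <- v[!is.na(v)]
  if (length(v) < 10) stop("need at least 10 samples")
  rng <- range(v)
  mode <- if (rng[1] == rng[2]) rng[1] else
    density_mode(suppressWarnings(
      estimate_density(v, rng, grid_size, source = "unconditional")))
  structure(list(mean = mean(v), variance = stats::var(v), mode = mode),
            class = "density_stats")
}

#' @export
print.density_stats <- function(x, ...) {
  cat(sprintf("mean %.6g  variance %.6g  mode %.6g\n",
              x$mean, x$variance, x$mode))
  invisible(x)
}

#' Multi-objective conditioning set
#'
#' Builds one conditioning entry per objective: each objective
#' contributes its top-MIRI parameter not already claimed by an earlier
#' objective (objectives are visited in priority order), fixed at the
#' mode of the tail density matching that objective's direction.
#'
#' @param miri_tables named list of `miri_table`s, one per objective.
#' @param densities_list named list (same names) of per-parameter
#'   density pairs, as in [cra_realization()].
#' @param directions named character vector: `"maximize"` /
#'   `"minimize"` per objective.
#' @param priority objective evaluation order (default: declaration
#'   order of `miri_tables`).
#' @return a `conditioning_set` with one row per objective.
#' @export
multiobjective_select <- function(miri_tables, densities_list,
                                  directions,
                                  priority = names(miri_tables)) {
  stopifnot(length(miri_tables) >= 1,
            setequal(names(miri_tables), priority))
  q <- nrow(miri_tables[[1]])
  if (length(priority) > q)
    stop("more objectives than parameters")
  taken <- character()
  rows <- lapply(priority, function(obj) {
    ranked <- rank_parameters(miri_tables[[obj]], q)
    pick <- setdiff(ranked, taken)[1]
    taken <<- c(taken, pick)
    dir <- match.arg(directions[[obj]], c("maximize", "minimize"))
    src <- if (dir == "maximize") "U" else "L"
    new_conditioning_set(pick,
                         density_mode(densities_list[[obj]][[pick]][[src]]),
                         src, obj)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conditioning_set", "data.frame")
  out
}

#' Replicate the MIRI analysis across realizations
#'
#' Repeats the full sampling-to-MIRI pipeline `n_realizations` times
#' with seeds `base_seed + 1, ..., base_seed + n`, and aggregates each
#' parameter's mu values into box-plot statistics (median, quartiles,
#' 1.5 IQR whiskers, outlier count).  Realizations are independent, so
#' the result does not depend on execution order or worker count.
#'
#' @inheritParams cra_realization
#' @param n_realizations number of replicates (>= 2).
#' @param base_seed seeds are derived as `base_seed + r`.
#' @param workers forked workers used across realizations.
#' @return object of class `realization_summary`: list with `mu`
#'   (n x q matrix of MIRI values; for multiple objectives a named
#'   list of such matrices), `summary` (data frame: objective,
#'   parameter, q1, median, q3, whisker_lo, whisker_hi, n_outliers)
#'   and `long` (realization, objective, parameter, miri).
#' @export
repeat_realizations <- function(model, space, fn = NULL, N, alpha,
                                n_realizations, base_seed = 0L,
                                sim = NULL, workers = 1L,
                                density_grid = 1024) {
  stopifnot(n_realizations >= 2)
  seeds <- base_seed + seq_len(n_realizations)
  run_one <- function(seed) {
    r <- cra_realization(model, space, fn, N, alpha, seed, sim = sim,
                         density_grid = density_grid)
    if (!is.null(r$miri)) list(default = r$miri)
    else lapply(r$objectives, `[[`, "miri")
  }
  res <- if (workers > 1L)
    parallel::mclapply(seeds, run_one, mc.cores = workers)
  else lapply(seeds, run_one)

  objectives <- names(res[[1]])
  mu <- lapply(objectives, function(obj)
    do.call(rbind, lapply(res, function(r)
      stats::setNames(r[[obj]]$miri, r[[obj]]$parameter))))
  names(mu) <- objectives

  long <- do.call(rbind, lapply(seq_along(res), function(r)
    do.call(rbind, lapply(objectives, function(obj)
      data.frame(realization = r, objective = obj,
                 parameter = res[[r]][[obj]]$parameter,
                 miri = res[[r]][[obj]]$miri)))))

  summ <- do.call(rbind, lapply(objectives, function(obj)
    do.call(rbind, lapply(colnames(mu[[obj]]), function(p) {
      v <- mu[[obj]][, p]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- qs[3] - qs[1]
      wlo <- min(v[v >= qs[1] - 1.5 * iqr])
      whi <- max(v[v <= qs[3] + 1.5 * iqr])
      data.frame(objective = obj, parameter = p, q1 = qs[1],
                 median = qs[2], q3 = qs[3], whisker_lo = wlo,
                 whisker_hi = whi,
                 n_outliers = sum(v < wlo | v > whi))
    }))))

  structure(list(mu = if (length(mu) == 1L) mu[[1]] else mu,
                 summary = summ, long = long, seeds = seeds,
                 alpha = alpha, N = N),
            class = "realization_summary")
}

#' Median-MIRI ranking across realizations
#' @param rs a `realization_summary`.
#' @param k top-k to return.
#' @param objective objective name (when several were analysed).
#' @return character vector of k parameter names by descending median
#'   mu.
#' @export
median_ranking <- function(rs, k, objective = NULL) {
  s <- rs$summary
  if (!is.null(objective)) s <- s[s$objective == objective, ]
  s$parameter[order(-s$median)][seq_len(k)]
}
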