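#' Run the full conditional robustness pipeline
#'
#' Executes the six-step analysis end to end: Latin hypercube sampling
#' of the parameter space, simulation of every sample, partitioning of
#' each objective's output distribution into its alpha tails,
#' conditional density estimation, MIRI ranking, and conditioning-set
#' selection — followed by a conditional re-analysis with the selected
#' parameters pinned.  When `n_realizations > 1`, the MIRI stage is
#' replicated across seeds and the conditioning set is selected on the
#' first realization's densities while the ranking uses the
#' median MIRI across realizations.
#'
#' When `outdir` is set, writes: `samples.csv` (first realization's
#' draw), `outputs.csv`, `miri.csv` (long format over realizations),
#' `conditioning.json`, `stats.json` (unconditional and conditional
#' density statistics side by side) and `manifest.json` (seeds,
#' configuration echo, software versions, effective sample counts).
#' Identical configuration and base seed reproduce identical artifacts.
#'
#' @param config a [cra_config()].
#' @return (invisibly) a result bundle: list with `realizations`
#'   summary, `miri`, `ranking`, `conditioning`, `unconditional` and
#'   `conditional` stats per objective.
#' @export
run_cra <- function(config) {
  stopifnot(inherits(config, "cra_config"))
  parts <- build_from_config(config)
  model <- parts$model; space <- parts$space; fn <- parts$fn
  sim <- model_sim(model, config)

  stage <- "sampling/simulation"
  bundle <- tryCatch({
    first <- cra_realization(model, space, fn, config$N, config$alpha,
                             seed = config$base_seed + 1L, sim = sim,
                             workers = config$workers)
    objs <- realization_objectives(first)

    stage <- "realization replication"
    rs <- NULL
    if (config$n_realizations > 1) {
      rs <- repeat_realizations(model, space, fn, config$N,
                                config$alpha, config$n_realizations,
                                base_seed = config$base_seed,
                                sim = sim, workers = config$workers)
    }

    stage <- "conditioning"
    per_obj <- lapply(names(objs), function(nm) {
      o <- objs[[nm]]
      dir <- objective_direction(model, fn, nm)
      ranking <- if (is.null(rs)) rank_parameters(o$miri, config$k)
                 else median_ranking(rs, config$k,
                                     objective = if (length(objs) > 1)
                                       nm else NULL)
      K <- select_conditioning_set(o$densities, ranking, config$k,
                                   direction = dir, objective = nm)
      cond <- conditional_analysis(model, space, K,
                                   fn = if (is.null(fn)) NULL
                                        else fn[[nm]],
                                   N = config$N,
                                   seed = config$base_seed + 1L,
                                   sim = sim,
                                   workers = config$workers)
      list(objective = nm, miri = o$miri, ranking = ranking,
           conditioning = K,
           unconditional = density_stats(o$outputs),
           conditional = cond$stats,
           n_effective = o$outputs$n_effective)
    })
    names(per_obj) <- names(objs)
    list(first = first, realizations = rs, per_objective = per_obj)
  }, error = function(e) {
    stop("CRA stage `", stage, "` failed (base seed ",
         config$base_seed, "): ", conditionMessage(e), call. = FALSE)
  })

  if (!is.null(config$outdir))
    write_cra_artifacts(bundle, config)
  invisible(bundle)
}

model_sim <- function(model, config) {
  if (inherits(model, "fixture_model")) return(NULL)
  s <- model$default_sim
  sim_control(horizon = config$horizon %||% s$horizon,
              grid_size = config$grid_size %||% s$grid_size,
              rtol = config$rtol %||% s$rtol,
              atol = config$atol %||% s$atol,
              clamp_tol = s$clamp_tol)
}

realization_objectives <- function(r) {
  if (!is.null(r$miri))
    list(output = list(outputs = r$outputs, partition = r$partition,
                       densities = r$densities, miri = r$miri))
  else r$objectives
}

objective_direction <- function(model, fn, nm) {
  if (inherits(model, "fixture_model")) return("maximize")
  if (inherits(fn, "evaluation_function")) fn$direction
  else fn[[nm]]$direction
}

write_cra_artifacts <- function(bundle, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)

  write_samples_csv(bundle$first$samples, p("samples.csv"))

  objs <- realization_objectives(bundle$first)
  outdf <- data.frame(sample = seq_along(objs[[1]]$outputs$values))
  for (nm in names(objs)) outdf[[nm]] <- objs[[nm]]$outputs$values
  utils::write.csv(outdf, p("outputs.csv"), row.names = FALSE)

  miri_long <- if (!is.null(bundle$realizations))
    bundle$realizations$long
  else do.call(rbind, lapply(names(objs), function(nm)
    data.frame(realization = 1L, objective = nm,
               parameter = objs[[nm]]$miri$parameter,
               miri = objs[[nm]]$miri$miri)))
  utils::write.csv(miri_long, p("miri.csv"), row.names = FALSE)

  cond <- do.call(rbind, lapply(bundle$per_objective,
                                function(o) o$conditioning))
  jsonlite::write_json(cond, p("conditioning.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)

  stats <- lapply(bundle$per_objective, function(o)
    list(unconditional = unclass(o$unconditional),
         conditional = unclass(o$conditional),
         n_effective = o$n_effective,
         ranking = o$ranking))
  jsonlite::write_json(stats, p("stats.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("condrob")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    base_seed = config$base_seed,
    realization_seeds = config$base_seed +
      seq_len(config$n_realizations),
    N = config$N, alpha = config$alpha, k = config$k,
    n_realizations = config$n_realizations,
    model = if (is.character(config$model)) config$model
            else config$model$name,
    lower_factor = config$lower_factor,
    upper_factor = config$upper_factor,
    n_effective = as.list(vapply(bundle$per_objective, function(o)
      o$n_effective, numeric(1))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$outdir)
}
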