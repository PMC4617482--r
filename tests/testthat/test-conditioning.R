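test_that("conditioning values are the modes of the matching tail density", {
  pair <- gaussian_density_pair(2, -2, sigma = 0.5, span = 10)
  dens <- list(p1 = pair)
  K_up <- select_conditioning_set(dens, "p1", 1, "maximize")
  K_lo <- select_conditioning_set(dens, "p1", 1, "minimize")
  expect_equal(K_up$value, 2, tolerance = 0.01)
  expect_equal(K_lo$value, -2, tolerance = 0.01)
  expect_identical(K_up$source, "U")
  expect_identical(K_lo$source, "L")
})

test_that("an empty conditioning set is legal and leaves the analysis unconditional", {
  fx <- make_identity_fixture(2)
  r <- quiet(cra_realization(fx, fx$space, N = 2000, alpha = 0.1,
                             seed = 41))
  K0 <- select_conditioning_set(r$densities, r$miri, 0, "maximize")
  expect_identical(nrow(K0), 0L)
  cond <- conditional_analysis(fx, fx$space, K0, N = 2000, seed = 43)
  ks <- suppressWarnings(stats::ks.test(cond$outputs$values,
                                        r$outputs$values))
  expect_gt(ks$p.value, 0.01)
})

test_that("conditioning the driving parameter shifts the conditional mean", {
  fx <- make_identity_fixture(3)
  r <- quiet(cra_realization(fx, fx$space, N = 3000, alpha = 0.1,
                             seed = 47))
  K <- select_conditioning_set(r$densities, r$miri, 1, "maximize")
  expect_identical(K$parameter, "p1")
  cond <- conditional_analysis(fx, fx$space, K, N = 1000, seed = 49)
  expect_gt(cond$stats$mean, kitano_robustness(r$outputs))
  expect_gt(cond$stats$mean, 0.9)  # top decile of [0, 1]
  # pinned column is exactly constant
  expect_identical(unique(cond$samples$samples[, "p1"]), K$value)
  K_bad <- structure(
    data.frame(parameter = "p1", value = 5, source = "U",
               objective = "", stringsAsFactors = FALSE),
    class = c("conditioning_set", "data.frame"))
  expect_error(conditional_analysis(fx, fx$space, K_bad,
                                    N = 100, seed = 1),
               "outside bounds")
})

test_that("direction soundness on a monotone fixture", {
  fx <- make_linear_fixture(c(p1 = 1, p2 = 0.3, p3 = 0))
  r <- quiet(cra_realization(fx, fx$space, N = 3000, alpha = 0.1,
                             seed = 53))
  base <- kitano_robustness(r$outputs)

  up1 <- conditional_analysis(fx, fx$space,
    select_conditioning_set(r$densities, r$miri, 1, "maximize"),
    N = 1500, seed = 55)
  lo1 <- conditional_analysis(fx, fx$space,
    select_conditioning_set(r$densities, r$miri, 1, "minimize"),
    N = 1500, seed = 55)
  up2 <- conditional_analysis(fx, fx$space,
    select_conditioning_set(r$densities, r$miri, 2, "maximize"),
    N = 1500, seed = 55)

  expect_gt(up1$stats$mean, base)
  expect_lt(lo1$stats$mean, base)
  # conditioning more top-ranked parameters moves the mean further
  expect_gt(up2$stats$mean, up1$stats$mean)
})

test_that("density statistics report mean, variance and KDE mode", {
  s <- density_stats(rep(3, 25))
  expect_equal(unclass(s)[c("mean", "variance", "mode")],
               list(mean = 3, variance = 0, mode = 3))

  set.seed(59)
  x <- rnorm(50000, mean = 5, sd = 2)
  st <- density_stats(x)
  expect_equal(st$mean, 5, tolerance = 0.05)
  expect_equal(st$variance, 4, tolerance = 0.05)
  expect_equal(st$mode, 5, tolerance = 0.05 * 5 / 5)
  expect_gte(st$mode, min(x))
  expect_lte(st$mode, max(x))
  expect_error(density_stats(1:5), "at least 10")
})

test_that("multi-objective selection takes one parameter per objective", {
  mk_tab <- function(mu) {
    tab <- data.frame(parameter = c("a", "b", "c"), miri = mu)
    tab$rank <- rank(-tab$miri, ties.method = "first")
    class(tab) <- c("miri_table", "data.frame")
    tab
  }
  mk_dens <- function(modes) {
    lapply(modes, function(m) gaussian_density_pair(m, -m, span = 12))
  }
  tabs <- list(o1 = mk_tab(c(2, 1, 0.1)), o2 = mk_tab(c(1.8, 1.5, 0.2)))
  dens <- list(o1 = mk_dens(c(a = 1, b = 2, c = 3)),
               o2 = mk_dens(c(a = 1, b = 2, c = 3)))
  dirs <- c(o1 = "maximize", o2 = "minimize")

  K <- multiobjective_select(tabs, dens, dirs)
  # o1 takes its top parameter a; o2's top is also a, so it falls
  # back to its next-ranked b
  expect_identical(K$parameter, c("a", "b"))
  expect_identical(K$source, c("U", "L"))
  expect_equal(K$value, c(1, -2), tolerance = 0.02)

  # single objective degenerates to plain top-1 selection
  K1 <- multiobjective_select(tabs["o1"], dens["o1"],
                              dirs["o1"])
  expect_identical(K1$parameter, "a")
  expect_error(
    multiobjective_select(c(tabs, list(o3 = tabs$o1, o4 = tabs$o1)),
                          c(dens, list(o3 = dens$o1, o4 = dens$o1)),
                          c(dirs, o3 = "maximize", o4 = "maximize")),
    "more objectives")
})

test_that("replicated realizations aggregate into ordered box statistics", {
  fx <- make_identity_fixture(3)
  rs <- quiet(repeat_realizations(fx, fx$space, N = 1200, alpha = 0.1,
                                  n_realizations = 4, base_seed = 60))
  expect_identical(dim(rs$mu), c(4L, 3L))
  expect_true(all(rs$summary$q1 <= rs$summary$median &
                    rs$summary$median <= rs$summary$q3))
  expect_identical(median_ranking(rs, 1), "p1")
  expect_identical(sort(unique(rs$long$realization)), 1:4)

  # equal seeds give equal MIRI vectors (replication is deterministic)
  r1 <- quiet(cra_realization(fx, fx$space, N = 1200, alpha = 0.1,
                              seed = 61))
  expect_identical(rs$mu[1, ], stats::setNames(r1$miri$miri,
                                               r1$miri$parameter))
})
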