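test_that("tail partition picks the extreme order statistics", {
  part <- partition_output(c(3, 1, 4, 1.5, 9, 2.6, 5, 8, 7, 10),
                           alpha = 0.2)
  expect_setequal(part$lower_idx, c(2, 4))   # values 1, 1.5
  expect_setequal(part$upper_idx, c(5, 10))  # values 9, 10
  expect_equal(part$a_L, 1.5)
  expect_equal(part$a_U, 9)
})

test_that("threshold ties resolve by ascending index and keep L, U disjoint", {
  part <- partition_output(rep(5, 10), alpha = 0.1)
  expect_identical(part$lower_idx, 1L)
  expect_identical(part$upper_idx, 10L)
  expect_length(intersect(part$lower_idx, part$upper_idx), 0)

  # |L| = |U| = round(alpha * N) across sizes
  for (N in c(100, 999, 5000)) {
    v <- seq_len(N)
    p <- partition_output(v, 0.1)
    expect_length(p$lower_idx, round(0.1 * N))
    expect_length(p$upper_idx, round(0.1 * N))
  }
  expect_error(partition_output(1:3, 0.1), "tails")
  expect_error(partition_output(1:10, 0.6))
})

test_that("failed samples are masked out of the partition", {
  v <- c(1:8, NA, NA)
  part <- partition_output(v, 0.25)
  expect_equal(part$n_effective, 8)
  expect_setequal(part$lower_idx, 1:2)
  expect_setequal(part$upper_idx, 7:8)
})

test_that("interval subsets count samples and empirical probability", {
  res <- partition_interval(1:10, 2.5, 4.5)
  expect_setequal(res$indices, 3:4)
  expect_equal(res$probability, 0.2)
  expect_equal(partition_interval(1:10, 0, 11)$probability, 1)

  set.seed(31)
  z <- rnorm(10000)
  p <- partition_interval(z, -1, 1)$probability
  expect_equal(p, 2 * pnorm(1) - 1, tolerance = 0.02 / 0.68)
})

test_that("conditional parameter sets are the aligned row subsets", {
  fx <- make_identity_fixture(3)
  s <- sample_l2hs(fx$space, 500, 13)
  out <- evaluate_batch(fx, s)
  part <- partition_output(out, 0.1)
  ps <- conditional_parameter_sets(s, part)
  expect_identical(nrow(ps$P_U), 50L)
  expect_identical(nrow(ps$P_L), 50L)
  # brute-force oracle: z = p1, so P_L rows carry the 50 smallest p1
  expect_setequal(ps$P_L[, "p1"],
                  sort(s$samples[, "p1"])[1:50])
  expect_setequal(ps$P_U[, "p1"],
                  sort(s$samples[, "p1"], decreasing = TRUE)[1:50])
  expect_lt(max(ps$P_L[, "p1"]), 0.12)
  expect_gt(min(ps$P_U[, "p1"]), 0.88)
  expect_length(intersect(part$lower_idx, part$upper_idx), 0)
  expect_error(conditional_parameter_sets(s$samples[1:10, ], part),
               "misaligned")
})

test_that("kernel density estimates recover analytic densities", {
  set.seed(17)
  x <- rnorm(10000)
  d <- estimate_density(x, c(-6, 6))
  at0 <- d$y[which.min(abs(d$x))]
  expect_equal(at0, dnorm(0), tolerance = 0.05)
  expect_true(all(d$y >= 0))
  # unit mass up to boundary leakage and trapezoid quadrature error
  expect_lte(pracma::trapz(d$x, d$y), 1 + 1e-3)
  expect_gte(pracma::trapz(d$x, d$y), 0.95)

  u <- runif(10000)
  du <- estimate_density(u, c(0, 1))
  interior <- du$x >= 0.2 & du$x <= 0.8
  expect_equal(mean(du$y[interior]), 1, tolerance = 0.1)
})

test_that("degenerate density inputs fall back to the bandwidth floor", {
  d <- quiet(estimate_density(rep(2, 100), c(0, 4)))
  expect_true(is.finite(d$bw) && d$bw > 0)
  expect_equal(d$x[which.max(d$y)], 2, tolerance = 0.01)
  expect_error(estimate_density(1:5, c(0, 10)), "at least 10")
})

test_that("MIRI matches the closed-form L1 distance of shifted normals", {
  pair0 <- gaussian_density_pair(0, 0)
  expect_equal(miri(pair0$U, pair0$L), 0)

  pair3 <- gaussian_density_pair(0, 3)
  expect_equal(miri(pair3$U, pair3$L), 2 * (2 * pnorm(1.5) - 1),
               tolerance = 1e-3 / 1.73)
  # symmetry
  expect_equal(miri(pair3$U, pair3$L), miri(pair3$L, pair3$U))

  # KDE route: near-disjoint supports approach the upper bound of 2
  set.seed(5)
  a <- quiet(estimate_density(runif(5000, 0, 0.3), c(0, 10)))
  b <- quiet(estimate_density(runif(5000, 9, 9.7), c(0, 10)))
  expect_gte(miri(a, b), 1.9)

  bad <- gaussian_density_pair(0, 3, grid_size = 512)
  expect_error(miri(pair3$U, bad$L), "different grids")
})

test_that("parameters rank by descending MIRI with declaration-order ties", {
  tab <- data.frame(parameter = c("a", "b", "c"),
                    miri = c(0.1, 1.9, 0.5))
  tab$rank <- rank(-tab$miri, ties.method = "first")
  class(tab) <- c("miri_table", "data.frame")
  expect_identical(rank_parameters(tab, 2), c("b", "c"))

  tied <- data.frame(parameter = c("a", "b", "c"),
                     miri = c(1, 1, 0.2))
  tied$rank <- rank(-tied$miri, ties.method = "first")
  class(tied) <- c("miri_table", "data.frame")
  expect_identical(rank_parameters(tied, 2), c("a", "b"))
})

test_that("robustness estimate is the masked sample mean", {
  expect_equal(kitano_robustness(rep(4.2, 50)), 4.2)
  fx <- make_identity_fixture(2)
  s <- sample_l2hs(fx$space, 4000, 19)
  out <- evaluate_batch(fx, s)
  expect_equal(kitano_robustness(out), 0.5,
               tolerance = 3 / sqrt(4000) / 0.5)
  # invariant to row permutation
  set.seed(1)
  expect_equal(kitano_robustness(sample(out$values)),
               kitano_robustness(out))
})

test_that("batch evaluation routes sample columns and masks failures", {
  fx <- make_identity_fixture(3, driving_index = 1)
  s <- sample_l2hs(fx$space, 200, 23)
  out <- evaluate_batch(fx, s)
  expect_identical(out$values, s$samples[, 1])

  # a <5% failure rate is masked with a message, never dropped
  fm <- fragile_model(threshold = 0.99)
  m <- matrix(c(runif(30, 0, 0.9), 0.999), ncol = 1,
              dimnames = list(NULL, "p1"))
  fn1 <- evaluation_function("maximum", "x")
  expect_message(out2 <- evaluate_batch(fm, m, fn1), "masked")
  expect_equal(out2$n_effective, 30)
  expect_true(is.na(out2$values[31]))

  # >= 5% failures abort with a diagnostic
  mbad <- matrix(seq(0.05, 1, length.out = 20), ncol = 1,
                 dimnames = list(NULL, "p1"))
  expect_error(evaluate_batch(fragile_model(0.5), mbad, fn1),
               "ill-posed")

  expect_error(evaluate_batch(pulse_generator_model(),
                              s, pulse_objectives()$area),
               "lack parameter columns")
})

test_that("batch results are identical across worker counts", {
  m <- pulse_generator_model()
  s <- sample_l2hs(pulse_parameter_space(), 24, 29)
  fn <- pulse_objectives()$area
  o1 <- evaluate_batch(m, s, fn, workers = 1)
  o2 <- evaluate_batch(m, s, fn, workers = 2)
  expect_identical(o1$values, o2$values)
})

test_that("a full realization wires partition, densities and MIRI together", {
  fx <- make_identity_fixture(3)
  r <- quiet(cra_realization(fx, fx$space, N = 800, alpha = 0.1,
                             seed = 37))
  expect_s3_class(r$miri, "miri_table")
  expect_true(all(r$miri$miri >= 0 & r$miri$miri <= 2))
  expect_identical(rank_parameters(r$miri, 1), "p1")
  expect_named(r$densities, c("p1", "p2", "p3"))
  expect_identical(r$densities$p1$U$source, "U")
})

test_that("undersampled configurations trigger the 1000/alpha warning", {
  expect_warning(check_n_alpha(500, 0.1), "1000/alpha")
  expect_silent(check_n_alpha(10000, 0.1))
})
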