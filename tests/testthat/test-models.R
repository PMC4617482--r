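test_that("pulse circuit rests at zero without stimulation", {
  m <- pulse_generator_model(input_amplitude = 0)
  tr <- integrate_model(m, pulse_nominal_parameters(),
                        sim = sim_control(horizon = 100,
                                          grid_size = 51))
  expect_true(all(tr$states == 0))
})

test_that("sustained stimulation drives R2 to its closed-form fixed point", {
  # under constant S1 the repressor equation is linear:
  # R2_ss = k1 * H / lambda2 with H = (470/K1)^3 / (1 + (470/K1)^3)
  m <- pulse_generator_model(input_duration = 2001)
  p <- pulse_nominal_parameters()
  tr <- integrate_model(m, p, sim = sim_control(horizon = 2000,
                                                grid_size = 201))
  H <- 470^3 / (1 + 470^3)
  r2_ss <- p[["k1"]] * H / p[["lambda2"]]
  expect_equal(tail(tr$states[, "R2"], 1)[[1]], r2_ss,
               tolerance = 1e-4)
  expect_equal(r2_ss, 500, tolerance = 1e-3)
})

test_that("rectangular stimulus yields a single interior pulse of Y", {
  m <- pulse_generator_model()
  tr <- integrate_model(m, pulse_nominal_parameters())
  y <- tr$states[, "Y"]
  i <- which.max(y)
  expect_gt(i, 1)
  expect_lt(i, length(y))
  # rises before the peak, decays to (almost) nothing afterwards
  expect_true(all(diff(y[1:i]) >= 0))
  expect_lt(tail(y, 1), 0.01 * max(y))
})

test_that("integrator matches analytic exponential decay", {
  tr <- integrate_model(decay_model(), c(r = 1))
  expect_equal(tail(tr$states[, "x"], 1)[[1]], exp(-10),
               tolerance = 1e-6)
})

test_that("grid_size = 2 returns exactly the start and end points", {
  tr <- integrate_model(decay_model(), c(r = 1),
                        sim = sim_control(horizon = 10, grid_size = 2))
  expect_identical(tr$times, c(0, 10))
  expect_identical(nrow(tr$states), 2L)
})

test_that("evaluation functions score traces as defined", {
  tr <- make_traj(seq(0, 8, by = 0.5), rep(3, 17))
  expect_equal(evaluate(tr, evaluation_function("area", "Y")), 3 * 8)
  expect_equal(evaluate(tr, evaluation_function("maximum", "Y")), 3)
  # all-constant trace: first grid index achieving the maximum is t=0
  expect_equal(evaluate(tr, evaluation_function("time_to_maximum",
                                                "Y")), 0)

  tt <- seq(0, 10, length.out = 2001)
  tr2 <- make_traj(tt, exp(-tt))
  expect_equal(evaluate(tr2, evaluation_function("area", "Y")),
               1 - exp(-10), tolerance = 1e-4)
  expect_error(evaluate(tr2, evaluation_function("area", "Z")),
               "not in trajectory")
})

test_that("time-to-maximum conditioning values give a fast pulse", {
  p <- pulse_nominal_parameters()
  p[c("k1", "K2", "lambda")] <- c(43.4827, 40.0512, 0.3360)
  m <- pulse_generator_model()
  tr <- integrate_model(m, p, sim = sim_control(horizon = 500,
                                                grid_size = 5001))
  tmax <- evaluate(tr, evaluation_function("time_to_maximum", "Y"))
  expect_equal(tmax, 1.5, tolerance = 0.5 / 1.5)
})

test_that("area and maximum are stable under grid refinement", {
  m <- pulse_generator_model()
  p <- pulse_nominal_parameters()
  a <- evaluation_function("area", "Y")
  mx <- evaluation_function("maximum", "Y")
  t1 <- integrate_model(m, p, sim = sim_control(500, 1001))
  t2 <- integrate_model(m, p, sim = sim_control(500, 2001))
  expect_lt(abs(evaluate(t1, a) - evaluate(t2, a)) / evaluate(t2, a),
            0.005)
  expect_lt(abs(evaluate(t1, mx) - evaluate(t2, mx)) /
              evaluate(t2, mx), 0.005)
})

test_that("EGFR cascade: zero input is an equilibrium, receptors start it", {
  e <- egfr_igf1r_model(initial_receptors = c(0, 0),
                        inputs = c(0, 0, 0))
  tr <- integrate_model(e, attr(e, "nominal"))
  expect_true(all(tr$states == 0))

  e2 <- egfr_igf1r_model(initial_receptors = c(1, 0))
  tr2 <- integrate_model(e2, attr(e2, "nominal"))
  x1 <- tr2$states[, "x1"]
  expect_true(all(diff(x1) < 0))            # receptor decays
  expect_gt(tr2$states[10, "x3"], 0)        # cascade activates
})

test_that("EGFR constructor validates its inputs", {
  expect_error(egfr_igf1r_model(parameter_values = rep(1, 38)), "39")
  expect_error(egfr_igf1r_model(totals = rep(1, 7)), "8 totals")
  expect_error(egfr_igf1r_model(inputs = c(-1, 1, 1)), ">= 0")
  expect_error(egfr_igf1r_model(parameter_values = c(-1, rep(1, 38))),
               "> 0")
})

test_that("EGFR states respect conservation bounds across random draws", {
  e <- egfr_igf1r_model()
  nom <- attr(e, "nominal")
  set.seed(7)
  for (i in 1:30) {
    p <- nom * runif(39, 0.1, 10)
    tr <- integrate_model(e, p)
    if (is.null(tr)) next   # failed integrations are flagged upstream
    expect_true(all(tr$states[, 3:10] <= 1 + 1e-4))
    expect_true(all(tr$states >= 0))
  }
})

test_that("integration is deterministic", {
  m <- pulse_generator_model()
  p <- pulse_nominal_parameters()
  t1 <- integrate_model(m, p)
  t2 <- integrate_model(m, p)
  expect_identical(t1$states, t2$states)
})
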