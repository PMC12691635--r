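# Closed-form structural models against independent numerical oracles.

test_that("one-compartment closed form agrees with the ODE oracle", {
  skip_if_not_installed("deSolve")
  # the reference typical subject, checked at infusion end and at 3 weeks
  expect_equal(concentration_at(c(V = 17.9, CL = 0.036),
                                dose_event(1500, 0, 0.5), c(0.5, 504)),
               ode_conc(17.9, 0.036, 1500, 0.5, c(0.5, 504)),
               tolerance = 1e-6)
  expect_equal(concentration_at(c(V = 17.9, CL = 0.036),
                                dose_event(1500, 0, 0.5), 0.5),
               83.8, tolerance = 1e-3)
  set.seed(11)
  for (r in 1:100) {
    V <- runif(1, 5, 60); CL <- runif(1, 0.01, 2)
    dur <- runif(1, 0.25, 4); t <- runif(1, 0, 800)
    got <- concentration_at(c(V = V, CL = CL), dose_event(1500, 0, dur), t)
    ref <- ode_conc(V, CL, 1500, dur, t)
    if (ref > 1e-8) expect_lt(abs(got / ref - 1), 1e-3)
  }
})

test_that("two-compartment closed form agrees with the ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(12)
  for (r in 1:25) {
    p <- c(V = runif(1, 5, 30), CL = runif(1, 0.05, 2),
           Q = runif(1, 0.5, 10), V2 = runif(1, 10, 80))
    dur <- runif(1, 0.5, 2); t <- runif(1, 0.1, 400)
    got <- concentration_at(p, dose_event(1000, 0, dur), t,
                            model = two_compartment())
    ref <- ode_conc2(p[1], p[2], p[3], p[4], 1000, dur, t)
    if (ref > 1e-8) expect_lt(abs(got / ref - 1), 1e-3)
  }
})

test_that("no drug gives zero, and profiles superpose over doses", {
  expect_identical(concentration_at(c(V = 17.9, CL = 0.036), NULL, 100), 0)
  p <- c(V = 20, CL = 0.5)
  two <- rbind(dose_event(1500, 0, 0.5), dose_event(800, 48, 2))
  tt <- c(10, 49, 100)
  expect_equal(concentration_at(p, two, tt),
               concentration_at(p, dose_event(1500, 0, 0.5), tt) +
                 concentration_at(p, dose_event(800, 48, 2), tt))
  expect_error(concentration_at(p, dose_event(1500), -1), "time")
  expect_error(concentration_at(c(V = -1, CL = 0.1), dose_event(1500), 1),
               "positive")
})

test_that("concentration decreases strictly after the infusion ends", {
  p <- c(V = 17.9, CL = 0.036)
  tt <- seq(1, 800, by = 1)
  cc <- concentration_at(p, dose_event(1500, 0, 0.5), tt)
  expect_true(all(diff(cc) < 0))
})

test_that("windowed AUC is exact, additive, and Dose/CL at infinity", {
  p <- c(V = 17.9, CL = 0.036)
  d <- dose_event(1500, 0, 0.5)
  expect_identical(auc_window(p, d, 10, 10), 0)
  expect_equal(auc_window(p, d, 0, Inf), 1500 / 0.036, tolerance = 1e-12)
  # additivity to machine tolerance
  a <- auc_window(p, d, 0, 200) + auc_window(p, d, 200, 504) +
    auc_window(p, d, 504, Inf)
  expect_equal(a, auc_window(p, d, 0, Inf), tolerance = 1e-12)
  # trapezoidal oracle over the day-21 window
  expect_equal(auc_window(p, d, 504, 528),
               trap_auc(17.9, 0.036, 1500, 0.5, 504, 528),
               tolerance = 1e-5)
  # AUC over a fixed-width window decreases with window start (post peak)
  starts <- seq(24, 600, by = 24)
  aucs <- vapply(starts, function(s) auc_window(p, d, s, s + 24), 0)
  expect_true(all(diff(aucs) < 0))
  expect_error(auc_window(p, d, 10, 5), "t2")
})

test_that("unbound fraction and residual-error model follow their formulas", {
  expect_equal(unbound_fraction(93), 0.07)
  expect_equal(unbound_fraction(99), 0.01)
  expect_identical(unbound_fraction(100), 0)
  expect_error(unbound_fraction(101), "between")
  expect_identical(apply_residual_error(10, 0, 3), 10)
  expect_equal(apply_residual_error(10, 0.12, 1), 11.2)
  expect_identical(apply_residual_error(0, 0.12, 2.5), 0)
  expect_error(apply_residual_error(-1, 0.1, 0), "pred")
})
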