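# SAEM estimator: degenerate limits, determinism, EBEs, shrinkage, RSE.

test_that("with no IIV and tiny error the fit matches an NLS curve fit", {
  skip_if_not_installed("minpack.lm")
  set.seed(21)
  tt <- seq(12, 700, length.out = 24)
  f <- conc1_oracle(17.9, 0.036, 1500, 0.5, tt)
  y <- f * (1 + 1e-6 * rnorm(24))
  dat <- pk_dataset(data.frame(id = 1, time = tt, dv = y),
                    data.frame(id = 1, time = 0, amt = 1500, dur = 0.5))
  fit <- saem(dat, control = saem_control(fix_omega = c(V = 0, CL = 0),
                                          rse_method = "none"))
  ref <- minpack.lm::nlsLM(y ~ conc1_oracle(V, CL, 1500, 0.5, tt),
                           start = list(V = 10, CL = 0.01))
  expect_lt(abs(coef(fit)[["V"]] / coef(ref)[["V"]] - 1), 0.005)
  expect_lt(abs(coef(fit)[["CL"]] / coef(ref)[["CL"]] - 1), 0.005)
})

test_that("the fit is reproducible given a seed and moves with it", {
  dat <- generate_pk_dataset(study_design(n_subjects = 8),
                             dalbavancin_model(), seed = 4)
  f1 <- saem(dat, control = fast_ctl(), seed = 7)
  f2 <- saem(dat, control = fast_ctl(), seed = 7)
  f3 <- saem(dat, control = fast_ctl(), seed = 8)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("empirical Bayes modes track individual fits for rich subjects", {
  skip_if_not_installed("minpack.lm")
  set.seed(22)
  # richly sampled subjects with small residual error: the likelihood
  # dominates the prior, so the EBE tracks the per-subject curve fit
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.25, CL = 0.25), b = 0.02)
  tt_rich <- seq(24, 700, length.out = 16)
  dat <- make_toy_dataset(5, list(tt_rich), pop, seed = 5)
  fit <- saem(dat, init = pop, control = fast_ctl(), seed = 2)
  eb <- empirical_bayes(fit)
  ind <- exp(sweep(eb, 2, log(fit$estimates$fixed), "+"))
  sub1 <- dat$obs[dat$obs$id == 1, ]
  ref <- minpack.lm::nlsLM(dv ~ conc1_oracle(V, CL, 1500, 0.5, time),
                           data = sub1, start = list(V = 15, CL = 0.03))
  expect_lt(abs(ind[1, "V"] / coef(ref)[["V"]] - 1), 0.05)
  expect_lt(abs(ind[1, "CL"] / coef(ref)[["CL"]] - 1), 0.05)
})

test_that("EBEs correlate with the generating random effects", {
  dat <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 6)
  fit <- saem(dat, control = fast_ctl(), seed = 6)
  true_eta <- attr(dat, "true_eta")
  eb <- empirical_bayes(fit)
  expect_gt(cor(eb[, "CL"], true_eta[, "CL"]), 0.7)
})

test_that("shrinkage is small with rich data and NA for zero IIV", {
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.3, CL = 0.3), b = 0.08)
  tt <- seq(24, 700, length.out = 10)
  dat <- make_toy_dataset(14, list(tt), pop, seed = 8)
  fit <- saem(dat, init = pop, control = fast_ctl(), seed = 3)
  expect_true(all(shrinkage(fit) < 30))
  fit0 <- saem(dat, init = pop,
               control = fast_ctl(fix_omega = c(V = 0, CL = 0)), seed = 3)
  expect_true(all(is.na(shrinkage(fit0))))
})

test_that("RSE in the no-IIV limit matches the observed-information oracle", {
  set.seed(23)
  tt <- seq(24, 700, length.out = 12)
  f <- conc1_oracle(17.9, 0.036, 1500, 0.5, tt)
  y <- f * (1 + 0.1 * rnorm(12))
  dat <- pk_dataset(data.frame(id = 1, time = tt, dv = y),
                    data.frame(id = 1, time = 0, amt = 1500, dur = 0.5))
  fit <- saem(dat, control = saem_control(fix_omega = c(V = 0, CL = 0),
                                          rse_method = "none"))
  got <- rse(fit, method = "fd")
  # independent oracle: numerical observed information of the direct
  # log-likelihood at the estimates
  est <- coef(fit)[c("V", "CL", "b")]
  nll <- function(th) {
    fi <- conc1_oracle(th[1], th[2], 1500, 0.5, tt)
    -sum(dnorm(y, fi, th[3] * fi, log = TRUE))
  }
  H <- stats::optimHess(est, nll)
  ref <- 100 * sqrt(diag(solve(H))) / est
  expect_equal(unname(got[c("V", "CL", "b")]), unname(ref),
               tolerance = 0.05)
})

test_that("the study design identifies both fixed effects (RSE < 25%)", {
  dat <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 2)
  fit <- saem(dat, control = saem_control(rse_method = "none"), seed = 2)
  r <- rse(fit)
  expect_lt(r[["V"]], 25)
  expect_lt(r[["CL"]], 25)
  expect_true(attr(r, "method") %in% c("louis", "fd"))
})

test_that("a power covariate effect on CL is recovered", {
  dat <- make_cov_dataset(40, beta_crcl = 0.9, seed = 31)
  fit <- saem(dat, covariates = list(list(param = "CL",
                                          covariate = "crcl")),
              control = fast_ctl(), seed = 31)
  expect_equal(unname(coef(fit)[["crcl_on_CL"]]), 0.9, tolerance = 0.35)
})

test_that("the smoothing-phase trace stabilises on an easy problem", {
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.2, CL = 0.25), b = 0.1)
  tt <- seq(48, 700, length.out = 6)
  dat <- make_toy_dataset(16, list(tt), pop, seed = 12)
  fit <- saem(dat, control = saem_control(rse_method = "none"), seed = 12)
  expect_true(fit$converged)
  tr <- fit$trace
  tail_n <- ceiling(0.2 * nrow(tr))
  tl <- tr[seq(nrow(tr) - tail_n + 1, nrow(tr)), "V"]
  sl <- coef(lm(tl ~ seq_along(tl)))[2]
  expect_lt(abs(sl) * tail_n / mean(tl), 0.1)
})

test_that("degenerate inputs are refused cleanly", {
  empty <- generate_pk_dataset(study_design(n_subjects = 0),
                               dalbavancin_model(), seed = 1)
  expect_error(saem(empty), "empty dataset")
})
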