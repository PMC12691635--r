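# Importance-sampling OFV against closed-form and quadrature oracles.

test_that("with no random effects the OFV equals the normal likelihood", {
  set.seed(41)
  tt <- seq(24, 700, length.out = 10)
  f <- conc1_oracle(18, 0.04, 1500, 0.5, tt)
  y <- f * (1 + 0.1 * rnorm(10))
  dat <- pk_dataset(data.frame(id = 1, time = tt, dv = y),
                    data.frame(id = 1, time = 0, amt = 1500, dur = 0.5))
  fit <- saem(dat, control = saem_control(fix_omega = c(V = 0, CL = 0),
                                          rse_method = "none"))
  ll <- compute_ofv(fit)
  est <- coef(fit)
  fhat <- conc1_oracle(est[["V"]], est[["CL"]], 1500, 0.5, tt)
  ref <- -2 * sum(dnorm(y, fhat, est[["b"]] * fhat, log = TRUE))
  expect_equal(ll$ofv, ref, tolerance = 1e-10)
  expect_identical(ll$se, 0)
  expect_equal(ll$aic, ll$ofv + 2 * 3)
})

test_that("the IS estimate matches 20-node adaptive quadrature on a toy", {
  skip_if_not_installed("pracma")
  set.seed(42)
  pop <- popmodel(c(V = 18, CL = 0.04), c(V = 0.2, CL = 0.3), b = 0.12)
  dat <- make_toy_dataset(2, list(c(48, 300, 550), c(120, 400, 650)),
                          pop, seed = 42)
  # omegas held at their generating values: a 2-subject toy cannot
  # identify them, and the oracle check concerns the likelihood value
  fit <- saem(dat, init = pop,
              control = saem_control(n_explore = 120, n_smooth = 60,
                                     fix_omega = c(V = 0.2, CL = 0.3),
                                     rse_method = "none"), seed = 2)
  is_est <- compute_ofv(fit, n_is = 20000, seed = 5)
  # independent oracle: adaptive Gauss-Hermite with pracma nodes, own code
  gh <- pracma::gaussHermite(20)
  est <- fit$estimates
  loglik <- 0
  for (i in 1:2) {
    sub <- dat$obs[dat$obs$id == i, ]
    cll <- function(e1, e2) {
      fi <- conc1_oracle(est$fixed[["V"]] * exp(e1),
                         est$fixed[["CL"]] * exp(e2), 1500, 0.5, sub$time)
      sum(dnorm(sub$dv, fi, est$b * fi, log = TRUE)) +
        dnorm(e1, 0, est$omega[["V"]], log = TRUE) +
        dnorm(e2, 0, est$omega[["CL"]], log = TRUE)
    }
    opt <- optim(c(0, 0), function(e) -cll(e[1], e[2]), hessian = TRUE)
    S <- solve(opt$hessian)
    L <- chol(S)
    tot <- 0
    for (a in 1:20) for (bb in 1:20) {
      e <- opt$par + sqrt(2) * as.numeric(c(gh$x[a], gh$x[bb]) %*% L)
      tot <- tot + gh$w[a] * gh$w[bb] *
        exp(cll(e[1], e[2]) + gh$x[a]^2 + gh$x[bb]^2)
    }
    loglik <- loglik + log(tot * 2^(2 / 2) * prod(diag(L)) / pi^0)
  }
  ref_ofv <- -2 * loglik
  expect_lt(abs(is_est$ofv - ref_ofv), max(3 * is_est$se, 0.05))
})

test_that("an unnecessary parameter never worsens the marginal fit and the
           information criteria penalise it", {
  dat <- make_cov_dataset(20, beta_crcl = 0, seed = 44)
  ctl <- saem_control(n_explore = 400, n_smooth = 200, rse_method = "none")
  init <- dalbavancin_model()
  base <- saem(dat, init = init, control = ctl, seed = 4)
  ext <- saem(dat, init = init,
              covariates = list(list(param = "CL", covariate = "crcl")),
              control = ctl, seed = 4)
  o_base <- compute_ofv(base, n_is = 8000, seed = 9)
  o_ext <- compute_ofv(ext, n_is = 8000, seed = 9)
  slack <- 3 * (o_base$se + o_ext$se) + 2   # SAEM + IS noise
  expect_lt(o_ext$ofv, o_base$ofv + slack)
  expect_equal(o_ext$aic - o_ext$ofv, o_base$aic - o_base$ofv + 2)
  # BICc convention: ln(N) per population parameter, ln(n_obs) for error
  expect_equal(o_base$bicc,
               o_base$ofv + log(base$prep$N) * 4 + log(base$prep$n_obs))
  expect_equal(o_ext$bicc,
               o_ext$ofv + log(ext$prep$N) * 5 + log(ext$prep$n_obs))
})
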