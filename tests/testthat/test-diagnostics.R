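# Bootstrap, NPDE, pc-VPC and goodness-of-fit diagnostics.

test_that("bootstrap of a cohort of identical subjects collapses its CI", {
  set.seed(61)
  tt <- seq(48, 700, length.out = 8)
  f <- conc1_oracle(17.9, 0.036, 1500, 0.5, tt)
  y <- f * (1 + 0.05 * rnorm(8))
  obs <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(id = i, time = tt, dv = y)   # same data for every subject
  }))
  dat <- pk_dataset(obs, data.frame(id = 1:8, time = 0, amt = 1500,
                                    dur = 0.5))
  fit <- saem(dat, control = fast_ctl(), seed = 1)
  bs <- pk_bootstrap(fit, n_resamples = 12, seed = 2)
  tab <- bs$table
  v <- tab[tab$parameter == "V", ]
  expect_lt(abs(v$median / v$estimate - 1), 0.05)
  expect_lt((v$ci_upper - v$ci_lower) / v$estimate, 0.1)
})

test_that("a small bootstrap run completes, orders its CIs and is
           reproducible under a fixed seed", {
  dat <- generate_pk_dataset(study_design(n_subjects = 8),
                             dalbavancin_model(), seed = 62)
  fit <- saem(dat, control = fast_ctl(), seed = 1)
  b1 <- pk_bootstrap(fit, n_resamples = 4, seed = 9)
  b2 <- pk_bootstrap(fit, n_resamples = 4, seed = 9)
  expect_true(all(b1$table$ci_lower <= b1$table$median))
  expect_true(all(b1$table$median <= b1$table$ci_upper))
  expect_lte(b1$n_converged, 4L)
  expect_identical(b1$table, b2$table)
})

test_that("scalar NPDE equals the inverse normal of the simple rank", {
  dat <- generate_pk_dataset(study_design(n_subjects = 10,
                                          samples_range = c(1L, 1L)),
                             dalbavancin_model(), seed = 63)
  pop <- dalbavancin_model()
  K <- 400L
  res <- npde(dat, popmodel = pop, K = K, seed = 7)
  # recompute from the same simulated replicates: with one observation per
  # subject decorrelation rescales but cannot reorder
  prep <- dalbapk:::.prep_estimation(dat, pop$model)
  sims <- dalbapk:::.simulate_replicates(prep, pop, K, seed = 7)
  for (i in seq_len(prep$N)) {
    sel <- which(prep$obs_subj == i)
    r <- sum(sims$y[sel, ] < prep$y[sel]) +
      0.5 * sum(sims$y[sel, ] == prep$y[sel])
    expect_equal(res$npde[sel], qnorm((r + 0.5) / (K + 1)))
  }
  expect_error(npde(dat, popmodel = pop, K = 50), "at least 100")
})

test_that("NPDE detects a grossly misspecified clearance", {
  truth <- dalbavancin_model()
  dat <- generate_pk_dataset(study_design(), truth, seed = 64)
  wrong <- popmodel(c(V = truth$fixed[["V"]],
                      CL = 2 * truth$fixed[["CL"]]),
                    truth$omega, truth$b)
  res <- npde(dat, popmodel = wrong, K = 600, seed = 3)
  expect_lt(res$global$p_value[1], 0.01)   # mean-zero test rejects
  ok <- npde(dat, popmodel = truth, K = 600, seed = 3)
  expect_gt(ok$global$p_value[4], 0.05)
})

test_that("prediction correction is the identity when PRED is flat within
           bins, and bands cover self-simulated data", {
  set.seed(65)
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.2, CL = 0.29), b = 0.12)
  # every subject sampled at the same two times -> constant PRED per bin
  dat <- make_toy_dataset(20, list(c(240, 550)), pop, seed = 65)
  v <- pc_vpc(dat, popmodel = pop, n_sim = 120,
              bins = c(0, 400, 700), seed = 2)
  for (bn in 1:2) {
    tsel <- if (bn == 1) 240 else 550
    raw <- dat$obs$dv[dat$obs$time == tsel]
    expect_equal(v$bands$obs_p50[bn],
                 unname(quantile(raw, 0.5, type = 7)))
  }
  # coverage on a 4-bin design simulated from the model itself
  dat2 <- make_toy_dataset(24, list(c(100, 240, 400, 600)), pop, seed = 66)
  v2 <- pc_vpc(dat2, popmodel = pop, n_sim = 300,
               bins = c(0, 168, 336, 504, 720), seed = 4)
  inside <- with(v2$bands, c(
    obs_p10 >= sim_p10_lo & obs_p10 <= sim_p10_hi,
    obs_p50 >= sim_p50_lo & obs_p50 <= sim_p50_hi,
    obs_p90 >= sim_p90_lo & obs_p90 <= sim_p90_hi))
  expect_gte(mean(inside), 0.8)
})

test_that("weekly binning runs on the study design and thin bins merge", {
  dat <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 66)
  v <- pc_vpc(dat, popmodel = dalbavancin_model(), n_sim = 100,
              bins = c(0, 7, 14, 21, 30) * 24, seed = 1)
  expect_gte(nrow(v$bands), 2)
  expect_true(all(diff(v$bands$t_lo) > 0))
  # nested band invariant
  expect_true(all(v$bands$sim_p10_lo <= v$bands$sim_p10_hi))
})

test_that("pc-VPC bands widen with the residual-error magnitude", {
  pop_lo <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.2, CL = 0.29),
                     b = 0.05)
  pop_hi <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.2, CL = 0.29),
                     b = 0.35)
  dat <- generate_pk_dataset(study_design(), pop_lo, seed = 67)
  v_lo <- pc_vpc(dat, popmodel = pop_lo, n_sim = 150, seed = 2)
  v_hi <- pc_vpc(dat, popmodel = pop_hi, n_sim = 150, seed = 2)
  w <- function(v) mean(v$bands$sim_p90_hi - v$bands$sim_p10_lo)
  expect_gt(w(v_hi), w(v_lo))
})

test_that("goodness-of-fit residuals are calibrated on self-simulated
           rich data", {
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0.2, CL = 0.29), b = 0.12)
  tt <- seq(48, 700, length.out = 8)
  dat <- make_toy_dataset(12, list(tt), pop, seed = 68)
  fit <- saem(dat, init = pop, control = fast_ctl(), seed = 68)
  tab <- gof_table(fit, include_npde = FALSE)
  expect_named(tab, c("id", "time", "dv", "pred", "ipred", "iwres"))
  expect_gt(sd(tab$iwres), 0.8)
  expect_lt(sd(tab$iwres), 1.2)
  expect_equal(tab$iwres, residuals(fit))
  # near-zero error, rich data: IPRED tracks DV closely
  pop0 <- popmodel(pop$fixed, pop$omega, b = 0.01)
  dat0 <- make_toy_dataset(6, list(tt), pop0, seed = 69)
  fit0 <- saem(dat0, init = pop0, control = fast_ctl(), seed = 69)
  tab0 <- gof_table(fit0, include_npde = FALSE)
  expect_lt(max(abs(tab0$dv / tab0$ipred - 1)), 0.05)
})
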