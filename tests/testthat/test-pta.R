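# Monte Carlo PTA engine: profile draws, windowed unbound exposure,
# target-attainment tables and their invariants.

test_that("profile simulation honours the IIV and the seed", {
  pop <- dalbavancin_model()
  # no IIV: everyone is the typical individual
  pop0 <- popmodel(pop$fixed, c(V = 0, CL = 0), pop$b)
  P0 <- simulate_profiles(pop0, pta_scenario(n_profiles = 50, seed = 1))
  expect_equal(P0[, "V"], rep(17.9, 50), ignore_attr = TRUE)
  expect_equal(P0[, "CL"], rep(0.036, 50), ignore_attr = TRUE)
  # large-sample SD of log CL reproduces the generating 0.290
  Pbig <- simulate_profiles(pop, pta_scenario(n_profiles = 100000, seed = 2))
  expect_equal(sd(log(Pbig[, "CL"])), 0.290, tolerance = 0.02)
  # determinism
  P1 <- simulate_profiles(pop, pta_scenario(n_profiles = 100, seed = 3))
  P2 <- simulate_profiles(pop, pta_scenario(n_profiles = 100, seed = 3))
  expect_identical(P1, P2)
})

test_that("fauc24 is the unbound windowed AUC", {
  p <- c(V = 17.9, CL = 0.036)
  d <- dose_event(1500, 0, 0.5)
  expect_identical(fauc24(p, d, 21, 0), 0)
  expect_equal(fauc24(p, d, 21, 0.07),
               0.07 * trap_auc(17.9, 0.036, 1500, 0.5, 504, 528),
               tolerance = 1e-4)
  expect_equal(fauc24(p, d, 21, 0.07), 49.8, tolerance = 0.01)
  # post-peak decay: day 27 exposure below day 21 for every profile
  P <- simulate_profiles(dalbavancin_model(),
                         pta_scenario(n_profiles = 200, seed = 4))
  a21 <- dalbapk:::.auc24_profiles(one_compartment(), P, d, 21)
  a27 <- dalbapk:::.auc24_profiles(one_compartment(), P, d, 27)
  expect_true(all(a27 < a21))
  expect_error(fauc24(p, d, 0, 0.07), "before")
})

test_that("PTA is monotone in MIC, binding and day, and stasis dominates
           kill", {
  pt <- pta_table(dalbavancin_model(), pta_scenario(seed = 5))
  st <- stasis_table(dalbavancin_model(), pta_scenario(seed = 5))
  arr <- pt$pta
  for (b in seq_len(dim(arr)[1])) for (d in seq_len(dim(arr)[2])) {
    expect_true(all(diff(arr[b, d, ]) <= 0))   # MIC
  }
  for (b in seq_len(dim(arr)[1])) for (m in seq_len(dim(arr)[3])) {
    expect_true(all(diff(arr[b, , m]) <= 0))   # day
  }
  for (d in seq_len(dim(arr)[2])) for (m in seq_len(dim(arr)[3])) {
    expect_true(all(diff(arr[, d, m]) <= 0))   # binding
  }
  expect_true(all(st$pta >= pt$pta))
  expect_true(all(arr >= 0 & arr <= 100))
  df <- as.data.frame(pt)
  expect_identical(df$optimal, df$pta >= 90)
})

test_that("tiny MICs saturate and a single profile is all-or-nothing", {
  sc <- pta_scenario(n_profiles = 300, mic = c(1e-6, 0.25),
                     report_mic = c(0.25), seed = 6)
  pt <- pta_table(dalbavancin_model(), sc)
  expect_true(all(pt$pta[, , 1] == 100))
  sc1 <- pta_scenario(n_profiles = 1, seed = 7)
  p1 <- pta_table(dalbavancin_model(), sc1)
  expect_true(all(p1$pta %in% c(0, 100)))
})

test_that("with IIV on CL only, PTA matches the exact lognormal tail", {
  pop <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0, CL = 0.29), b = 0.12)
  sc <- pta_scenario(n_profiles = 1000, seed = 8)
  pt <- pta_table(pop, sc)
  d <- dose_event(1500, 0, 0.5)
  # oracle: fAUC24 is monotone decreasing in CL, so PTA = P(CL <= c*) with
  # c* found by root-finding on the analytic exposure
  for (cell in list(c(bi = 3, day = 21, mic = 0.25),
                    c(bi = 1, day = 35, mic = 0.25),
                    c(bi = 4, day = 21, mic = 0.125))) {
    fu <- unbound_fraction(sc$binding[cell[["bi"]]])
    thr <- 50 * cell[["mic"]]
    g <- function(cl) {
      fu * trap_auc(17.9, cl, 1500, 0.5, 24 * cell[["day"]],
                    24 * cell[["day"]] + 24, step = 0.05) - thr
    }
    ref <- if (g(1e-4) < 0) 0 else if (g(1) > 0) 100 else {
      cstar <- uniroot(g, c(1e-4, 1), tol = 1e-10)$root
      100 * pnorm(log(cstar / 0.036) / 0.29)
    }
    got <- pt$pta[cell[["bi"]], paste0("day", cell[["day"]]),
                  as.character(cell[["mic"]])]
    expect_lt(abs(got - ref), 3)
  }
})

test_that("Monte Carlo error at p near 50% follows the binomial law", {
  pop <- dalbavancin_model()
  # pick a mid-probability cell: 97% binding, day 27, MIC 0.25 sits near
  # the centre of the distribution
  vals <- vapply(1:24, function(s) {
    sc <- pta_scenario(n_profiles = 1000, binding = 97, mic = 0.25,
                       report_mic = 0.25, eval_days = 27, seed = 100 + s)
    as.numeric(pta_table(pop, sc)$pta)
  }, 0)
  p <- mean(vals)
  expect_equal(sd(vals), sqrt(p * (100 - p) / 1000), tolerance = 0.45)
})

test_that("table output formats round-trip the reported grid", {
  pt <- pta_table(dalbavancin_model(), pta_scenario(n_profiles = 100,
                                                    seed = 9))
  tsv <- tempfile(fileext = ".tsv")
  md <- tempfile(fileext = ".md")
  write_pta_table(pt, tsv)
  write_pta_table(pt, md, format = "markdown")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 4 * 3)
  expect_equal(ncol(tab), 2 + 4)
  expect_true(any(grepl("^\\|", readLines(md))))
})
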