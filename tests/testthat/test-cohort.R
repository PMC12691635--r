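# Synthetic cohort generator and the packaged clinical-outcomes fixture.

test_that("fixture aggregates equal every printed cohort count", {
  fx <- cohort_fixture()
  expect_equal(nrow(fx), 20)
  expect_equal(sum(fx$sex == "F"), 14)
  jt <- table(fx$joint)
  expect_equal(unname(jt[c("hip", "knee", "shoulder", "ankle")]),
               c(11L, 6L, 2L, 1L), ignore_attr = TRUE)
  iso <- c(fx$isolate_1, fx$isolate_2)
  iso <- iso[!is.na(iso) & iso != ""]
  expect_length(iso, 24)
  cons <- c("S. epidermidis", "S. lugdunensis", "S. capitis", "S. hominis",
            "S. pettenkoferi")
  expect_equal(sum(iso %in% cons), 17)
  expect_equal(sum(iso == "S. epidermidis"), 12)
  expect_equal(sum(iso == "S. lugdunensis"), 1)
  expect_equal(sum(iso == "C. acnes"), 6)
  expect_equal(sum(iso == "E. faecalis"), 1)
  expect_equal(sum(!is.na(fx$isolate_2) & fx$isolate_2 != ""), 4)
  expect_equal(sum(fx$second_stage == 1), 19)
  expect_equal(sum(fx$second_stage == 0), 1)
  expect_equal(fx$sex[fx$second_stage == 0], "F")
  expect_equal(sum(fx$second_stage_culture_positive == 1, na.rm = TRUE), 1)
})

test_that("cohort summary reproduces the printed rates and medians", {
  s <- cohort_summary(cohort_fixture())
  expect_equal(s$microbiological_cure_pct, 94.7)
  expect_equal(s$clinical_cure_pct, 100)
  expect_equal(unname(s$isolate_pct["CoNS"]), 70.8)
  expect_equal(unname(s$isolate_pct["S. epidermidis"]), 50)
  expect_equal(unname(s$isolate_pct["C. acnes"]), 25)
  expect_equal(unname(s$isolate_pct["E. faecalis"]), 4.2)
  expect_equal(s$pct_female, 70)
  expect_equal(unname(s$age), c(75.5, 69, 79))
  expect_equal(unname(s$prior_iv_days), c(11.5, 10, 16))
  expect_equal(unname(s$interval_days), c(134, 85, 175))
  expect_equal(unname(s$follow_up_days), c(693, 630, 824))
})

test_that("an all-negative toy fixture gives 100% microbiological cure", {
  toy <- data.frame(sex = c("F", "M"), age = c(70, 75),
                    joint = c("hip", "knee"),
                    isolate_1 = "S. epidermidis", isolate_2 = "",
                    prior_iv_days = c(10, 12), second_stage = 1,
                    second_stage_culture_positive = 0,
                    interval_days = c(100, 120),
                    follow_up_days = c(600, 700), clinical_cure = 1)
  s <- cohort_summary(toy)
  expect_equal(s$microbiological_cure_pct, 100)
})

test_that("noise-free generation lies exactly on the typical curve", {
  truth <- popmodel(c(V = 17.9, CL = 0.036), c(V = 0, CL = 0), b = 0)
  dat <- generate_pk_dataset(study_design(n_subjects = 6), truth, seed = 5)
  f <- conc1_oracle(17.9, 0.036, 1500,
                    dat$doses$dur[match(dat$obs$id, dat$doses$id)],
                    dat$obs$time)
  expect_equal(dat$obs$dv, round(f, 2))
})

test_that("pooled week-3 concentrations bracket the observed cohort
           median", {
  dat <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 1)
  sel <- dat$obs$time >= 18 * 24 & dat$obs$time <= 23 * 24
  expect_gt(sum(sel), 2)
  m <- median(dat$obs$dv[sel])
  expect_gt(m, 29.7 * 0.8)
  expect_lt(m, 29.7 * 1.2)
})

test_that("generation is seed-reproducible and refuses nothing it
           should accept", {
  d1 <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 10)
  d2 <- generate_pk_dataset(study_design(), dalbavancin_model(), seed = 10)
  expect_identical(d1$obs, d2$obs)
  expect_identical(d1$covariates, d2$covariates)
  empty <- generate_pk_dataset(study_design(n_subjects = 0),
                               dalbavancin_model(), seed = 1)
  expect_length(empty$ids, 0)
})
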