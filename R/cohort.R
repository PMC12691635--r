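# Synthetic-cohort generator (study-design emulation of sparse trough
# sampling after a single dalbavancin dose) and the packaged
# clinical-outcomes fixture.

#' Study design for the synthetic PK cohort
#'
#' Describes the sampling design being emulated: a cohort of elderly
#' patients with preserved renal function and normal albumin, each given a
#' single 1,500 mg IV dose (infused over 0.5 h or 2 h), contributing 1-3
#' trough-like samples drawn from weekly follow-up windows between about
#' day 8 and day 30 post dose.
#'
#' @param n_subjects cohort size (default 18, the modelled cohort).
#' @param samples_range min/max samples per subject.
#' @param windows list of day windows (inclusive) from which sampling days
#'   are drawn.
#' @param window_weights sampling probability of each window (normalised).
#' @param dose_amount mg.
#' @param infusion_mix probability that a subject receives the short
#'   (0.5 h) infusion; the remainder get the 2 h extended infusion.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_subjects = 18L, samples_range = c(1L, 3L),
                         windows = list(c(8, 14), c(18, 23), c(26, 30)),
                         window_weights = c(0.2, 0.45, 0.35),
                         dose_amount = 1500, infusion_mix = 0.5) {
  stopifnot(n_subjects >= 0, samples_range[1] >= 1,
            samples_range[2] <= length(windows) * 7)
  structure(list(n_subjects = as.integer(n_subjects),
                 samples_range = as.integer(samples_range),
                 windows = windows,
                 window_weights = window_weights / sum(window_weights),
                 dose_amount = dose_amount, infusion_mix = infusion_mix),
            class = "study_design")
}

# invert CKD-EPI for serum creatinine given a target eGFR; clamps to the
# physiologic creatinine range when the target is not reachable at that age
.scr_from_egfr <- function(egfr, age, sex) {
  vapply(seq_along(egfr), function(i) {
    f <- function(s) egfr_ckd_epi(s, age[i], sex[i]) - egfr[i]
    lo <- 0.1; hi <- 8
    if (f(lo) <= 0) return(lo)
    if (f(hi) >= 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }, 0)
}

#' Generate a synthetic sparse PK dataset
#'
#' Simulates a cohort under a [study_design()] and a generating
#' [popmodel()] truth: covariates are drawn to match an elderly,
#' predominantly female cohort with preserved renal function (median eGFR
#' near 90 mL/min) and normal albumin (median near 45 g/L); sampling days
#' come from the design's follow-up windows; concentrations are model
#' predictions perturbed by proportional residual error, with values below
#' the 1.0 mg/L quantification limit flagged BLQ.
#'
#' @param design a [study_design()].
#' @param truth a [popmodel()] used as generating truth (e.g.
#'   [dalbavancin_model()]).
#' @param seed integer seed; generation is fully reproducible.
#' @param lloq lower limit of quantification (mg/L).
#' @return A [pk_dataset()] with covariates `age`, `sex`, `height`,
#'   `weight`, `bmi`, `scr`, `albumin`, `egfr`, `crcl`.
#' @export
generate_pk_dataset <- function(design = study_design(),
                                truth = dalbavancin_model(), seed = 1L,
                                lloq = 1.0) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "popmodel"))
  set.seed(seed)
  N <- design$n_subjects
  if (N == 0L) {
    return(pk_dataset(data.frame(id = integer(), time = numeric(),
                                 dv = numeric()),
                      data.frame(id = integer(), time = numeric(),
                                 amt = numeric(), dur = numeric()),
                      lloq = lloq))
  }
  sex <- ifelse(stats::runif(N) < 0.7, "F", "M")
  age <- round(pmin(pmax(stats::rnorm(N, 75, 6), 60), 92))
  height <- round(ifelse(sex == "F", stats::rnorm(N, 158, 6),
                         stats::rnorm(N, 172, 7)))
  weight <- round(pmin(pmax(ifelse(sex == "F", stats::rnorm(N, 66, 10),
                                   stats::rnorm(N, 80, 11)), 42), 120), 1)
  albumin <- round(pmin(pmax(stats::rnorm(N, 44, 4.5), 30), 55))
  egfr <- round(pmin(pmax(stats::rnorm(N, 89, 13), 60), 125), 1)
  scr <- round(.scr_from_egfr(egfr, age, sex), 2)
  covs <- data.frame(id = seq_len(N), age = age, sex = sex,
                     height = height, weight = weight,
                     bmi = round(body_mass_index(weight, height), 1),
                     scr = scr, albumin = albumin,
                     egfr = round(egfr_ckd_epi(scr, age, sex), 1),
                     crcl = round(crcl_cockcroft_gault(age, weight, scr,
                                                       sex), 1))
  dur <- ifelse(stats::runif(N) < design$infusion_mix, 0.5, 2)
  doses <- data.frame(id = seq_len(N), time = 0,
                      amt = design$dose_amount, dur = dur)
  # individual parameters from the generating truth
  d <- truth$model$npar
  eta <- matrix(stats::rnorm(N * d), N, d)
  eta <- sweep(eta, 2, truth$omega, "*")
  P <- exp(sweep(eta, 2, log(truth$fixed), "+"))
  obs <- vector("list", N)
  nw <- length(design$windows)
  for (i in seq_len(N)) {
    n_i <- sample(seq(design$samples_range[1], design$samples_range[2]), 1)
    win <- sample(nw, min(n_i, nw), prob = design$window_weights)
    days <- vapply(design$windows[win], function(w) {
      sample(seq(w[1], w[2]), 1)
    }, 0)
    times <- sort(days * 24)
    f <- concentration_at(stats::setNames(P[i, ], truth$model$pnames),
                          doses[i, c("time", "amt", "dur")], times,
                          model = truth$model)
    y <- apply_residual_error(f, truth$b, stats::rnorm(length(f)))
    obs[[i]] <- data.frame(id = i, time = times, dv = pmax(round(y, 2), 0))
  }
  out <- pk_dataset(do.call(rbind, obs), doses, covs, lloq = lloq)
  # generating individual effects, retained for simulation studies
  dimnames(eta) <- list(NULL, truth$model$pnames)
  attr(out, "true_eta") <- eta
  attr(out, "true_params") <- P
  out
}

# ---- clinical-outcomes fixture -------------------------------------------

.CONS_SPECIES <- c("S. epidermidis", "S. lugdunensis", "S. capitis",
                   "S. hominis", "S. pettenkoferi")

#' Packaged synthetic clinical-outcomes fixture
#'
#' A deterministic, patient-level record set for a 20-patient chronic
#' prosthetic joint infection cohort managed with two-stage exchange and a
#' single 1,500 mg dalbavancin dose. Aggregate counts (sex, infected
#' joint, microbiological isolates, second-stage surgery and its culture
#' results) and the medians/interquartile intervals of the continuous
#' fields reproduce the published cohort summary; patient-level values and
#' isolate MICs are synthetic constructions and carry no patient
#' information.
#'
#' @return Data frame of class `cohort_fixture`, one row per patient.
#' @export
cohort_fixture <- function() {
  path <- system.file("extdata", "cohort_synthetic.csv", package = "dalbapk",
                      mustWork = TRUE)
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(fx) <- c("cohort_fixture", "data.frame")
  fx
}

.isolates_of <- function(fx) {
  iso <- c(fx$isolate_1, fx$isolate_2)
  iso[!is.na(iso) & iso != ""]
}

#' Cohort descriptive summary
#'
#' Counts and percentages for categorical fields, medians with
#' interquartile intervals (type-7 quantiles; even-n medians are the mean
#' of the middle pair) for continuous ones, and the outcome rates:
#' microbiological cure = patients with negative intraoperative cultures
#' at second-stage surgery / patients undergoing second-stage surgery;
#' clinical cure from the per-patient cure flag. Percentages are reported
#' to one decimal.
#'
#' @param fixture a [cohort_fixture()]-style data frame.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(fixture = cohort_fixture()) {
  fx <- fixture
  iso <- .isolates_of(fx)
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round(100 * num / den, 1)
  }
  med_iqi <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(median = NA, q1 = NA, q3 = NA))
    c(median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25, type = 7)),
      q3 = unname(stats::quantile(v, 0.75, type = 7)))
  }
  n <- nrow(fx)
  second <- fx$second_stage == 1
  n_second <- sum(second, na.rm = TRUE)
  pos <- sum(fx$second_stage_culture_positive == 1, na.rm = TRUE)
  out <- list(
    n_patients = n,
    n_female = sum(fx$sex == "F"),
    pct_female = pct(sum(fx$sex == "F"), n),
    joints = table(fx$joint),
    n_isolates = length(iso),
    isolate_counts = c(
      CoNS = sum(iso %in% .CONS_SPECIES),
      `S. epidermidis` = sum(iso == "S. epidermidis"),
      `C. acnes` = sum(iso == "C. acnes"),
      `E. faecalis` = sum(iso == "E. faecalis")),
    isolate_pct = c(
      CoNS = pct(sum(iso %in% .CONS_SPECIES), length(iso)),
      `S. epidermidis` = pct(sum(iso == "S. epidermidis"), length(iso)),
      `C. acnes` = pct(sum(iso == "C. acnes"), length(iso)),
      `E. faecalis` = pct(sum(iso == "E. faecalis"), length(iso))),
    n_polymicrobial = sum(!is.na(fx$isolate_2) & fx$isolate_2 != ""),
    n_second_stage = n_second,
    n_culture_positive = pos,
    microbiological_cure_pct = pct(n_second - pos, n_second),
    clinical_cure_pct = pct(sum(fx$clinical_cure == 1), n),
    age = med_iqi(fx$age),
    prior_iv_days = med_iqi(fx$prior_iv_days),
    interval_days = med_iqi(fx$interval_days[second]),
    follow_up_days = med_iqi(fx$follow_up_days[second]))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d female (%.1f%%)\n", x$n_patients,
              x$n_female, x$pct_female))
  cat("Joints:", paste(sprintf("%s %d", names(x$joints), x$joints),
                       collapse = ", "), "\n")
  cat(sprintf("Isolates (n = %d): CoNS %d (%.1f%%), S. epidermidis %d, C. acnes %d, E. faecalis %d; polymicrobial %d\n",
              x$n_isolates, x$isolate_counts["CoNS"], x$isolate_pct["CoNS"],
              x$isolate_counts["S. epidermidis"],
              x$isolate_counts["C. acnes"], x$isolate_counts["E. faecalis"],
              x$n_polymicrobial))
  cat(sprintf("Second-stage surgery %d/%d; positive cultures %d\n",
              x$n_second_stage, x$n_patients, x$n_culture_positive))
  cat(sprintf("Microbiological cure %.1f%%; clinical cure %.1f%%\n",
              x$microbiological_cure_pct, x$clinical_cure_pct))
  cat(sprintf("Age %.1f (IQI %.0f-%.0f); prior IV %.1f d (%.0f-%.0f); surgery interval %.0f d (%.0f-%.0f); follow-up %.0f d (%.0f-%.0f)\n",
              x$age[1], x$age[2], x$age[3],
              x$prior_iv_days[1], x$prior_iv_days[2], x$prior_iv_days[3],
              x$interval_days[1], x$interval_days[2], x$interval_days[3],
              x$follow_up_days[1], x$follow_up_days[2], x$follow_up_days[3]))
  invisible(x)
}
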