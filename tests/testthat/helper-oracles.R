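# Independent oracles and small fixture builders used across the suite.

# inline one-compartment infusion closed form, written independently of the
# package internals (vectorised over t)
conc1_oracle <- function(V, CL, amt, dur, t) {
  k <- CL / V
  R0 <- amt / dur
  a <- pmin(pmax(t, 0), dur)
  w <- pmax(t - dur, 0)
  (R0 / CL) * (1 - exp(-k * a)) * exp(-k * w)
}

# numerical ODE solution dA/dt = R0*1{t<=dur} - k*A, C = A/V (deSolve)
ode_conc <- function(V, CL, amt, dur, times) {
  rhs <- function(t, A, p) {
    list(ifelse(t <= dur, amt / dur, 0) - (CL / V) * A)
  }
  tt <- sort(unique(c(0, dur, times)))
  out <- deSolve::lsoda(c(A = 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  out[match(times, out[, "time"]), "A"] / V
}

# two-compartment ODE oracle
ode_conc2 <- function(V1, CL, Q, V2, amt, dur, times) {
  rhs <- function(t, A, p) {
    c1 <- A[1] / V1; c2 <- A[2] / V2
    list(c(ifelse(t <= dur, amt / dur, 0) - CL * c1 - Q * (c1 - c2),
           Q * (c1 - c2)))
  }
  tt <- sort(unique(c(0, dur, times)))
  out <- deSolve::lsoda(c(A1 = 0, A2 = 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  out[match(times, out[, "time"]), "A1"] / V1
}

# trapezoidal AUC oracle on a fine grid
trap_auc <- function(V, CL, amt, dur, t1, t2, step = 0.01) {
  tt <- seq(t1, t2, by = step)
  cc <- conc1_oracle(V, CL, amt, dur, tt)
  sum((cc[-1] + cc[-length(cc)]) / 2) * step
}

# small sparse dataset built by hand (no generator) for toy problems
make_toy_dataset <- function(n_subj, times_list, pop, seed) {
  set.seed(seed)
  doses <- data.frame(id = seq_len(n_subj), time = 0, amt = 1500, dur = 0.5)
  obs <- lapply(seq_len(n_subj), function(i) {
    eta <- rnorm(2, 0, pop$omega)
    V <- pop$fixed[["V"]] * exp(eta[1])
    CL <- pop$fixed[["CL"]] * exp(eta[2])
    tt <- times_list[[min(i, length(times_list))]]
    f <- conc1_oracle(V, CL, 1500, 0.5, tt)
    data.frame(id = i, time = tt, dv = f * (1 + pop$b * rnorm(length(tt))))
  })
  pk_dataset(do.call(rbind, obs), doses)
}

# dataset with a genuine covariate effect on CL: CL_i = CL_pop *
# (crcl_i / median)^beta * exp(eta)
make_cov_dataset <- function(n_subj, beta_crcl = 0, pop = dalbavancin_model(),
                             seed = 1) {
  set.seed(seed)
  crcl <- pmin(pmax(rnorm(n_subj, 75, 20), 30), 130)
  ref <- median(crcl)
  age <- round(runif(n_subj, 62, 88))
  weight <- round(rnorm(n_subj, 72, 10))
  covs <- data.frame(id = seq_len(n_subj), crcl = crcl, age = age,
                     weight = weight)
  doses <- data.frame(id = seq_len(n_subj), time = 0, amt = 1500, dur = 0.5)
  obs <- lapply(seq_len(n_subj), function(i) {
    eta <- rnorm(2, 0, pop$omega)
    V <- pop$fixed[["V"]] * exp(eta[1])
    CL <- pop$fixed[["CL"]] * (crcl[i] / ref)^beta_crcl * exp(eta[2])
    tt <- sort(sample(seq(200, 700, by = 24), 3))
    f <- conc1_oracle(V, CL, 1500, 0.5, tt)
    data.frame(id = i, time = tt, dv = f * (1 + pop$b * rnorm(length(tt))))
  })
  pk_dataset(do.call(rbind, obs), doses, covs)
}

fast_ctl <- function(...) {
  saem_control(n_explore = 150L, n_smooth = 75L, rse_method = "none", ...)
}
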