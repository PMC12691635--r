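#' Structural pharmacokinetic models
#'
#' Constructors for the closed-form intravenous-infusion structural models
#' used throughout the package. Disposition is represented as a sum of
#' exponential terms, so that the unit-bolus concentration is
#' \eqn{C(t) = \sum_m c_m e^{-\lambda_m t}}; zero-order infusion input and
#' windowed AUC then have exact piecewise-analytic solutions shared by all
#' models.
#'
#' @details
#' `one_compartment()` has parameters `V` (volume of distribution, L) and
#' `CL` (clearance, L/h), with elimination rate `k = CL/V`.
#' `two_compartment()` adds inter-compartmental clearance `Q` (L/h) and
#' peripheral volume `V2` (L); its two disposition rates are the usual
#' macro-constants \eqn{\alpha,\beta}.
#'
#' @return An object of class `pk_model`: a list with the model `name`,
#'   parameter names `pnames`, parameter count `npar`, and a vectorised
#'   `terms(P)` function mapping a parameter matrix (one row per individual)
#'   to exponential coefficients and rates.
#' @examples
#' m <- one_compartment()
#' concentration_at(c(V = 17.9, CL = 0.036), dose_event(1500, 0, 0.5), 504)
#' @export
one_compartment <- function() {
  structure(list(
    name = "one-compartment IV infusion",
    pnames = c("V", "CL"),
    npar = 2L,
    terms = function(P) {
      V <- P[, 1L]
      CL <- P[, 2L]
      list(coef = cbind(1 / V), rate = cbind(CL / V))
    }
  ), class = "pk_model")
}

#' @rdname one_compartment
#' @export
two_compartment <- function() {
  structure(list(
    name = "two-compartment IV infusion",
    pnames = c("V", "CL", "Q", "V2"),
    npar = 4L,
    terms = function(P) {
      V1 <- P[, 1L]; CL <- P[, 2L]; Q <- P[, 3L]; V2 <- P[, 4L]
      k10 <- CL / V1; k12 <- Q / V1; k21 <- Q / V2
      s <- k10 + k12 + k21
      disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
      alpha <- (s + disc) / 2
      beta <- (s - disc) / 2
      dd <- alpha - beta
      # guard the (numerically) degenerate alpha == beta case
      dd[dd < 1e-12] <- 1e-12
      list(
        coef = cbind((alpha - k21) / (dd * V1), (k21 - beta) / (dd * V1)),
        rate = cbind(alpha, beta)
      )
    }
  ), class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Structural PK model:", x$name, "\n")
  cat("Parameters:", paste(x$pnames, collapse = ", "), "\n")
  invisible(x)
}

#' Dosing events
#'
#' A dosing record: amount infused (mg), start time (h) and infusion
#' duration (h). Several events may be stacked into one data frame;
#' concentration and AUC are computed by superposition.
#'
#' @param amount dose amount in mg (non-negative).
#' @param time infusion start time in h (non-negative).
#' @param duration infusion duration in h (strictly positive).
#' @return A data frame with columns `time`, `amt`, `dur`.
#' @export
dose_event <- function(amount, time = 0, duration = 0.5) {
  if (any(amount < 0)) stop("dose amount must be >= 0")
  if (any(time < 0)) stop("dose start time must be >= 0")
  if (any(duration <= 0)) stop("infusion duration must be > 0")
  data.frame(time = time, amt = amount, dur = duration)
}

.check_doses <- function(doses) {
  if (is.null(doses) || NROW(doses) == 0L) {
    return(data.frame(time = numeric(), amt = numeric(), dur = numeric()))
  }
  stopifnot(all(c("time", "amt", "dur") %in% names(doses)))
  if (any(doses$amt < 0) || any(doses$time < 0) || any(doses$dur <= 0)) {
    stop("invalid dose event: need amt >= 0, time >= 0, dur > 0")
  }
  doses
}

.check_params <- function(params, model) {
  p <- unlist(params)[model$pnames]
  if (anyNA(p)) stop("parameters must include ", paste(model$pnames, collapse = ", "))
  if (any(p <= 0)) stop("structural parameters must be strictly positive")
  p
}

# Piecewise closed form for one exponential-terms row set.
# coef, rate: n x m matrices; tsince: length-n time since dose start;
# R0: infusion rate (amt/dur); dur: infusion duration. Returns length-n
# concentration contributions.
.conc_terms <- function(coef, rate, R0, tsince, dur) {
  a <- pmin(pmax(tsince, 0), dur)     # infused-time reached
  w <- pmax(tsince - dur, 0)          # washout time since infusion end
  g <- (1 - exp(-rate * a)) * exp(-rate * w)
  rowSums(R0 * coef / rate * g)
}

# Cumulative AUC from dose start to tsince (supports tsince = Inf).
.cumauc_terms <- function(coef, rate, R0, tsince, dur) {
  a <- pmin(pmax(tsince, 0), dur)
  w <- pmax(tsince - dur, 0)
  e_a <- 1 - exp(-rate * a)
  e_w <- 1 - exp(-rate * w)
  rowSums(R0 * coef / rate * (a - e_a / rate + e_a * e_w / rate))
}

#' Concentration-time profile of the closed-form infusion model
#'
#' Total plasma concentration at time `t` for an individual with parameters
#' `params` receiving the dosing events `doses`, by superposition of the
#' exact zero-order-infusion / first-order-elimination solution.
#'
#' @param params named vector or list of individual parameters (for the
#'   default one-compartment model, `V` in L and `CL` in L/h).
#' @param doses a data frame of dosing events (see [dose_event()]); may be
#'   empty, giving zero concentration.
#' @param t vector of times (h), all non-negative.
#' @param model a [one_compartment()] or [two_compartment()] model object.
#' @return Vector of total concentrations (mg/L), continuous in `t`.
#' @export
concentration_at <- function(params, doses, t, model = one_compartment()) {
  if (any(t < 0)) stop("time must be >= 0")
  doses <- .check_doses(doses)
  p <- .check_params(params, model)
  out <- numeric(length(t))
  if (nrow(doses) == 0L) return(out)
  tm <- model$terms(matrix(p, nrow = 1L))
  for (i in seq_len(nrow(doses))) {
    coef <- matrix(tm$coef, length(t), ncol(tm$coef), byrow = TRUE)
    rate <- matrix(tm$rate, length(t), ncol(tm$rate), byrow = TRUE)
    out <- out + .conc_terms(coef, rate, doses$amt[i] / doses$dur[i],
                             t - doses$time[i], doses$dur[i])
  }
  out
}

#' Windowed area under the concentration-time curve
#'
#' Exact analytic integral of the closed-form total-concentration profile
#' over `[t1, t2]`; additive over adjacent windows. `t2 = Inf` gives the
#' infinite-horizon exposure, which equals (total amount)/CL for the
#' one-compartment model.
#'
#' @inheritParams concentration_at
#' @param t1,t2 window bounds in h, `0 <= t1 <= t2` (`t2` may be `Inf`).
#' @return AUC in mg·h/L.
#' @export
auc_window <- function(params, doses, t1, t2, model = one_compartment()) {
  if (t1 < 0) stop("t1 must be >= 0")
  if (t2 < t1) stop("t2 must be >= t1")
  doses <- .check_doses(doses)
  p <- .check_params(params, model)
  if (nrow(doses) == 0L || t1 == t2) return(0)
  tm <- model$terms(matrix(p, nrow = 1L))
  total <- 0
  for (i in seq_len(nrow(doses))) {
    cum <- function(t) {
      .cumauc_terms(tm$coef, tm$rate, doses$amt[i] / doses$dur[i],
                    t - doses$time[i], doses$dur[i])
    }
    total <- total + (cum(t2) - cum(t1))
  }
  total
}

#' Unbound fraction from a protein-binding percentage
#'
#' @param protein_binding_percent percent bound, in \\[0, 100\\].
#' @return Unbound fraction `(100 - binding)/100`.
#' @examples
#' unbound_fraction(93) # 0.07
#' @export
unbound_fraction <- function(protein_binding_percent) {
  if (any(protein_binding_percent < 0 | protein_binding_percent > 100)) {
    stop("protein binding must be between 0 and 100 percent")
  }
  (100 - protein_binding_percent) / 100
}

#' Proportional residual-error model
#'
#' Applies the proportional residual-error model
#' \eqn{y = f (1 + b \epsilon)} with a supplied standard-normal draw; used
#' by both the simulator and the estimation likelihood.
#'
#' @param pred model-predicted concentration (mg/L), non-negative.
#' @param b proportional error magnitude (dimensionless, non-negative).
#' @param noise standard-normal draw(s).
#' @return Perturbed concentration(s).
#' @export
apply_residual_error <- function(pred, b, noise) {
  if (any(pred < 0)) stop("pred must be >= 0")
  if (any(b < 0)) stop("b must be >= 0")
  pred * (1 + b * noise)
}

# ---- internal vectorised prediction over a stacked design ----------------

# Build the expanded (observation x dose) design used by the estimation and
# simulation machinery. obs: data.frame(id_index, time); doses:
# data.frame(id_index, time, amt, dur). Observation rows must be grouped by
# subject. Returns a list consumed by .predict_design().
.build_design <- function(obs, doses) {
  m <- merge(data.frame(obs_id = seq_len(nrow(obs)), subj = obs$id_index,
                        t = obs$time),
             data.frame(subj = doses$id_index, dt = doses$time,
                        amt = doses$amt, dur = doses$dur),
             by = "subj")
  m <- m[order(m$obs_id), , drop = FALSE]
  list(obs_id = m$obs_id, subj = m$subj, tsince = m$t - m$dt,
       R0 = m$amt / m$dur, dur = m$dur, n_obs = nrow(obs))
}

# Predict concentrations for every observation given a parameter matrix P
# (one row per subject index used in the design).
.predict_design <- function(model, P, ex) {
  if (length(ex$obs_id) == 0L) return(numeric(0))
  tm <- model$terms(P[ex$subj, , drop = FALSE])
  contrib <- .conc_terms(tm$coef, tm$rate, ex$R0, ex$tsince, ex$dur)
  out <- numeric(ex$n_obs)
  agg <- rowsum(contrib, ex$obs_id)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
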