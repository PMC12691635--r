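# Renal-function / body-size covariate formulas and the stepwise
# forward-inclusion / backward-elimination covariate search.

#' Cockcroft-Gault creatinine clearance
#'
#' `CrCL = (140 - age) * weight / (72 * scr)`, multiplied by 0.85 for
#' females. Units: mL/min.
#'
#' @param age years; `weight` kg; `scr` serum creatinine in mg/dL;
#'   `sex` `"F"`/`"M"` (or a factor with those levels).
#' @param weight,scr,sex see above.
#' @return CrCL in mL/min.
#' @examples
#' crcl_cockcroft_gault(40, 72, 1.0, "M") # 100
#' @export
crcl_cockcroft_gault <- function(age, weight, scr, sex) {
  if (any(scr <= 0)) stop("serum creatinine must be > 0")
  if (any(age <= 0) || any(weight <= 0)) stop("age and weight must be > 0")
  f <- ifelse(toupper(as.character(sex)) %in% c("F", "FEMALE"), 0.85, 1)
  (140 - age) * weight / (72 * scr) * f
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The 2009 creatinine equation with sex-specific kappa and alpha; the
#' race coefficient is omitted. Units: mL/min/1.73 m^2.
#'
#' @param scr serum creatinine in mg/dL; `age` years; `sex` `"F"`/`"M"`.
#' @param age,sex see above.
#' @return eGFR in mL/min/1.73 m^2; strictly decreasing in `scr`.
#' @export
egfr_ckd_epi <- function(scr, age, sex) {
  if (any(scr <= 0) || any(age <= 0)) stop("scr and age must be > 0")
  female <- toupper(as.character(sex)) %in% c("F", "FEMALE")
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1)
}

#' Body mass index
#'
#' @param weight kg; `height` cm.
#' @param height see above.
#' @return BMI in kg/m^2.
#' @export
body_mass_index <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) stop("weight and height must be > 0")
  weight / (height / 100)^2
}

#' Stepwise covariate search
#'
#' Forward-inclusion / backward-elimination search over candidate
#' (parameter x covariate) pairs. Forward: at each step the candidate with
#' the largest objective-function drop exceeding the chi-square(1)
#' threshold at `forward_alpha` enters the model. Backward: covariates
#' whose removal worsens the OFV by less than the threshold at
#' `backward_alpha` are eliminated, least significant first. Continuous
#' covariates enter as power functions normalised to the cohort median,
#' categorical ones as proportional factors. Ties in OFV drop are broken
#' by the larger IIV reduction, then alphabetically.
#'
#' All candidate OFVs are importance-sampling estimates computed with a
#' common seed (common random numbers across models, which keeps OFV
#' differences stable well below the decision thresholds).
#'
#' @param data a [pk_dataset()] carrying covariate columns.
#' @param base_fit a converged `saem_fit` of the structural model.
#' @param candidates data frame with columns `param`, `covariate`
#'   (defaults to every structural parameter crossed with every covariate
#'   column).
#' @param forward_alpha,backward_alpha significance levels (chi-square,
#'   1 df); defaults 0.05 forward and 0.01 backward.
#' @param control [saem_control()] for candidate fits (default: the base
#'   fit's control without RSE computation).
#' @param n_is importance-sampling size for candidate OFVs.
#' @param seed integer seed.
#' @return An object of class `covariate_search`: the final fit, retained
#'   covariates and a complete decision log (every tested pair with its
#'   OFV drop, IIV reduction and decision, plus a manual-review
#'   plausibility column).
#' @export
stepwise_covariates <- function(data, base_fit, candidates = NULL,
                                forward_alpha = 0.05, backward_alpha = 0.01,
                                control = NULL, n_is = 2000L, seed = 1L) {
  stopifnot(inherits(base_fit, "saem_fit"))
  if (!base_fit$converged) warning("base fit flagged as non-converged")
  if (is.null(data$covariates)) stop("dataset carries no covariates")
  if (is.null(candidates)) {
    covs <- setdiff(names(data$covariates), "id")
    candidates <- expand.grid(param = base_fit$model$pnames,
                              covariate = covs, stringsAsFactors = FALSE)
  }
  if (is.null(control)) {
    control <- base_fit$control
    control$rse_method <- "none"
    control$compute_ll <- FALSE
  }
  thr_f <- stats::qchisq(1 - forward_alpha, 1)
  thr_b <- stats::qchisq(1 - backward_alpha, 1)
  is_seed <- seed + 1000L

  fit_with <- function(terms) {
    cv <- if (length(terms)) {
      lapply(terms, function(tt) list(param = tt$param,
                                      covariate = tt$covariate))
    }
    f <- saem(data, model = base_fit$model, init = base_fit$estimates,
              covariates = cv, control = control, seed = seed)
    f$ofv <- compute_ofv(f, n_is = n_is, seed = is_seed)$ofv
    f
  }

  base <- base_fit
  if (is.null(base$ofv)) {
    base$ofv <- compute_ofv(base, n_is = n_is, seed = is_seed)$ofv
  }
  current <- list()
  cur_fit <- base
  log <- list()
  step <- 0L
  key <- function(tt) paste0(tt$covariate, "_on_", tt$param)

  # ---- forward inclusion
  repeat {
    step <- step + 1L
    in_model <- vapply(current, key, "")
    cand_rows <- candidates[!paste0(candidates$covariate, "_on_",
                                    candidates$param) %in% in_model, ,
                            drop = FALSE]
    if (!nrow(cand_rows)) break
    trial <- vector("list", nrow(cand_rows))
    for (r in seq_len(nrow(cand_rows))) {
      tt <- list(param = cand_rows$param[r],
                 covariate = cand_rows$covariate[r])
      f <- tryCatch(fit_with(c(current, list(tt))), error = function(e) e)
      if (inherits(f, "error")) {
        log[[length(log) + 1L]] <- data.frame(
          step = step, phase = "forward", parameter = tt$param,
          covariate = tt$covariate, ofv = NA_real_, delta_ofv = NA_real_,
          threshold = thr_f, omega_reduction = NA_real_,
          action = paste("skipped:", conditionMessage(f)),
          plausibility = "review")
        trial[[r]] <- NULL
        next
      }
      j <- match(tt$param, base_fit$model$pnames)
      dom <- cur_fit$estimates$omega[j] - f$estimates$omega[j]
      trial[[r]] <- list(term = tt, fit = f,
                         delta = cur_fit$ofv - f$ofv, dom = dom)
      log[[length(log) + 1L]] <- data.frame(
        step = step, phase = "forward", parameter = tt$param,
        covariate = tt$covariate, ofv = f$ofv,
        delta_ofv = cur_fit$ofv - f$ofv, threshold = thr_f,
        omega_reduction = dom, action = "tested", plausibility = "review")
    }
    trial <- trial[!vapply(trial, is.null, TRUE)]
    sig <- Filter(function(tr) tr$delta > thr_f, trial)
    if (!length(sig)) break
    ord <- order(-vapply(sig, `[[`, 0, "delta"),
                 -vapply(sig, `[[`, 0, "dom"),
                 vapply(sig, function(tr) key(tr$term), ""))
    pick <- sig[[ord[1]]]
    current <- c(current, list(pick$term))
    cur_fit <- pick$fit
    log[[length(log) + 1L]] <- data.frame(
      step = step, phase = "forward", parameter = pick$term$param,
      covariate = pick$term$covariate, ofv = pick$fit$ofv,
      delta_ofv = pick$delta, threshold = thr_f,
      omega_reduction = pick$dom, action = "included",
      plausibility = "review")
  }

  # ---- backward elimination
  repeat {
    if (!length(current)) break
    step <- step + 1L
    worst <- NULL
    for (r in seq_along(current)) {
      reduced <- current[-r]
      f <- tryCatch(fit_with(reduced), error = function(e) NULL)
      if (is.null(f)) next
      delta <- f$ofv - cur_fit$ofv   # worsening caused by removal
      log[[length(log) + 1L]] <- data.frame(
        step = step, phase = "backward", parameter = current[[r]]$param,
        covariate = current[[r]]$covariate, ofv = f$ofv,
        delta_ofv = delta, threshold = thr_b,
        omega_reduction = NA_real_, action = "tested",
        plausibility = "review")
      if (delta < thr_b && (is.null(worst) || delta < worst$delta)) {
        worst <- list(r = r, fit = f, delta = delta)
      }
    }
    if (is.null(worst)) break
    log[[length(log) + 1L]] <- data.frame(
      step = step, phase = "backward",
      parameter = current[[worst$r]]$param,
      covariate = current[[worst$r]]$covariate, ofv = worst$fit$ofv,
      delta_ofv = worst$delta, threshold = thr_b,
      omega_reduction = NA_real_, action = "removed",
      plausibility = "review")
    current <- current[-worst$r]
    cur_fit <- worst$fit
  }

  structure(list(final_fit = cur_fit,
                 retained = if (length(current)) {
                   do.call(rbind, lapply(current, function(tt) {
                     data.frame(parameter = tt$param,
                                covariate = tt$covariate)
                   }))
                 } else {
                   data.frame(parameter = character(),
                              covariate = character())
                 },
                 log = do.call(rbind, log),
                 base_ofv = base$ofv, final_ofv = cur_fit$ofv,
                 forward_alpha = forward_alpha,
                 backward_alpha = backward_alpha),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  if (nrow(x$retained)) {
    cat("Retained covariate effects:\n")
    print(x$retained, row.names = FALSE)
  } else {
    cat("No covariate retained: the structural model stands.\n")
  }
  cat(sprintf("OFV %.2f -> %.2f; %d decisions logged\n", x$base_ofv,
              x$final_ofv, nrow(x$log)))
  invisible(x)
}

#' @rdname stepwise_covariates
#' @param x a `covariate_search`.
#' @param path TSV output path for the decision log.
#' @export
write_decision_log <- function(x, path) {
  stopifnot(inherits(x, "covariate_search"))
  utils::write.table(x$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
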