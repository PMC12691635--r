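#' SAEM control settings
#'
#' Tuning parameters of the stochastic approximation EM estimator. The
#' defaults (500 exploration + 200 smoothing iterations, 2 Markov chains)
#' suit sparse datasets of a few dozen subjects; bootstrap refits use a
#' reduced budget.
#'
#' @param n_explore iterations of the exploration phase (step size 1).
#' @param n_smooth iterations of the smoothing phase (step size
#'   \eqn{(k - K_1)^{-0.7}} by default).
#' @param n_chains number of MCMC chains per subject.
#' @param step_power exponent of the smoothing-phase step-size decay.
#' @param anneal per-iteration floor factor on variance components during
#'   exploration (simulated-annealing style guard against premature
#'   collapse of \eqn{\omega} and `b`).
#' @param fix_omega optional named vector fixing IIV standard deviations
#'   (a value of 0 removes the random effect from that parameter).
#' @param compute_ll if `TRUE`, compute the importance-sampling OFV, AIC
#'   and BICc after fitting.
#' @param n_is importance-sampling size for the likelihood estimate.
#' @param rse_method `"louis"` (stochastic Fisher information on the MCMC
#'   chain), `"fd"` (finite differences of the adaptive-quadrature marginal
#'   likelihood), or `"none"`.
#' @param rse_samples posterior draws per subject for the Louis estimator.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_explore = 500L, n_smooth = 200L, n_chains = 2L,
                         step_power = 0.7, anneal = 0.95, fix_omega = NULL,
                         compute_ll = FALSE, n_is = 5000L,
                         rse_method = c("louis", "fd", "none"),
                         rse_samples = 300L) {
  structure(list(n_explore = as.integer(n_explore),
                 n_smooth = as.integer(n_smooth),
                 n_chains = as.integer(n_chains),
                 step_power = step_power, anneal = anneal,
                 fix_omega = fix_omega, compute_ll = compute_ll,
                 n_is = as.integer(n_is),
                 rse_method = match.arg(rse_method),
                 rse_samples = as.integer(rse_samples)),
            class = "saem_control")
}

.OMEGA_FLOOR <- 1e-4

# ---- estimation scaffolding ----------------------------------------------

# Prepare the estimation problem: index included subjects (>= 1 non-BLQ
# observation), stack their usable observations, build the expanded
# prediction design and per-parameter covariate design matrices.
.prep_estimation <- function(data, model, covariates = NULL) {
  stopifnot(inherits(data, "pk_dataset"))
  if (length(data$ids) == 0L) stop("empty dataset: nothing to estimate")
  usable <- data$obs[!data$obs$blq & !is.na(data$obs$dv), , drop = FALSE]
  inc <- intersect(data$ids, unique(usable$id))
  if (length(inc) == 0L) stop("no subject has a quantifiable observation")
  dropped <- setdiff(data$ids, inc)
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " subject(s) without quantifiable observations: ",
            paste(dropped, collapse = ", "))
  }
  usable <- usable[usable$id %in% inc, , drop = FALSE]
  obs <- data.frame(id_index = match(usable$id, inc), time = usable$time)
  o <- order(obs$id_index, obs$time)
  obs <- obs[o, , drop = FALSE]
  y <- usable$dv[o]
  dos <- data$doses[data$doses$id %in% inc, , drop = FALSE]
  doses <- data.frame(id_index = match(dos$id, inc), time = dos$time,
                      amt = dos$amt, dur = dos$dur)
  ex <- .build_design(obs, doses)
  N <- length(inc)
  d <- model$npar
  # covariate design matrices: phi_j = X_j beta_j + eta_j
  X <- vector("list", d)
  xnames <- vector("list", d)
  for (j in seq_len(d)) {
    X[[j]] <- matrix(1, N, 1L)
    xnames[[j]] <- "(Intercept)"
  }
  cov_spec <- list()
  if (!is.null(covariates) && length(covariates)) {
    if (is.null(data$covariates)) stop("dataset carries no covariates")
    cv <- data$covariates[match(inc, data$covariates$id), , drop = FALSE]
    for (term in covariates) {
      j <- match(term$param, model$pnames)
      if (is.na(j)) stop("unknown parameter in covariate model: ", term$param)
      v <- cv[[term$covariate]]
      if (is.null(v)) stop("covariate not in dataset: ", term$covariate)
      if (is.numeric(v)) {
        ref <- if (!is.null(term$ref)) term$ref else stats::median(v)
        col <- log(v / ref)
        form <- "power"
      } else {
        lev <- sort(unique(as.character(v)))
        ref <- lev[1L]
        col <- as.numeric(as.character(v) != ref)
        form <- "proportional"
      }
      X[[j]] <- cbind(X[[j]], col)
      xnames[[j]] <- c(xnames[[j]],
                       paste0(term$covariate, "_on_", term$param))
      cov_spec[[length(cov_spec) + 1L]] <-
        list(param = term$param, covariate = term$covariate,
             form = form, ref = ref)
    }
  }
  for (j in seq_len(d)) colnames(X[[j]]) <- xnames[[j]]
  list(ids = inc, N = N, d = d, obs = obs, y = y, doses = doses, ex = ex,
       obs_subj = obs$id_index, n_obs = length(y), X = X,
       cov_spec = cov_spec, model = model)
}

# per-subject observation log-likelihood (proportional error)
.llo_by_subject <- function(prep, f, b) {
  sdv <- b * pmax(f, 1e-12)
  ll <- stats::dnorm(prep$y, f, sdv, log = TRUE)
  ll[f <= 0 & prep$y > 0] <- -Inf
  as.numeric(rowsum(ll, prep$obs_subj))
}

.phi_from <- function(prep, beta, eta) {
  phi <- eta
  for (j in seq_len(prep$d)) phi[, j] <- phi[, j] + prep$X[[j]] %*% beta[[j]]
  phi
}

# naive pooled initialisation: terminal slope for CL/V, back-extrapolated
# intercept for V
.init_popmodel <- function(data, model) {
  usable <- data$obs[!data$obs$blq & !is.na(data$obs$dv) & data$obs$dv > 0, ]
  mean_dose <- mean(tapply(data$doses$amt, data$doses$id, sum))
  k <- 0.002; C0 <- mean_dose / 20
  if (nrow(usable) >= 2 && stats::sd(usable$time) > 0) {
    fit <- stats::lm(log(dv) ~ time, data = usable)
    if (is.finite(stats::coef(fit)[2]) && stats::coef(fit)[2] < 0) {
      k <- -stats::coef(fit)[2]
      C0 <- exp(stats::coef(fit)[1])
    }
  } else if (nrow(usable) >= 1) {
    C0 <- max(usable$dv)
  }
  V <- min(max(mean_dose / C0, 1), 1000)
  CL <- min(max(k * V, 1e-4), 100)
  fixed <- switch(model$npar - 1L,
                  c(V = V, CL = CL),                       # one-compartment
                  NULL,
                  c(V = 0.7 * V, CL = CL, Q = 2 * CL, V2 = 0.7 * V))
  popmodel(fixed = fixed,
           omega = stats::setNames(rep(0.3, model$npar), model$pnames),
           b = 0.2, model = model)
}

# ---- the SAEM estimator --------------------------------------------------

#' Fit a population PK model by the SAEM algorithm
#'
#' Maximum-likelihood estimation of a nonlinear mixed-effects model from
#' sparse concentration data by stochastic approximation EM: a random-walk
#' Metropolis E-step samples each subject's random effects, and a
#' stochastic-approximation M-step updates the population parameters from
#' the accumulated sufficient statistics. Individual parameters are
#' log-normal (estimation operates on log parameters, enforcing
#' positivity), residual error is proportional, and the random-effect
#' covariance is diagonal.
#'
#' If every IIV standard deviation is fixed at zero (via
#' `saem_control(fix_omega = )`) the model has no latent variables and the
#' fixed effects and error magnitude are instead estimated by direct
#' maximum likelihood.
#'
#' @param data a [pk_dataset()]. Subjects need at least one quantifiable
#'   (non-BLQ) observation to enter the likelihood; others are dropped with
#'   a message.
#' @param model structural model, [one_compartment()] (default) or
#'   [two_compartment()].
#' @param init optional [popmodel()] (or list with elements `fixed`,
#'   `omega`, `b`) of starting values; defaults to a naive pooled
#'   back-extrapolation/terminal-slope heuristic.
#' @param covariates optional covariate model: a list of terms
#'   `list(param =, covariate =, ref =)`, each adding a power function of a
#'   continuous covariate (normalised to `ref`, default the cohort median)
#'   or a proportional factor for a categorical one, on the named
#'   structural parameter.
#' @param control a [saem_control()] list.
#' @param seed integer seed; the fit is fully reproducible given the seed.
#' @return An object of class `saem_fit` with components `estimates` (a
#'   [popmodel()]), `beta` (covariate coefficients), `ebe` (empirical Bayes
#'   modes of the random effects), `shrinkage`, `rse` (percent, when
#'   computed), `trace` (per-iteration parameter path), `converged`,
#'   `flags`, and (when computed) `ofv`, `aic`, `bicc`.
#' @seealso [compute_ofv()], [rse()], [pk_bootstrap()], [npde()],
#'   [pc_vpc()], [select_structural_model()]
#' @examples
#' truth <- dalbavancin_model()
#' dat <- generate_pk_dataset(study_design(n_subjects = 6), truth, seed = 1)
#' fit <- saem(dat, control = saem_control(n_explore = 60, n_smooth = 30,
#'                                         rse_method = "none"), seed = 1)
#' coef(fit)
#' @export
saem <- function(data, model = one_compartment(), init = NULL,
                 covariates = NULL, control = saem_control(), seed = 1L) {
  cl <- match.call()
  prep <- .prep_estimation(data, model, covariates)
  if (is.null(init)) init <- .init_popmodel(data, model)
  if (!inherits(init, "popmodel")) {
    init <- popmodel(init$fixed, init$omega, init$b, model = model)
  }
  d <- prep$d; N <- prep$N
  fix <- rep(NA_real_, d); names(fix) <- model$pnames
  if (!is.null(control$fix_omega)) fix[names(control$fix_omega)] <- control$fix_omega
  omega <- init$omega
  omega[!is.na(fix)] <- fix[!is.na(fix)]
  if (all(!is.na(fix)) && all(fix == 0)) {
    return(.fit_fixed_effects(data, prep, init, control, seed, cl))
  }
  omega_int <- pmax(omega, .OMEGA_FLOOR)   # internal (floored) scale
  b <- max(init$b, 1e-3)
  set.seed(seed)

  beta <- lapply(seq_len(d), function(j) {
    c(log(init$fixed[j]), rep(0, ncol(prep$X[[j]]) - 1L))
  })
  XtXi <- lapply(prep$X, function(x) solve(crossprod(x)))
  nch <- control$n_chains
  # chain state: individual log-parameters phi (the data likelihood depends
  # on phi only, so M-step updates of the population parameters never
  # invalidate the cached predictions)
  Xb <- function() {
    xb <- matrix(0, N, d)
    for (j in seq_len(d)) xb[, j] <- prep$X[[j]] %*% beta[[j]]
    xb
  }
  xb <- Xb()
  phi_ch <- replicate(nch, xb, simplify = FALSE)
  prop_sd <- matrix(pmax(omega_int, 0.1), N, d, byrow = TRUE)
  f_ch <- vector("list", nch)
  llo_ch <- vector("list", nch)
  for (c in seq_len(nch)) {
    f_ch[[c]] <- .predict_design(model, exp(phi_ch[[c]]), prep$ex)
    llo_ch[[c]] <- .llo_by_subject(prep, f_ch[[c]], b)
  }
  K1 <- control$n_explore; K2 <- control$n_smooth
  Ktot <- K1 + K2
  H1 <- matrix(0, N, d); H2 <- matrix(0, N, d); H3 <- 0
  tr_names <- c(model$pnames,
                unlist(lapply(seq_len(d), function(j) colnames(prep$X[[j]])[-1])),
                paste0("omega_", model$pnames), "b")
  trace <- matrix(NA_real_, Ktot, length(tr_names),
                  dimnames = list(NULL, tr_names))

  for (k in seq_len(Ktot)) {
    s1 <- matrix(0, N, d); s2 <- matrix(0, N, d); s3 <- 0
    for (c in seq_len(nch)) {
      phi <- phi_ch[[c]]
      f <- f_ch[[c]]; llo <- llo_ch[[c]]
      for (j in seq_len(d)) {
        pj <- phi
        pj[, j] <- phi[, j] + stats::rnorm(N) * prop_sd[, j]
        fp <- .predict_design(model, exp(pj), prep$ex)
        llp <- .llo_by_subject(prep, fp, b)
        dlp <- ((phi[, j] - xb[, j])^2 - (pj[, j] - xb[, j])^2) /
          (2 * omega_int[j]^2)
        lacc <- llp - llo + dlp
        lacc[is.na(lacc)] <- 0   # both states impossible: move on
        acc <- log(stats::runif(N)) < lacc
        if (any(acc)) {
          phi[acc, j] <- pj[acc, j]
          sel <- acc[prep$obs_subj]
          f[sel] <- fp[sel]
          llo[acc] <- llp[acc]
        }
        prop_sd[, j] <- prop_sd[, j] * ifelse(acc, 1.08, 0.95)
      }
      phi_ch[[c]] <- phi
      f_ch[[c]] <- f; llo_ch[[c]] <- llo
      s1 <- s1 + phi / nch
      s2 <- s2 + phi^2 / nch
      s3 <- s3 + sum(((prep$y - f) / pmax(f, 1e-12))^2) / nch
    }
    gamma <- if (k <= K1) 1 else (k - K1)^(-control$step_power)
    H1 <- H1 + gamma * (s1 - H1)
    H2 <- H2 + gamma * (s2 - H2)
    H3 <- H3 + gamma * (s3 - H3)
    # M-step
    for (j in seq_len(d)) {
      beta[[j]] <- as.numeric(XtXi[[j]] %*% crossprod(prep$X[[j]], H1[, j]))
      fitj <- as.numeric(prep$X[[j]] %*% beta[[j]])
      if (is.na(fix[j])) {
        w2 <- mean(H2[, j] - 2 * fitj * H1[, j] + fitj^2)
        if (k <= K1) w2 <- max(w2, control$anneal * omega_int[j]^2)
        omega_int[j] <- sqrt(max(w2, .OMEGA_FLOOR^2))
      }
    }
    b2 <- H3 / prep$n_obs
    if (k <= K1) b2 <- max(b2, control$anneal * b^2)
    b <- sqrt(max(b2, 1e-8))
    xb <- Xb()   # population location moved; phi and f remain valid
    # the error magnitude changed: refresh the cached data log-likelihoods
    for (c in seq_len(nch)) {
      llo_ch[[c]] <- .llo_by_subject(prep, f_ch[[c]], b)
    }
    trace[k, ] <- c(exp(vapply(beta, `[`, 0, 1L)),
                    unlist(lapply(beta, `[`, -1L)),
                    omega_int, b)
  }

  omega_out <- omega_int
  omega_out[!is.na(fix)] <- fix[!is.na(fix)]   # report fixed values exactly
  fixed_out <- stats::setNames(exp(vapply(beta, `[`, 0, 1L)), model$pnames)
  est <- popmodel(fixed = fixed_out, omega = omega_out, b = b, model = model)

  fit <- structure(list(
    estimates = est, beta = beta, prep = prep, data = data, model = model,
    control = control, seed = seed, trace = as.data.frame(trace),
    fix_omega = fix, call = cl
  ), class = "saem_fit")
  fit$ebe <- .ebe_modes(fit)
  fit$shrinkage <- shrinkage(fit)
  conv <- .check_convergence(fit)
  fit$converged <- conv$converged
  fit$flags <- conv$flags
  if (control$rse_method != "none") {
    fit$rse <- tryCatch(rse(fit, method = control$rse_method),
                        error = function(e) {
                          fit$flags <- c(fit$flags, paste("RSE failed:",
                                                          conditionMessage(e)))
                          NULL
                        })
    fit$rse_method <- control$rse_method
  }
  if (control$compute_ll) {
    ll <- compute_ofv(fit, n_is = control$n_is, seed = seed + 1L)
    fit$ofv <- ll$ofv; fit$aic <- ll$aic; fit$bicc <- ll$bicc
    fit$ofv_se <- ll$se
  }
  fit
}

# direct ML when the model has no random effects (all omegas fixed at 0)
.fit_fixed_effects <- function(data, prep, init, control, seed, cl) {
  d <- prep$d
  nll <- function(par) {
    beta <- vector("list", d)
    pos <- 0L
    for (j in seq_len(d)) {
      nb <- ncol(prep$X[[j]])
      beta[[j]] <- par[pos + seq_len(nb)]; pos <- pos + nb
    }
    b <- exp(par[length(par)])
    f <- .predict_design(prep$model, exp(.phi_from(prep, beta,
                                                   matrix(0, prep$N, d))),
                         prep$ex)
    if (anyNA(f) || any(f <= 0)) return(1e10)
    val <- -sum(stats::dnorm(prep$y, f, b * f, log = TRUE))
    if (!is.finite(val)) 1e10 else val
  }
  start <- c(unlist(lapply(seq_len(d), function(j) {
    c(log(init$fixed[j]), rep(0, ncol(prep$X[[j]]) - 1L))
  })), log(max(init$b, 1e-3)))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  beta <- vector("list", d); pos <- 0L
  for (j in seq_len(d)) {
    nb <- ncol(prep$X[[j]])
    beta[[j]] <- opt$par[pos + seq_len(nb)]; pos <- pos + nb
  }
  b <- exp(opt$par[length(opt$par)])
  est <- popmodel(stats::setNames(exp(vapply(beta, `[`, 0, 1L)),
                                  prep$model$pnames),
                  omega = NULL, b = b, model = prep$model)
  fit <- structure(list(
    estimates = est, beta = beta, prep = prep, data = data,
    model = prep$model, control = control, seed = seed,
    trace = NULL, fix_omega = stats::setNames(rep(0, d), prep$model$pnames),
    method = "ml-fixed", converged = opt$convergence == 0,
    flags = if (opt$convergence != 0) "optim did not converge" else character(),
    ebe = matrix(0, prep$N, d), shrinkage = stats::setNames(rep(NA_real_, d),
                                                            prep$model$pnames),
    call = cl
  ), class = "saem_fit")
  if (control$compute_ll) {
    ll <- compute_ofv(fit, n_is = control$n_is, seed = seed + 1L)
    fit$ofv <- ll$ofv; fit$aic <- ll$aic; fit$bicc <- ll$bicc
    fit$ofv_se <- ll$se
  }
  fit
}

# Convergence assessment. Hard failures (non-finite estimates, collapsed
# IIV, grossly diverging traces) unset the converged flag; a mild residual
# drift over the last 20% of iterations is reported as a warning flag only,
# as is common practice with stochastic EM traces.
.check_convergence <- function(fit) {
  flags <- character()
  hard <- FALSE
  if (any(!is.finite(coef(fit)))) {
    flags <- c(flags, "non-finite estimates")
    hard <- TRUE
  }
  if (!is.null(fit$trace)) {
    tr <- fit$trace
    tail_n <- max(10L, ceiling(0.2 * nrow(tr)))
    tl <- tr[seq(nrow(tr) - tail_n + 1L, nrow(tr)), , drop = FALSE]
    it <- seq_len(nrow(tl))
    for (nm in colnames(tl)) {
      v <- tl[[nm]]
      if (!all(is.finite(v)) || stats::sd(v) < 1e-12) next
      sl <- stats::coef(stats::lm(v ~ it))[2]
      drift <- abs(sl) * nrow(tl) / max(abs(mean(v)), 1e-8)
      if (is.finite(drift) && drift > 0.5) {
        flags <- c(flags, sprintf("trace of %s diverging (%.0f%% over tail)",
                                  nm, 100 * drift))
        hard <- TRUE
      } else if (is.finite(drift) && drift > 0.10) {
        flags <- c(flags,
                   sprintf("trace of %s still drifting (%.1f%% over tail)",
                           nm, 100 * drift))
      }
    }
  }
  om <- fit$estimates$omega
  est_om <- is.na(fit$fix_omega)
  if (any(est_om & om <= 2 * .OMEGA_FLOOR)) {
    flags <- c(flags, paste("omega collapse:",
                            paste(names(om)[est_om & om <= 2 * .OMEGA_FLOOR],
                                  collapse = ", ")))
    hard <- TRUE
  }
  list(converged = !hard, flags = flags)
}

# ---- S3 methods ----------------------------------------------------------

#' @export
coef.saem_fit <- function(object, ...) {
  est <- object$estimates
  out <- c(est$fixed,
           stats::setNames(est$omega, paste0("omega_", names(est$omega))),
           b = est$b)
  extra <- unlist(lapply(seq_along(object$beta), function(j) {
    bj <- object$beta[[j]][-1L]
    if (length(bj)) stats::setNames(bj, colnames(object$prep$X[[j]])[-1L])
  }))
  c(out, extra)
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("Population PK fit (SAEM), ", x$prep$N, " subjects, ",
      x$prep$n_obs, " observations\n", sep = "")
  print(x$estimates)
  if (!is.null(x$ofv)) {
    cat(sprintf("OFV %.2f  AIC %.2f  BICc %.2f\n", x$ofv, x$aic, x$bicc))
  }
  if (!x$converged) cat("WARNING:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.saem_fit <- function(object, ...) {
  est <- coef(object)
  base <- c(object$model$pnames, paste0("omega_", object$model$pnames), "b")
  tab <- data.frame(parameter = names(est), estimate = as.numeric(est))
  tab$rse_percent <- NA_real_
  if (!is.null(object$rse)) {
    tab$rse_percent[match(names(object$rse), tab$parameter)] <- object$rse
  }
  tab$shrinkage_percent <- NA_real_
  shr <- object$shrinkage
  tab$shrinkage_percent[match(paste0("omega_", names(shr)), tab$parameter)] <- shr
  structure(list(table = tab[tab$parameter %in% base |
                               !tab$parameter %in% base, ],
                 n_subjects = object$prep$N, n_obs = object$prep$n_obs,
                 converged = object$converged, flags = object$flags,
                 ofv = object$ofv, aic = object$aic, bicc = object$bicc),
            class = "summary.saem_fit")
}

#' @export
print.summary.saem_fit <- function(x, ...) {
  cat("Population PK parameter estimates\n")
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$rse_percent <- round(tab$rse_percent, 1)
  tab$shrinkage_percent <- round(tab$shrinkage_percent, 1)
  print(tab, row.names = FALSE)
  cat(sprintf("\n%d subjects, %d observations; converged: %s\n",
              x$n_subjects, x$n_obs, x$converged))
  if (!is.null(x$ofv)) {
    cat(sprintf("OFV %.2f  AIC %.2f  BICc %.2f\n", x$ofv, x$aic, x$bicc))
  }
  invisible(x)
}

#' Predictions from a fitted population PK model
#'
#' @param object an `saem_fit`.
#' @param newdata optional data frame with columns `id`, `time`; defaults
#'   to the fitted observations.
#' @param type `"ipred"` (individual predictions, using the empirical Bayes
#'   random effects) or `"pred"` (population predictions, random effects at
#'   zero).
#' @param ... unused.
#' @return Numeric vector of predicted total concentrations (mg/L).
#' @export
predict.saem_fit <- function(object, newdata = NULL,
                             type = c("ipred", "pred"), ...) {
  type <- match.arg(type)
  prep <- object$prep
  if (is.null(newdata)) {
    obs <- prep$obs
  } else {
    idx <- match(newdata$id, prep$ids)
    if (anyNA(idx)) stop("unknown subject id in newdata")
    obs <- data.frame(id_index = idx, time = newdata$time)
  }
  ex <- .build_design(obs, prep$doses)
  ex$n_obs <- nrow(obs)
  eta <- if (type == "ipred") object$ebe else matrix(0, prep$N, prep$d)
  P <- exp(.phi_from(prep, object$beta, eta))
  .predict_design(object$model, P, ex)
}

#' @export
fitted.saem_fit <- function(object, ...) predict(object, type = "ipred")

#' Individual weighted residuals
#'
#' `IWRES = (DV - IPRED) / (b * IPRED)` under the proportional
#' residual-error model; approximately standard normal when the model fits.
#'
#' @param object an `saem_fit`.
#' @param ... unused.
#' @export
residuals.saem_fit <- function(object, ...) {
  ipred <- predict(object, type = "ipred")
  (object$prep$y - ipred) / (object$estimates$b * pmax(ipred, 1e-12))
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new random effects and residual errors under the fitted (or any)
#' population model, keeping the observed design (subjects, doses,
#' sampling times).
#'
#' @param object an `saem_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` [pk_dataset()] objects.
#' @export
simulate.saem_fit <- function(object, nsim = 1, seed = 1L, ...) {
  sims <- .simulate_replicates(object$prep, object$estimates, nsim, seed)
  lapply(seq_len(nsim), function(k) {
    obs <- data.frame(id = object$prep$ids[object$prep$obs$id_index],
                      time = object$prep$obs$time, dv = sims$y[, k])
    doses <- data.frame(id = object$prep$ids[object$prep$doses$id_index],
                        time = object$prep$doses$time,
                        amt = object$prep$doses$amt,
                        dur = object$prep$doses$dur)
    pk_dataset(obs, doses, object$data$covariates, lloq = object$data$lloq)
  })
}

# K replicate observation vectors under a population model, observed design.
# Returns list(y = n_obs x K matrix, f = n_obs x K, eta = N x d x K).
.simulate_replicates <- function(prep, pop, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- prep$N; d <- prep$d; n <- prep$n_obs
  eta <- array(stats::rnorm(N * d * K), c(N, d, K))
  for (j in seq_len(d)) eta[, j, ] <- eta[, j, ] * pop$omega[j]
  mu <- log(pop$fixed)
  big_subj <- rep(prep$ex$subj, K) + rep((seq_len(K) - 1L) * N,
                                         each = length(prep$ex$subj))
  big_ex <- list(obs_id = rep(prep$ex$obs_id, K) +
                   rep((seq_len(K) - 1L) * n, each = length(prep$ex$obs_id)),
                 subj = big_subj,
                 tsince = rep(prep$ex$tsince, K), R0 = rep(prep$ex$R0, K),
                 dur = rep(prep$ex$dur, K), n_obs = n * K)
  P <- exp(matrix(mu, N * K, d, byrow = TRUE) +
             matrix(aperm(eta, c(1, 3, 2)), N * K, d))
  f <- matrix(.predict_design(prep$model, P, big_ex), n, K)
  y <- f * (1 + pop$b * matrix(stats::rnorm(n * K), n, K))
  list(y = y, f = f, eta = eta)
}

# ---- empirical Bayes estimates and shrinkage -----------------------------

# MAP modes of the random effects at the final estimates
.ebe_modes <- function(fit, pop = NULL) {
  prep <- fit$prep
  pop <- if (is.null(pop)) fit$estimates else pop
  d <- prep$d
  omega <- pmax(pop$omega, .OMEGA_FLOOR)
  out <- matrix(0, prep$N, d,
                dimnames = list(prep$ids, prep$model$pnames))
  for (i in seq_len(prep$N)) {
    sel <- prep$obs_subj == i
    if (!any(sel)) next
    ti <- prep$obs$time[sel]; yi <- prep$y[sel]
    di <- prep$doses[prep$doses$id_index == i, , drop = FALSE]
    xrow <- vapply(seq_len(d),
                   function(j) sum(prep$X[[j]][i, ] * fit$beta[[j]]), 0)
    obj <- function(e) {
      if (any(abs(e) > 20)) return(1e10)
      p <- exp(xrow + e)
      fi <- concentration_at(stats::setNames(p, prep$model$pnames),
                             data.frame(time = di$time, amt = di$amt,
                                        dur = di$dur),
                             ti, model = prep$model)
      sdv <- pop$b * pmax(fi, 1e-12)
      val <- -sum(stats::dnorm(yi, fi, sdv, log = TRUE)) +
        sum(e^2 / (2 * omega^2))
      if (!is.finite(val)) 1e10 else val
    }
    res <- stats::nlminb(rep(0, d), obj)
    out[i, ] <- res$par
  }
  out
}

#' Empirical Bayes estimates of the random effects
#'
#' Maximum a posteriori modes of each subject's \eqn{\eta} given the fitted
#' population parameters. Subjects without observations sit at the prior
#' mode (zero).
#'
#' @param fit an `saem_fit`.
#' @return Matrix (subjects x parameters) of \eqn{\eta} modes.
#' @export
empirical_bayes <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  fit$ebe
}

#' Eta shrinkage
#'
#' `100 * (1 - SD(EBE eta) / omega)` per parameter: near 0% with rich data,
#' approaching 100% as individual data stop informing the random effects.
#' Undefined (NA) for parameters with zero IIV.
#'
#' @param fit an `saem_fit`.
#' @return Named vector of shrinkage percentages.
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "saem_fit"))
  om <- fit$estimates$omega
  out <- rep(NA_real_, length(om))
  names(out) <- names(om)
  ok <- om > 2 * .OMEGA_FLOOR
  if (nrow(fit$ebe) >= 2) {
    out[ok] <- 100 * (1 - apply(fit$ebe[, ok, drop = FALSE], 2, stats::sd) /
                        om[ok])
  } else if (nrow(fit$ebe) == 1) {
    out[ok] <- 100
  }
  out
}
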