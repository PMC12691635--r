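# Model-evaluation suite: non-parametric bootstrap, NPDE, pc-VPC and
# goodness-of-fit tables.

#' Non-parametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement, refits each replicate (reusing the
#' base-fit estimates as starting values), and summarises each parameter by
#' its median and 2.5/97.5 percentile confidence interval (type-7
#' quantiles). Replicates that fail or do not converge are dropped and
#' counted; more than 10% non-convergence raises a warning.
#'
#' @param fit a converged `saem_fit`.
#' @param n_resamples number of bootstrap replicates.
#' @param seed integer seed.
#' @param control optional [saem_control()] for the replicate fits;
#'   defaults to a reduced iteration budget (150 + 75) with no RSE
#'   computation, which keeps replicate fits fast.
#' @return An object of class `pk_bootstrap` with the per-replicate
#'   estimates, medians and CIs.
#' @export
pk_bootstrap <- function(fit, n_resamples = 1000L, seed = 1L,
                         control = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  if (is.null(control)) {
    control <- saem_control(n_explore = 150L, n_smooth = 75L,
                            rse_method = "none")
    control$fix_omega <- fit$control$fix_omega
  }
  data <- fit$data
  ids <- fit$prep$ids
  init <- fit$estimates
  cov_model <- if (length(fit$prep$cov_spec)) {
    lapply(fit$prep$cov_spec, function(s) {
      list(param = s$param, covariate = s$covariate, ref = s$ref)
    })
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_resamples)
  draws <- matrix(sample(ids, n_resamples * length(ids), replace = TRUE),
                  n_resamples, length(ids))
  res <- vector("list", n_resamples)
  n_fail <- 0L
  for (r in seq_len(n_resamples)) {
    take <- draws[r, ]
    # rebuild dataset with duplicated subjects re-identified
    obs <- do.call(rbind, lapply(seq_along(take), function(i) {
      o <- data$obs[data$obs$id == take[i], , drop = FALSE]
      if (nrow(o)) o$id <- i
      o
    }))
    doses <- do.call(rbind, lapply(seq_along(take), function(i) {
      d <- data$doses[data$doses$id == take[i], , drop = FALSE]
      d$id <- i
      d
    }))
    covs <- NULL
    if (!is.null(data$covariates)) {
      covs <- data$covariates[match(take, data$covariates$id), , drop = FALSE]
      covs$id <- seq_along(take)
    }
    bd <- pk_dataset(obs, doses, covs, lloq = data$lloq)
    ans <- tryCatch(
      saem(bd, model = fit$model, init = init, covariates = cov_model,
           control = control, seed = rep_seeds[r]),
      error = function(e) NULL)
    if (is.null(ans) || !ans$converged) {
      n_fail <- n_fail + 1L
      next
    }
    res[[r]] <- coef(ans)
  }
  keep <- !vapply(res, is.null, TRUE)
  est <- do.call(rbind, res[keep])
  if (is.null(est) || nrow(est) == 0L) stop("all bootstrap replicates failed")
  if (n_fail > 0.10 * n_resamples) {
    warning(sprintf("%d/%d bootstrap replicates non-convergent", n_fail,
                    n_resamples))
  }
  qs <- apply(est, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              type = 7)
  tab <- data.frame(parameter = colnames(est),
                    estimate = as.numeric(coef(fit)[colnames(est)]),
                    median = qs[2, ], ci_lower = qs[1, ], ci_upper = qs[3, ])
  rownames(tab) <- NULL
  structure(list(table = tab, replicates = est,
                 n_resamples = n_resamples, n_converged = sum(keep),
                 seed = seed),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Non-parametric bootstrap: %d/%d replicates converged\n",
              x$n_converged, x$n_resamples))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Normalised prediction distribution errors
#'
#' Simulates `K` replicates of every subject's observation vector under the
#' population model (inter-individual variability plus proportional
#' residual error), decorrelates observations and simulations with the
#' Cholesky factor of the simulated covariance, and maps the rank of each
#' decorrelated observation among its simulated counterparts through the
#' inverse normal: `npde = qnorm((rank + 0.5)/(K + 1))`, ties contributing
#' half a rank. Under a correct model the NPDE are standard normal; the
#' global test combines a t-test of mean zero, a chi-square test of unit
#' variance and a Shapiro-Wilk normality test with a Bonferroni
#' correction.
#'
#' @param object an `saem_fit`, or a [pk_dataset()] (then `popmodel` is
#'   required).
#' @param popmodel a [popmodel()] when `object` is a dataset.
#' @param K number of simulation replicates (at least 100).
#' @param seed integer seed.
#' @return An object of class `npde_result`: per-observation NPDE values
#'   and the global test table.
#' @export
npde <- function(object, popmodel = NULL, K = 1000L, seed = 1L) {
  if (K < 100L) stop("K must be at least 100 for usable NPDE resolution")
  if (inherits(object, "saem_fit")) {
    prep <- object$prep
    pop <- object$estimates
  } else {
    stopifnot(inherits(object, "pk_dataset"), inherits(popmodel, "popmodel"))
    prep <- .prep_estimation(object, popmodel$model)
    pop <- popmodel
  }
  sims <- .simulate_replicates(prep, pop, K, seed)
  vals <- numeric(prep$n_obs)
  for (i in seq_len(prep$N)) {
    sel <- which(prep$obs_subj == i)
    yi <- prep$y[sel]
    Si <- sims$y[sel, , drop = FALSE]               # n_i x K
    Ei <- rowMeans(Si)
    Vi <- stats::cov(t(Si))
    L <- t(chol(Vi + diag(1e-10, length(sel))))     # lower triangular
    ystar <- forwardsolve(L, yi - Ei)
    sstar <- forwardsolve(L, Si - Ei)
    for (jj in seq_along(sel)) {
      r <- sum(sstar[jj, ] < ystar[jj]) + 0.5 * sum(sstar[jj, ] == ystar[jj])
      vals[sel[jj]] <- stats::qnorm((r + 0.5) / (K + 1))
    }
  }
  tt <- stats::t.test(vals, mu = 0)
  n <- length(vals)
  chi <- (n - 1) * stats::var(vals)
  p_var <- 2 * min(stats::pchisq(chi, n - 1),
                   stats::pchisq(chi, n - 1, lower.tail = FALSE))
  p_norm <- if (n >= 3) stats::shapiro.test(vals)$p.value else NA_real_
  global <- data.frame(
    test = c("mean == 0 (t)", "variance == 1 (chi-square)",
             "normality (Shapiro-Wilk)", "global (Bonferroni)"),
    statistic = c(unname(tt$statistic), chi / (n - 1), NA_real_, NA_real_),
    p_value = c(tt$p.value, p_var, p_norm,
                min(1, 3 * min(tt$p.value, p_var, p_norm, na.rm = TRUE))))
  structure(list(npde = vals,
                 table = data.frame(id = prep$ids[prep$obs_subj],
                                    time = prep$obs$time, dv = prep$y,
                                    npde = vals),
                 global = global, K = K, seed = seed),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (K = %d): mean %.3f, var %.3f\n",
              length(x$npde), x$K, mean(x$npde), stats::var(x$npde)))
  g <- x$global
  g$statistic <- round(g$statistic, 3)
  g$p_value <- signif(g$p_value, 3)
  print(g, row.names = FALSE)
  invisible(x)
}

#' @export
plot.npde_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  stats::qqnorm(x$npde, main = "NPDE Q-Q")
  stats::qqline(x$npde)
  graphics::plot(x$table$time / 24, x$npde, xlab = "time (days)",
                 ylab = "NPDE", main = "NPDE vs time")
  graphics::abline(h = c(-1.96, 0, 1.96), lty = c(3, 2, 3))
  invisible(x)
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulations are rescaled within each time bin by the
#' ratio of the bin's median population prediction to the observation's own
#' population prediction (`pcY = Y * median(PRED_bin)/PRED`), removing
#' predictable between-subject design differences. Observed 10th/50th/90th
#' percentiles per bin are compared with 90% prediction intervals of the
#' same percentiles across `n_sim` simulated replicates.
#'
#' @inheritParams npde
#' @param n_sim number of simulated replicate datasets.
#' @param bins numeric vector of bin edges in hours; defaults to weekly
#'   bins spanning the observed times. Bins holding fewer than 2
#'   observations are merged with their neighbour (with a message).
#' @return An object of class `pc_vpc` with the band table.
#' @export
pc_vpc <- function(object, popmodel = NULL, n_sim = 500L, bins = NULL,
                   seed = 1L) {
  if (inherits(object, "saem_fit")) {
    prep <- object$prep
    pop <- object$estimates
    beta <- object$beta
  } else {
    stopifnot(inherits(object, "pk_dataset"), inherits(popmodel, "popmodel"))
    prep <- .prep_estimation(object, popmodel$model)
    pop <- popmodel
    beta <- lapply(log(pop$fixed), function(m) m)
  }
  pred <- .predict_design(prep$model,
                          exp(.phi_from(prep, beta,
                                        matrix(0, prep$N, prep$d))), prep$ex)
  if (is.null(bins)) {
    bins <- seq(floor(min(prep$obs$time) / 168) * 168,
                ceiling(max(prep$obs$time) / 168) * 168, by = 168)
    if (length(bins) < 3L) bins <- range(prep$obs$time) + c(-1, 1)
  }
  binid <- cut(prep$obs$time, bins, include.lowest = TRUE, labels = FALSE)
  # merge thin bins with their left neighbour
  repeat {
    cnt <- table(factor(binid, levels = seq_len(length(bins) - 1L)))
    thin <- which(cnt > 0 & cnt < 2)
    if (!length(thin)) break
    tgt <- if (thin[1] > 1) thin[1] - 1L else thin[1] + 1L
    message("merging thin VPC bin ", thin[1], " into bin ", tgt)
    binid[binid == thin[1]] <- tgt
  }
  used <- sort(unique(binid))
  if (length(used) < 2L) stop("need at least 2 populated bins")
  med_pred <- tapply(pred, binid, stats::median)
  pcf <- med_pred[as.character(binid)] / pred
  probs <- c(0.1, 0.5, 0.9)
  obs_pct <- t(vapply(used, function(bn) {
    stats::quantile(prep$y[binid == bn] * pcf[binid == bn], probs, type = 7)
  }, numeric(3)))
  sims <- .simulate_replicates(prep, pop, n_sim, seed)
  sim_pct <- array(NA_real_, c(length(used), 3, n_sim))
  for (s in seq_len(n_sim)) {
    ys <- sims$y[, s] * pcf
    sim_pct[, , s] <- t(vapply(used, function(bn) {
      stats::quantile(ys[binid == bn], probs, type = 7)
    }, numeric(3)))
  }
  lo <- apply(sim_pct, c(1, 2), stats::quantile, 0.05, type = 7)
  hi <- apply(sim_pct, c(1, 2), stats::quantile, 0.95, type = 7)
  bands <- data.frame(
    bin = used,
    t_lo = bins[used], t_hi = bins[pmin(used + 1L, length(bins))],
    n = as.integer(table(factor(binid, levels = used))),
    obs_p10 = obs_pct[, 1], obs_p50 = obs_pct[, 2], obs_p90 = obs_pct[, 3],
    sim_p10_lo = lo[, 1], sim_p10_hi = hi[, 1],
    sim_p50_lo = lo[, 2], sim_p50_hi = hi[, 2],
    sim_p90_lo = lo[, 3], sim_p90_hi = hi[, 3])
  structure(list(bands = bands, n_sim = n_sim, bins = bins, seed = seed),
            class = "pc_vpc")
}

#' @export
print.pc_vpc <- function(x, ...) {
  cat(sprintf("pc-VPC: %d bins, %d simulations\n", nrow(x$bands), x$n_sim))
  b <- x$bands
  b[-(1:4)] <- lapply(b[-(1:4)], signif, 3)
  print(b, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pc_vpc <- function(x, ...) {
  b <- x$bands
  mid <- (b$t_lo + b$t_hi) / 2 / 24
  rng <- range(c(b$obs_p10, b$obs_p90, b$sim_p10_lo, b$sim_p90_hi))
  graphics::plot(mid, b$obs_p50, type = "b", ylim = rng, log = "y",
                 xlab = "time (days)", ylab = "pc concentration (mg/L)",
                 main = "prediction-corrected VPC")
  for (k in c("p10", "p90")) {
    graphics::lines(mid, b[[paste0("obs_", k)]], lty = 2, type = "b")
  }
  for (k in c("p10", "p50", "p90")) {
    graphics::polygon(c(mid, rev(mid)),
                      c(b[[paste0("sim_", k, "_lo")]],
                        rev(b[[paste0("sim_", k, "_hi")]])),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
  }
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Per-observation population prediction (PRED), individual prediction
#' (IPRED), individual weighted residual (IWRES) and, optionally, NPDE.
#' Subjects without quantifiable observations are absent (with a message
#' at fit time).
#'
#' @param fit an `saem_fit`.
#' @param include_npde add an NPDE column (simulation-based, `K`
#'   replicates).
#' @param K,seed NPDE settings.
#' @return A data frame, one row per quantifiable observation.
#' @export
gof_table <- function(fit, include_npde = TRUE, K = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "saem_fit"))
  prep <- fit$prep
  tab <- data.frame(id = prep$ids[prep$obs_subj], time = prep$obs$time,
                    dv = prep$y,
                    pred = predict(fit, type = "pred"),
                    ipred = predict(fit, type = "ipred"))
  tab$iwres <- (tab$dv - tab$ipred) / (fit$estimates$b * pmax(tab$ipred, 1e-12))
  if (include_npde) tab$npde <- npde(fit, K = K, seed = seed)$npde
  tab
}

#' @export
plot.saem_fit <- function(x, ...) {
  tab <- gof_table(x, include_npde = FALSE)
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  lim <- range(c(tab$dv, tab$pred, tab$ipred))
  graphics::plot(tab$pred, tab$dv, xlim = lim, ylim = lim,
                 xlab = "PRED (mg/L)", ylab = "observed (mg/L)")
  graphics::abline(0, 1, lty = 2)
  graphics::plot(tab$ipred, tab$dv, xlim = lim, ylim = lim,
                 xlab = "IPRED (mg/L)", ylab = "observed (mg/L)")
  graphics::abline(0, 1, lty = 2)
  graphics::plot(tab$time / 24, tab$iwres, xlab = "time (days)",
                 ylab = "IWRES")
  graphics::abline(h = c(-1.96, 0, 1.96), lty = c(3, 2, 3))
  graphics::plot(tab$time / 24, tab$dv, log = "y", xlab = "time (days)",
                 ylab = "concentration (mg/L)",
                 main = "observed (semi-log)")
  invisible(x)
}
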