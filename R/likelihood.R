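# Likelihood, information criteria and standard errors for saem_fit objects.

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
# by Golub-Welsch on the Jacobi matrix.
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(sqrt(pi) * e$vectors[1L, ]^2))
}

# theta packing: named natural-scale parameter vector <-> model pieces
.theta_pack <- function(fit) {
  prep <- fit$prep; d <- prep$d
  est_om <- is.na(fit$fix_omega)
  om_nm <- names(fit$estimates$omega)[est_om]
  om_part <- if (length(om_nm)) {
    stats::setNames(fit$estimates$omega[est_om], paste0("omega_", om_nm))
  }
  vals <- c(fit$estimates$fixed,
            unlist(lapply(seq_len(d), function(j) {
              bj <- fit$beta[[j]][-1L]
              if (length(bj)) stats::setNames(bj, colnames(prep$X[[j]])[-1L])
            })),
            om_part,
            b = fit$estimates$b)
  nbeta <- vapply(prep$X, ncol, 0L) - 1L
  unpack <- function(th) {
    pos <- d
    beta <- vector("list", d)
    for (j in seq_len(d)) {
      beta[[j]] <- c(log(th[j]),
                     if (nbeta[j]) th[pos + seq_len(nbeta[j])])
      pos <- pos + nbeta[j]
    }
    omega <- fit$estimates$omega
    omega[est_om] <- th[pos + seq_len(sum(est_om))]
    list(beta = beta, omega = pmax(omega, .OMEGA_FLOOR),
         b = th[length(th)])
  }
  list(values = vals, unpack = unpack, n_pop = d + sum(nbeta) + sum(est_om),
       n_err = 1L)
}

# per-subject vectorised complete-data log-likelihood evaluators
.subject_evals <- function(fit) {
  prep <- fit$prep; d <- prep$d
  lapply(seq_len(prep$N), function(i) {
    sel <- prep$obs_subj == i
    ti <- prep$obs$time[sel]; yi <- prep$y[sel]
    di <- prep$doses[prep$doses$id_index == i, , drop = FALSE]
    n_i <- length(ti)
    # per-subject expanded rows (obs x dose)
    g <- expand.grid(obs = seq_len(n_i), dose = seq_len(nrow(di)))
    tsince <- ti[g$obs] - di$time[g$dose]
    R0 <- di$amt[g$dose] / di$dur[g$dose]
    dur <- di$dur[g$dose]
    R <- nrow(g)
    Xi <- lapply(prep$X, function(x) x[i, ])
    function(beta, omega, b, eta) {
      M <- nrow(eta)
      xbase <- vapply(seq_len(d), function(j) sum(Xi[[j]] * beta[[j]]), 0)
      P <- exp(matrix(xbase, M, d, byrow = TRUE) + eta)
      tm <- fit$model$terms(P[rep(seq_len(M), each = R), , drop = FALSE])
      contrib <- .conc_terms(tm$coef, tm$rate, rep(R0, M),
                             rep(tsince, M), rep(dur, M))
      idx <- rep((seq_len(M) - 1L) * n_i, each = R) + rep(g$obs, M)
      f <- matrix(as.numeric(rowsum(contrib, idx)), n_i, M)
      sdv <- b * pmax(f, 1e-12)
      llo <- colSums(matrix(stats::dnorm(rep(yi, M), f, sdv, log = TRUE),
                            n_i, M))
      llo[colSums(f <= 0 & yi > 0) > 0] <- -Inf
      llp <- -0.5 * d * log(2 * pi) - sum(log(omega)) -
        rowSums(sweep(eta^2, 2, 2 * omega^2, "/"))
      list(obs = llo, total = llo + llp)
    }
  })
}

# numeric hessian of the negative conditional log-posterior in eta
.cond_hessian <- function(ev, beta, omega, b, mode, h = 1e-3) {
  d <- length(mode)
  fn <- function(e) {
    v <- -ev(beta, omega, b, matrix(e, 1))$total
    if (!is.finite(v)) 1e10 else v
  }
  H <- matrix(0, d, d)
  for (k in seq_len(d)) {
    ek <- numeric(d); ek[k] <- h
    for (l in seq_len(k)) {
      el <- numeric(d); el[l] <- h
      H[k, l] <- H[l, k] <-
        (fn(mode + ek + el) - fn(mode + ek - el) -
           fn(mode - ek + el) + fn(mode - ek - el)) / (4 * h^2)
    }
  }
  H
}

#' Importance-sampling objective function value and information criteria
#'
#' Estimates \eqn{-2 \log} marginal likelihood of a fitted model by
#' importance sampling: per subject, a multivariate t proposal (df = 4)
#' centred at the empirical Bayes mode with the conditional posterior
#' curvature as scale. Also reports `AIC = OFV + 2p` and the corrected BIC
#' with mixed penalty: `log(N)` per population parameter and `log(n_obs)`
#' per residual-error parameter.
#'
#' For a model without random effects the marginal likelihood is the
#' ordinary normal likelihood and is returned exactly (zero Monte Carlo
#' error).
#'
#' @param fit an `saem_fit`.
#' @param n_is importance-sampling draws per subject.
#' @param seed integer seed.
#' @param df degrees of freedom of the t proposal.
#' @return List with `ofv`, `aic`, `bicc`, `se` (Monte Carlo standard
#'   error of the OFV) and `p` (parameter count).
#' @export
compute_ofv <- function(fit, n_is = 5000L, seed = 1L, df = 4) {
  stopifnot(inherits(fit, "saem_fit"))
  pk <- .theta_pack(fit)
  p <- pk$n_pop + pk$n_err
  prep <- fit$prep
  est <- fit$estimates
  no_iiv <- all(est$omega <= 2 * .OMEGA_FLOOR | !is.na(fit$fix_omega) &
                  fit$fix_omega == 0)
  if (no_iiv) {
    f <- .predict_design(fit$model,
                         exp(.phi_from(prep, fit$beta,
                                       matrix(0, prep$N, prep$d))), prep$ex)
    ofv <- -2 * sum(stats::dnorm(prep$y, f, est$b * pmax(f, 1e-12),
                                 log = TRUE))
    p0 <- prep$d + sum(vapply(prep$X, ncol, 0L) - 1L) + 1L
    return(list(ofv = ofv, aic = ofv + 2 * p0,
                bicc = ofv + log(prep$N) * (p0 - 1L) + log(prep$n_obs),
                se = 0, p = p0))
  }
  set.seed(seed)
  evs <- .subject_evals(fit)
  d <- prep$d
  omega <- pmax(est$omega, .OMEGA_FLOOR)
  loglik <- 0; varsum <- 0
  for (i in seq_len(prep$N)) {
    mode <- fit$ebe[i, ]
    H <- .cond_hessian(evs[[i]], fit$beta, omega, est$b, mode)
    Sigma <- if (all(is.finite(H))) {
      tryCatch(solve(H), error = function(e) NULL)
    }
    ok <- !is.null(Sigma) && all(is.finite(Sigma)) &&
      all(tryCatch(eigen(Sigma, symmetric = TRUE,
                         only.values = TRUE)$values > 0,
                   error = function(e) FALSE))
    if (!ok) Sigma <- diag(omega^2, d)
    L <- chol(Sigma)
    z <- matrix(stats::rnorm(n_is * d), n_is, d)
    u <- stats::rchisq(n_is, df)
    eta <- matrix(mode, n_is, d, byrow = TRUE) +
      (z %*% L) * sqrt(df / u)
    dev <- eta - matrix(mode, n_is, d, byrow = TRUE)
    m <- rowSums((dev %*% solve(L)) ^ 2)          # Mahalanobis^2
    logq <- lgamma((df + d) / 2) - lgamma(df / 2) -
      (d / 2) * log(df * pi) - sum(log(diag(L))) -
      ((df + d) / 2) * log1p(m / df)
    logw <- evs[[i]](fit$beta, omega, est$b, eta)$total - logq
    mx <- max(logw)
    w <- exp(logw - mx)
    Li_log <- mx + log(mean(w))
    loglik <- loglik + Li_log
    varsum <- varsum + stats::var(w) / (n_is * mean(w)^2)
  }
  ofv <- -2 * loglik
  list(ofv = ofv, aic = ofv + 2 * p,
       bicc = ofv + log(prep$N) * pk$n_pop + log(prep$n_obs) * pk$n_err,
       se = 2 * sqrt(varsum), p = p)
}

#' @export
logLik.saem_fit <- function(object, ...) {
  if (is.null(object$ofv)) {
    ll <- compute_ofv(object, seed = object$seed + 1L)
    val <- -ll$ofv / 2; p <- ll$p
  } else {
    val <- -object$ofv / 2
    p <- .theta_pack(object)$n_pop + 1L
  }
  structure(val, df = p, nobs = object$prep$n_obs, class = "logLik")
}

# posterior eta samples at the final estimates (same RWM kernel as the fit)
.sample_posterior <- function(fit, n_keep = 300L, n_burn = 150L, seed = 1L) {
  set.seed(seed)
  prep <- fit$prep; d <- prep$d; N <- prep$N
  omega <- pmax(fit$estimates$omega, .OMEGA_FLOOR)
  b <- fit$estimates$b
  eta <- fit$ebe
  f <- .predict_design(fit$model, exp(.phi_from(prep, fit$beta, eta)),
                       prep$ex)
  llo <- .llo_by_subject(prep, f, b)
  prop_sd <- matrix(pmax(omega, 0.05), N, d, byrow = TRUE)
  keep <- array(NA_real_, c(N, d, n_keep))
  stored <- 0L
  for (k in seq_len(n_burn + n_keep)) {
    for (j in seq_len(d)) {
      ej <- eta
      ej[, j] <- eta[, j] + stats::rnorm(N) * prop_sd[, j]
      fp <- .predict_design(fit$model, exp(.phi_from(prep, fit$beta, ej)),
                            prep$ex)
      llp <- .llo_by_subject(prep, fp, b)
      dlp <- (eta[, j]^2 - ej[, j]^2) / (2 * omega[j]^2)
      lacc <- llp - llo + dlp
      lacc[is.na(lacc)] <- 0
      acc <- log(stats::runif(N)) < lacc
      if (any(acc)) {
        eta[acc, j] <- ej[acc, j]
        sel <- acc[prep$obs_subj]
        f[sel] <- fp[sel]
        llo[acc] <- llp[acc]
      }
      if (k <= n_burn) prop_sd[, j] <- prop_sd[, j] * ifelse(acc, 1.08, 0.95)
    }
    if (k > n_burn) {
      stored <- stored + 1L
      keep[, , stored] <- eta
    }
  }
  keep
}

#' Relative standard errors of the population estimates
#'
#' Per-parameter `100 * SE / estimate`. The default (`"louis"`) estimates
#' the observed Fisher information by Louis' identity on posterior samples
#' of the random effects drawn with the fit's Metropolis kernel; `"fd"`
#' differentiates the adaptive Gauss-Hermite marginal log-likelihood by
#' central finite differences (deterministic, used as fallback when the
#' stochastic information matrix is not positive definite).
#'
#' @param fit a converged `saem_fit`.
#' @param method `"louis"` or `"fd"`.
#' @param n_samples posterior draws per subject (Louis method).
#' @param seed integer seed for the posterior sampling.
#' @return Named vector of RSE percentages (attribute `method` records the
#'   method actually used, `se` the standard errors).
#' @export
rse <- function(fit, method = c("louis", "fd"), n_samples = NULL,
                seed = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  method <- match.arg(method)
  if (is.null(n_samples)) n_samples <- fit$control$rse_samples
  if (is.null(seed)) seed <- fit$seed + 7L
  pk <- .theta_pack(fit)
  th <- pk$values
  p <- length(th)
  if (method == "louis" && !all(fit$estimates$omega <= 2 * .OMEGA_FLOOR)) {
    I <- tryCatch(.fim_louis(fit, pk, n_samples, seed),
                  error = function(e) NULL)
    if (!is.null(I)) {
      V <- tryCatch(solve(I), error = function(e) NULL)
      if (!is.null(V) && all(diag(V) > 0)) {
        se <- sqrt(diag(V))
        out <- 100 * se / abs(th)
        attr(out, "method") <- "louis"
        attr(out, "se") <- stats::setNames(se, names(th))
        return(out)
      }
    }
    method <- "fd"   # fallback
  }
  I <- .fim_fd(fit, pk)
  V <- solve(I)
  dg <- diag(V)
  dg[dg < 0] <- NA_real_
  se <- sqrt(dg)
  out <- 100 * se / abs(th)
  attr(out, "method") <- "fd"
  attr(out, "se") <- stats::setNames(se, names(th))
  out
}

.fim_louis <- function(fit, pk, n_samples, seed) {
  th <- pk$values
  p <- length(th)
  h <- pmax(abs(th) * 1e-4, 1e-7)
  evs <- .subject_evals(fit)
  samples <- .sample_posterior(fit, n_keep = n_samples, seed = seed)
  N <- fit$prep$N
  I <- matrix(0, p, p)
  llth <- function(th2, ev, eta) {
    u <- pk$unpack(th2)
    ev(u$beta, u$omega, u$b, eta)$total
  }
  for (i in seq_len(N)) {
    eta <- t(matrix(samples[i, , ], fit$prep$d, n_samples))
    ev <- evs[[i]]
    ll0 <- llth(th, ev, eta)
    S <- matrix(0, n_samples, p)
    Hbar <- matrix(0, p, p)
    llp <- llm <- vector("list", p)
    for (k in seq_len(p)) {
      tp <- th; tp[k] <- tp[k] + h[k]
      tm <- th; tm[k] <- tm[k] - h[k]
      llp[[k]] <- llth(tp, ev, eta)
      llm[[k]] <- llth(tm, ev, eta)
      S[, k] <- (llp[[k]] - llm[[k]]) / (2 * h[k])
      Hbar[k, k] <- mean((llp[[k]] - 2 * ll0 + llm[[k]]) / h[k]^2)
    }
    for (k in seq_len(p - 1L)) {
      for (l in seq((k + 1L), p)) {
        tpp <- th; tpp[k] <- tpp[k] + h[k]; tpp[l] <- tpp[l] + h[l]
        tpm <- th; tpm[k] <- tpm[k] + h[k]; tpm[l] <- tpm[l] - h[l]
        tmp <- th; tmp[k] <- tmp[k] - h[k]; tmp[l] <- tmp[l] + h[l]
        tmm <- th; tmm[k] <- tmm[k] - h[k]; tmm[l] <- tmm[l] - h[l]
        Hbar[k, l] <- Hbar[l, k] <-
          mean((llth(tpp, ev, eta) - llth(tpm, ev, eta) -
                  llth(tmp, ev, eta) + llth(tmm, ev, eta)) /
                 (4 * h[k] * h[l]))
      }
    }
    Sbar <- colMeans(S)
    I <- I + (-Hbar - crossprod(S) / n_samples + tcrossprod(Sbar))
  }
  I
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature
.marg_ll_agq <- function(fit, pk, th, n_nodes = 9L) {
  u <- pk$unpack(th)
  evs <- .subject_evals(fit)
  d <- fit$prep$d
  gh <- .gauss_hermite(n_nodes)
  grid <- as.matrix(expand.grid(rep(list(gh$x), d)))
  logw <- rowSums(matrix(log(gh$w)[match(grid, gh$x)], nrow(grid), d))
  sq <- rowSums(grid^2)
  total <- 0
  for (i in seq_len(fit$prep$N)) {
    ev <- evs[[i]]
    obj <- function(e) {
      v <- -ev(u$beta, u$omega, u$b, matrix(e, 1))$total
      if (!is.finite(v)) 1e10 else v
    }
    mode <- stats::nlminb(fit$ebe[i, ], obj)$par
    H <- .cond_hessian(ev, u$beta, u$omega, u$b, mode)
    Sigma <- if (all(is.finite(H))) {
      tryCatch(solve(H), error = function(e) NULL)
    }
    ok <- !is.null(Sigma) && all(is.finite(Sigma)) &&
      all(tryCatch(eigen(Sigma, symmetric = TRUE,
                         only.values = TRUE)$values > 0,
                   error = function(e) FALSE))
    if (!ok) Sigma <- diag(u$omega^2, d)
    L <- chol(Sigma)
    eta <- matrix(mode, nrow(grid), d, byrow = TRUE) + sqrt(2) * grid %*% L
    g <- ev(u$beta, u$omega, u$b, eta)$total
    lse <- g + sq + logw
    mx <- max(lse)
    total <- total + (d / 2) * log(2) + sum(log(diag(L))) +
      mx + log(sum(exp(lse - mx)))
  }
  total
}

.fim_fd <- function(fit, pk) {
  th <- pk$values
  p <- length(th)
  h <- pmax(abs(th) * 1e-3, 1e-6)
  f0 <- .marg_ll_agq(fit, pk, th)
  H <- matrix(0, p, p)
  fp <- fm <- numeric(p)
  for (k in seq_len(p)) {
    tp <- th; tp[k] <- tp[k] + h[k]
    tm <- th; tm[k] <- tm[k] - h[k]
    fp[k] <- .marg_ll_agq(fit, pk, tp)
    fm[k] <- .marg_ll_agq(fit, pk, tm)
    H[k, k] <- (fp[k] - 2 * f0 + fm[k]) / h[k]^2
  }
  for (k in seq_len(p - 1L)) {
    for (l in seq(k + 1L, p)) {
      tpp <- th; tpp[k] <- tpp[k] + h[k]; tpp[l] <- tpp[l] + h[l]
      tmm <- th; tmm[k] <- tmm[k] - h[k]; tmm[l] <- tmm[l] - h[l]
      H[k, l] <- H[l, k] <-
        (.marg_ll_agq(fit, pk, tpp) - fp[k] - fp[l] + 2 * f0 -
           fm[k] - fm[l] + .marg_ll_agq(fit, pk, tmm)) / (2 * h[k] * h[l])
    }
  }
  -H
}
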