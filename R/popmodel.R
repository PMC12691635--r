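#' Population pharmacokinetic model specification
#'
#' Bundles the population-level parameters of a structural model: fixed
#' effects, log-normal inter-individual variability (IIV) standard
#' deviations, and the proportional residual-error magnitude. Individual
#' parameters are \eqn{\psi_i = \psi_{pop} e^{\eta_i}} with
#' \eqn{\eta_i \sim N(0, \omega^2)}.
#'
#' @param fixed named vector of fixed effects (names must match the
#'   structural model's parameters, e.g. `V` in L, `CL` in L/h).
#' @param omega named vector of IIV standard deviations on the log scale
#'   (dimensionless, `>= 0`); parameters omitted get zero IIV.
#' @param b proportional residual-error magnitude (dimensionless, `>= 0`).
#' @param model structural model object ([one_compartment()] by default).
#' @return An object of class `popmodel`.
#' @seealso [dalbavancin_model()] for the packaged single-dose dalbavancin
#'   model.
#' @export
popmodel <- function(fixed, omega = NULL, b = 0, model = one_compartment()) {
  fixed <- unlist(fixed)[model$pnames]
  if (anyNA(fixed) || any(fixed <= 0)) {
    stop("fixed effects must be strictly positive and cover: ",
         paste(model$pnames, collapse = ", "))
  }
  om <- stats::setNames(numeric(model$npar), model$pnames)
  if (!is.null(omega)) {
    omega <- unlist(omega)
    if (is.null(names(omega)) && length(omega) == model$npar) {
      names(omega) <- model$pnames
    }
    om[names(omega)] <- omega
  }
  if (any(om < 0) || b < 0) stop("omega and b must be >= 0")
  structure(list(fixed = fixed, omega = om, b = b, model = model),
            class = "popmodel")
}

#' @export
print.popmodel <- function(x, ...) {
  cat("Population PK model (", x$model$name, ")\n", sep = "")
  cat("Fixed effects: ",
      paste(sprintf("%s = %g", names(x$fixed), x$fixed), collapse = ", "),
      "\n")
  cat("IIV (SD of log):",
      paste(sprintf("%s = %g", names(x$omega), x$omega), collapse = ", "),
      "\n")
  cat("Proportional error b =", x$b, "\n")
  invisible(x)
}

#' Reference single-dose dalbavancin population model
#'
#' The final one-compartment population model for total dalbavancin in
#' elderly patients with chronic prosthetic joint infection after a single
#' 1,500 mg intravenous dose: `V = 17.9` L, `CL = 0.036` L/h, log-normal
#' IIV standard deviations 0.200 (V) and 0.290 (CL), and proportional
#' residual error `b = 0.120`. This model is the default input for the
#' dosing-simulation engine and the generating truth for the synthetic
#' cohort.
#'
#' @return A [popmodel()].
#' @examples
#' dalbavancin_model()
#' @export
dalbavancin_model <- function() {
  popmodel(fixed = c(V = 17.9, CL = 0.036),
           omega = c(V = 0.200, CL = 0.290),
           b = 0.120)
}
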