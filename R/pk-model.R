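#' Individual pharmacokinetic parameters from covariates
#'
#' Evaluates the covariate model for each subject:
#' \deqn{CL_i = tvCL \prod_{power} (x_i/x_{ref})^{\theta}
#'   \prod_{indicator} e^{\theta I_i} \; e^{\eta_{CL,i}}}
#' and analogously for \eqn{V_i}.
#'
#' @param covariates Data frame with one row per subject containing every
#'   covariate named in `spec$relations`.
#' @param params A [pk_params()] object.
#' @param spec A [pk_model_spec()] object.
#' @param eta Optional matrix (rows = subjects, columns = `spec$iiv`) of
#'   random effects; defaults to zero (typical-value prediction).
#' @return A tibble with columns `CL` (L/h) and `V` (L).
#' @export
#' @examples
#' refs <- data.frame(WT = 2.12, SCR = 30.52, DFI = 367.18, DA = 0)
#' individual_params(refs, vanco_final_params(), vanco_final_spec())
individual_params <- function(covariates, params, spec, eta = NULL) {
  covariates <- as_tibble(covariates)
  n <- nrow(covariates)
  rel <- spec$relations
  need <- unique(rel$covariate)
  missing_cov <- setdiff(need, names(covariates))
  if (length(missing_cov)) {
    abort(paste0("Missing covariate column(s): ", paste(missing_cov, collapse = ", ")))
  }
  th <- params$theta
  need_theta <- relation_theta_names(spec)
  missing_th <- setdiff(need_theta, names(th))
  if (length(missing_th)) {
    abort(paste0("Missing fixed effect(s) in theta: ", paste(missing_th, collapse = ", ")))
  }

  logCL <- rep(log(th[["tvCL"]]), n)
  logV <- rep(log(th[["tvV"]]), n)
  if (nrow(rel)) {
    for (i in seq_len(nrow(rel))) {
      x <- covariates[[rel$covariate[i]]]
      if (anyNA(x)) abort(paste0("Covariate ", rel$covariate[i], " contains NA."))
      coef <- th[[need_theta[i]]]
      term <- if (rel$form[i] == "power") {
        if (any(x <= 0)) {
          abort(paste0("Covariate ", rel$covariate[i],
                       " must be strictly positive for the power form."))
        }
        coef * log(x / rel$ref[i])
      } else {
        coef * x
      }
      if (rel$parameter[i] == "CL") logCL <- logCL + term else logV <- logV + term
    }
  }
  if (!is.null(eta)) {
    eta <- as.matrix(eta)
    stopifnot(nrow(eta) == n, ncol(eta) == length(spec$iiv))
    if ("CL" %in% spec$iiv) logCL <- logCL + eta[, match("CL", spec$iiv)]
    if ("V" %in% spec$iiv) logV <- logV + eta[, match("V", spec$iiv)]
  }
  tibble(CL = exp(logCL), V = exp(logV))
}

#' One-compartment IV-infusion concentration
#'
#' Analytic solution with first-order elimination (\eqn{k_e = CL/V}),
#' superposed over the full dose history (linear kinetics): during an
#' infusion of rate \eqn{R_0} the contribution is
#' \eqn{(R_0/CL)(1 - e^{-k_e \Delta t})}; after the infusion ends the
#' end-of-infusion value decays as \eqn{e^{-k_e (t - t_{end})}}.
#'
#' @param times Numeric vector of times (h since first dose); must be
#'   non-negative.
#' @param doses Data frame of dose events with columns `time` (h), `amt`
#'   (mg) and `dur` (h, infusion duration > 0).
#' @param CL Clearance (L/h), positive scalar.
#' @param V Volume of distribution (L), positive scalar.
#' @return Numeric vector of concentrations (mg/L).
#' @export
#' @examples
#' reg <- data.frame(time = c(0, 12), amt = 25, dur = 1)
#' pk_conc(c(1, 11.5, 13.5), reg, CL = 0.14, V = 1.04)
pk_conc <- function(times, doses, CL, V) {
  if (any(times < 0)) abort("`times` must be non-negative.")
  if (CL <= 0 || V <= 0) abort("CL and V must be strictly positive.")
  doses <- as_tibble(doses)
  stopifnot(all(c("time", "amt", "dur") %in% names(doses)))
  if (any(doses$amt <= 0) || any(doses$dur <= 0) || any(doses$time < 0)) {
    abort("Dose events need amt > 0, dur > 0, time >= 0.")
  }
  conc_onecpt_cpp(as.double(times), as.double(doses$time), as.double(doses$amt),
                  as.double(doses$dur), CL, V)
}

#' Residual-error variance
#'
#' Variance of an observation given its model prediction `f` under the
#' additive (`Y = F + e`), proportional (`Y = F(1 + e)`) or combined
#' (`Y = F(1 + e1) + e2`) residual model.
#'
#' @param f Predicted concentration(s), mg/L, non-negative.
#' @param sigma Named vector `c(prop = , add = )` of residual SDs.
#' @param residual One of `"additive"`, `"proportional"`, `"combined"`.
#' @return Variance(s) in (mg/L)^2.
#' @export
residual_variance <- function(f, sigma, residual) {
  if (any(f < 0)) abort("`f` must be non-negative.")
  sp <- if ("prop" %in% names(sigma)) sigma[["prop"]] else 0
  sa <- if ("add" %in% names(sigma)) sigma[["add"]] else 0
  switch(residual,
    additive = rep(sa^2, length(f)),
    proportional = f^2 * sp^2,
    combined = f^2 * sp^2 + sa^2,
    abort(paste0("Unknown residual model: ", residual))
  )
}

#' Steady-state 24-hour AUC
#'
#' At steady state the 24-hour area under the concentration-time curve of a
#' linear model equals daily dose divided by clearance.
#'
#' @param daily_dose Total daily dose (mg), non-negative.
#' @param CL Clearance (L/h), positive.
#' @return AUC over 24 h (mg·h/L).
#' @export
#' @examples
#' auc24_ss(56, 0.14)  # 400 mg.h/L
auc24_ss <- function(daily_dose, CL) {
  if (any(CL <= 0)) abort("CL must be strictly positive.")
  if (any(daily_dose < 0)) abort("daily_dose must be non-negative.")
  daily_dose / CL
}
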