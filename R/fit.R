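# FOCE-with-interaction estimation. The marginal likelihood of each
# subject's data is approximated by linearising the model about the
# conditional mode eta-hat of the random effects:
#   G_i = df_i/deta at eta-hat, Sigma_i = G_i Omega G_i' + R_i(eta-hat),
#   r_i  = y_i - f_i(eta-hat) + G_i eta-hat,
#   OFV  = sum_i [ log det Sigma_i + r_i' Sigma_i^-1 r_i + n_i log 2pi ].
# The n log 2pi constant is retained; every modelling decision rests on
# OFV differences, which are unaffected.

# parameter packing: log transform for scale parameters, identity for
# covariate coefficients
par_template <- function(spec) {
  theta <- c("tvCL", "tvV", relation_theta_names(spec))
  omega <- spec$iiv
  sigma <- switch(spec$residual,
                  additive = "add",
                  proportional = "prop",
                  combined = c("prop", "add"))
  list(theta = theta, omega = omega, sigma = sigma,
       n = length(theta) + length(omega) + length(sigma),
       log_scale = c("tvCL", "tvV") )
}

pack_params <- function(params, tpl) {
  th <- params$theta[tpl$theta]
  om <- params$omega[tpl$omega]
  si <- params$sigma[tpl$sigma]
  sel <- tpl$theta %in% tpl$log_scale
  th[sel] <- log(th[sel])
  v <- c(th, log(pmax(om, 1e-6)), log(pmax(si, 1e-6)))
  names(v) <- c(tpl$theta, paste0("omega_", tpl$omega), paste0("sigma_", tpl$sigma))
  v
}

unpack_params <- function(v, tpl) {
  nt <- length(tpl$theta)
  th <- v[seq_len(nt)]
  sel <- tpl$theta %in% tpl$log_scale
  th[sel] <- exp(th[sel])
  names(th) <- tpl$theta
  om <- exp(v[nt + seq_along(tpl$omega)])
  names(om) <- tpl$omega
  si <- exp(v[nt + length(tpl$omega) + seq_along(tpl$sigma)])
  names(si) <- tpl$sigma
  full_sigma <- c(prop = 0, add = 0)
  full_sigma[names(si)] <- si
  pk_params(theta = th, omega = om, sigma = full_sigma)
}

sigma_components <- function(params, spec) {
  switch(spec$residual,
         additive = c(0, params$sigma[["add"]]),
         proportional = c(params$sigma[["prop"]], 0),
         combined = c(params$sigma[["prop"]], params$sigma[["add"]]),
         abort(paste0("Unknown residual model: ", spec$residual)))
}

prepare_fit_data <- function(data, spec) {
  subjects <- as_subject_list(data)
  if (length(subjects) == 0) abort("No fittable subjects in dataset.")
  flat <- flatten_subjects(subjects)
  flat$n_subjects <- length(subjects)
  flat
}

# one objective evaluation; eta_warm is a matrix (subjects x d) or NULL
foce_eval <- function(flat, params, spec, eta_warm = NULL, detail = FALSE) {
  ip <- individual_params(flat$covariates, params, spec)
  d <- length(spec$iiv)
  om <- rep(0, d)
  names(om) <- spec$iiv
  have <- intersect(spec$iiv, names(params$omega))
  om[have] <- params$omega[have]
  sig <- sigma_components(params, spec)
  if (is.null(eta_warm)) eta_warm <- matrix(0, flat$n_subjects, max(d, 1))
  foce_ofv_cpp(flat$y, flat$tobs, flat$obs_ptr,
               flat$dtime, flat$damt, flat$ddur, flat$dose_ptr,
               ip$CL, ip$V,
               "CL" %in% spec$iiv, "V" %in% spec$iiv,
               as.double(om^2), sig[1], sig[2],
               eta_warm, detail)
}

#' FOCE objective function value
#'
#' Computes the FOCE-with-interaction approximation to minus twice the
#' marginal log-likelihood of an event-record dataset under a parameter set.
#' The additive \eqn{n \log 2\pi} constant is included, so absolute values
#' are comparable across this package's fits but only OFV differences are
#' meaningful across software.
#'
#' @param data Event-record tibble (see [read_pk_dataset()]).
#' @param params A [pk_params()] object.
#' @param spec A [pk_model_spec()] object.
#' @return The OFV (numeric scalar).
#' @export
foce_ofv <- function(data, params, spec) {
  flat <- prepare_fit_data(data, spec)
  res <- foce_eval(flat, params, spec)
  if (!is.finite(res$ofv)) {
    abort(paste0("Singular subject covariance for subject ",
                 flat$ids[res$failed_subject], "."))
  }
  res$ofv
}

#' Empirical Bayes estimates of the random effects
#'
#' For each subject, minimises the conditional objective
#' \eqn{\sum_j [(y_j - f_j(\eta))^2 / R_j(\eta) + \log R_j(\eta)]
#'  + \eta' \Omega^{-1} \eta} (residual variance evaluated at \eqn{\eta},
#' i.e. with interaction) by damped Newton from \eqn{\eta = 0} with a second
#' deterministic start.
#'
#' @inheritParams foce_ofv
#' @return Tibble with `ID` and one `eta_<parameter>` column per IIV term.
#' @export
estimate_etas <- function(data, params, spec) {
  flat <- prepare_fit_data(data, spec)
  res <- foce_eval(flat, params, spec)
  if (!is.finite(res$ofv)) {
    abort(paste0("Eta estimation failed for subject ",
                 flat$ids[res$failed_subject], "."))
  }
  eta <- res$eta[, seq_along(spec$iiv), drop = FALSE]
  colnames(eta) <- paste0("eta_", spec$iiv)
  dplyr::bind_cols(tibble(ID = flat$ids), as_tibble(eta))
}

default_inits <- function(spec) {
  rel <- relation_theta_names(spec)
  th <- setNames(rep(0, length(rel)), rel)
  # weight effects start near the allometric prior, others at no effect
  th[grepl("^WT_", names(th))] <- 1
  pk_params(
    theta = c(c(tvCL = 0.1, tvV = 1.0), th),
    omega = setNames(rep(0.15, length(spec$iiv)), spec$iiv),
    sigma = switch(spec$residual,
                   additive = c(prop = 0, add = 1),
                   proportional = c(prop = 0.2, add = 0),
                   combined = c(prop = 0.2, add = 0.5))
  )
}

#' Fit a population-PK model by FOCE
#'
#' Maximum-likelihood estimation of fixed effects, IIV variances and
#' residual parameters by quasi-Newton (BFGS) minimisation of [foce_ofv()]
#' on transformed parameters (log scale for typical values, IIV and residual
#' SDs; natural scale for covariate coefficients). Conditional modes are
#' warm-started between objective evaluations; optional jittered restarts
#' are seeded and deterministic.
#'
#' @param data Event-record tibble; observations flagged `EXCL` are not
#'   fitted.
#' @param spec A [pk_model_spec()].
#' @param init Optional initial [pk_params()]; defaults to neutral values.
#' @param se Compute standard errors by central-difference Hessian?
#' @param restarts Number of additional jittered starts (best fit wins).
#' @param seed Seed for the restart jitter.
#' @param control List: `reltol`, `maxit` for the outer BFGS.
#' @return A `pk_fit` object: estimates, OFV, empirical Bayes etas,
#'   per-observation residual table (`PRED`, `IPRED`, `CWRES`, `TAD`),
#'   RSE%, convergence flag.
#' @seealso [tidy.pk_fit()], [glance.pk_fit()], [gof_table()]
#' @export
pk_fit <- function(data, spec, init = NULL, se = TRUE, restarts = 0,
                   seed = 1, control = list()) {
  ctl <- utils::modifyList(list(reltol = 1e-10, maxit = 400), control)
  tpl <- par_template(spec)
  if (is.null(init)) init <- default_inits(spec)
  flat <- prepare_fit_data(data, spec)
  d <- max(length(spec$iiv), 1)

  run_one <- function(start_vec) {
    warm <- new.env(parent = emptyenv())
    warm$eta <- matrix(0, flat$n_subjects, d)
    obj <- function(v) {
      params <- try(unpack_params(v, tpl), silent = TRUE)
      if (inherits(params, "try-error")) return(1e10)
      res <- foce_eval(flat, params, spec, eta_warm = warm$eta)
      if (!is.finite(res$ofv)) return(1e10)
      warm$eta <- res$eta
      res$ofv
    }
    opt <- optim(start_vec, obj, method = "BFGS",
                 control = list(reltol = ctl$reltol, maxit = ctl$maxit))
    opt
  }

  start0 <- pack_params(init, tpl)
  fits <- list(run_one(start0))
  if (restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      fits[[r + 1]] <- run_one(start0 + rnorm(length(start0), 0, 0.2))
    }
  }
  best <- fits[[which.min(vapply(fits, function(f) f$value, double(1)))]]
  params <- unpack_params(best$par, tpl)

  detail <- foce_eval(flat, params, spec, detail = TRUE)
  eta <- detail$eta[, seq_along(spec$iiv), drop = FALSE]
  colnames(eta) <- paste0("eta_", spec$iiv)
  etas <- dplyr::bind_cols(tibble(ID = flat$ids), as_tibble(eta))

  resid_tbl <- residual_table(data, detail, flat)

  fit <- structure(list(
    params = params, spec = spec, ofv = best$value,
    etas = etas, residuals = resid_tbl,
    data = data, flat = flat, tpl = tpl,
    convergence = best$convergence == 0,
    message = if (best$convergence == 0) "converged" else
      paste0("optim code ", best$convergence),
    n_subjects = flat$n_subjects, n_obs = length(flat$y),
    vcov = NULL, rse = NULL, se_note = NULL
  ), class = "pk_fit")

  if (se) fit <- add_standard_errors(fit)
  fit
}

# per-observation residual table; TAD = time after most recent dose
residual_table <- function(data, detail, flat) {
  obs <- data[data$EVID == 0 & !data$EXCL, ]
  tad <- numeric(nrow(obs))
  for (j in seq_len(nrow(obs))) {
    dt <- data$TIME[data$ID == obs$ID[j] & data$EVID == 1]
    dt <- dt[dt <= obs$TIME[j]]
    tad[j] <- if (length(dt)) obs$TIME[j] - max(dt) else NA_real_
  }
  tibble(ID = obs$ID, TIME = obs$TIME, TAD = tad, DV = obs$DV,
         PRED = detail$pred, IPRED = detail$ipred, CWRES = detail$cwres)
}

# full central-difference Hessian of f at x
central_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 0.01 * pmax(abs(x), 0.1)
  f0 <- f(x)
  H <- matrix(0, p, p)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

# natural-scale parameter vector of a fit (thetas, omegas, sigmas in use)
natural_par <- function(params, tpl) {
  c(params$theta[tpl$theta],
    setNames(params$omega[tpl$omega], paste0("omega_", tpl$omega)),
    setNames(params$sigma[tpl$sigma], paste0("sigma_", tpl$sigma)))
}

natural_to_params <- function(v, tpl) {
  nt <- length(tpl$theta)
  th <- setNames(v[seq_len(nt)], tpl$theta)
  om <- setNames(v[nt + seq_along(tpl$omega)], tpl$omega)
  si <- setNames(v[nt + length(tpl$omega) + seq_along(tpl$sigma)], tpl$sigma)
  full_sigma <- c(prop = 0, add = 0)
  full_sigma[names(si)] <- si
  pk_params(theta = th, omega = pmax(om, 0), sigma = pmax(full_sigma, 0))
}

#' Standard errors and RSE% for a fitted model
#'
#' Asymptotic covariance from the inverse central-difference Hessian of
#' OFV/2 at the optimum (natural parameter scale). A non-positive-definite
#' Hessian is eigenvalue-adjusted and the result flagged approximate.
#'
#' @param fit A `pk_fit` object.
#' @return The fit with `vcov`, `rse` (percent) and `se_note` filled in.
#' @export
add_standard_errors <- function(fit) {
  tpl <- fit$tpl
  x0 <- natural_par(fit$params, tpl)
  flat <- fit$flat
  warm <- new.env(parent = emptyenv())
  warm$eta <- matrix(0, flat$n_subjects, max(length(fit$spec$iiv), 1))
  f <- function(v) {
    params <- try(natural_to_params(v, tpl), silent = TRUE)
    if (inherits(params, "try-error")) return(1e10)
    res <- foce_eval(flat, params, fit$spec, eta_warm = warm$eta)
    if (!is.finite(res$ofv)) return(1e10)
    warm$eta <- res$eta
    res$ofv / 2
  }
  H <- central_hessian(f, x0)
  ev <- eigen(H, symmetric = TRUE)
  note <- NULL
  if (any(ev$values <= 0)) {
    note <- "Hessian not positive definite; eigenvalue-adjusted SEs (approximate)."
    warn(note)
    vals <- pmax(ev$values, max(abs(ev$values)) * 1e-8)
    H <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  }
  V <- solve(H)
  se <- sqrt(pmax(diag(V), 0))
  fit$vcov <- V
  dimnames(fit$vcov) <- list(names(x0), names(x0))
  fit$rse <- setNames(100 * se / abs(x0), names(x0))
  fit$se_note <- note
  fit
}

#' Residual diagnostics at fixed parameters
#'
#' Computes the per-observation population prediction (`PRED`, eta = 0),
#' individual prediction (`IPRED`, at the empirical Bayes eta) and
#' conditional weighted residual (`CWRES`) for a dataset under a given
#' parameter set, without refitting. `CWRES` whitens the linearised
#' residual with the inverse Cholesky factor of each subject's marginal
#' covariance, so under the generating model it is approximately iid
#' standard normal.
#'
#' @inheritParams foce_ofv
#' @return Tibble: `ID`, `TIME`, `TAD`, `DV`, `PRED`, `IPRED`, `CWRES`.
#' @export
pk_residuals <- function(data, params, spec) {
  flat <- prepare_fit_data(data, spec)
  detail <- foce_eval(flat, params, spec, detail = TRUE)
  if (!is.finite(detail$ofv)) {
    abort(paste0("Singular subject covariance for subject ",
                 flat$ids[detail$failed_subject], "."))
  }
  residual_table(data, detail, flat)
}

#' Population predictions for new data
#'
#' Typical-value (eta = 0) concentration predictions for every non-excluded
#' observation row of an event-record dataset.
#'
#' @inheritParams foce_ofv
#' @return Tibble with `ID`, `TIME`, `DV` and `PRED`.
#' @export
pk_predict <- function(data, params, spec) {
  subjects <- as_subject_list(data)
  out <- purrr::map_dfr(subjects, function(s) {
    ip <- individual_params(s$covariates, params, spec)
    tibble(ID = s$id, TIME = s$obs$time, DV = s$obs$dv,
           PRED = pk_conc(s$obs$time, s$doses, ip$CL, ip$V))
  })
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> FOCE", if (x$convergence) "(converged)" else "(NOT converged)", "\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  cat("  OFV:", format(x$ofv, digits = 8), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fitted population-PK model
#'
#' @param x A `pk_fit` object.
#' @param cv_convention How IIV/residual SDs are expressed as %CV in the
#'   `percent_cv` column: `"sd"` (100·omega) or `"lognormal"`
#'   (100·sqrt(exp(omega^2)-1)).
#' @param ... Unused.
#' @return Tibble with term, type, estimate, std.error, rse (%), percent_cv.
#' @export
tidy.pk_fit <- function(x, cv_convention = c("sd", "lognormal"), ...) {
  cv_convention <- match.arg(cv_convention)
  tpl <- x$tpl
  est <- natural_par(x$params, tpl)
  type <- c(rep("theta", length(tpl$theta)),
            rep("omega", length(tpl$omega)),
            rep("sigma", length(tpl$sigma)))
  cv <- rep(NA_real_, length(est))
  scale_pars <- type %in% c("omega", "sigma")
  cv[scale_pars] <- if (cv_convention == "sd") 100 * est[scale_pars] else
    100 * sqrt(expm1(est[scale_pars]^2))
  out <- tibble(term = names(est), type = type, estimate = unname(est),
                percent_cv = cv)
  if (!is.null(x$rse)) {
    out$rse <- unname(x$rse)
    out$std.error <- abs(out$estimate) * out$rse / 100
  }
  out
}

#' @export
glance.pk_fit <- function(x, ...) {
  p <- length(natural_par(x$params, x$tpl))
  tibble(ofv = x$ofv, n_parameters = p, aic = x$ofv + 2 * p,
         n_subjects = x$n_subjects, n_obs = x$n_obs,
         convergence = x$convergence)
}
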