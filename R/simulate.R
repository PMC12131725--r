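#' Configuration of a synthetic NICU cohort
#'
#' Encodes the study conditions emulated by the cohort generator: marginal
#' covariate distributions (median and IQR of the observed neonatal cohort),
#' the two reported covariate correlations (weight–postmenstrual age 0.8696,
#' weight–daily-fluid-input 0.7274), comedication prevalences, the dosing
#' rule (10–15 mg/kg per dose, every 8 or 12 h, 1-h infusion) and the
#' steady-state sampling rule (trough 0.5 h before and peak 0.5 h after the
#' infusion of the 5th dose, i.e. after a 4-dose run-in).
#'
#' Continuous covariates are drawn from a Gaussian copula with log-normal
#' margins matched by (median, IQR); the copula correlation for each
#' constrained pair is back-solved so that the Pearson correlation of the
#' log-normal margins hits the target.
#'
#' @param margins Tibble with columns `covariate`, `median`, `q1`, `q3`.
#' @param correlations Tibble with columns `a`, `b`, `r` (target Pearson).
#' @param prevalence Named vector of Bernoulli probabilities for binary
#'   covariates (`DA` = diuretic use, etc.).
#' @param ncis_probs Probabilities of the three neonatal-critical-illness
#'   score classes (>90, 70–90, <70).
#' @param dose_mgkg Per-dose range, mg/kg.
#' @param intervals Candidate dosing intervals (h), chosen uniformly.
#' @param infusion_dur Infusion duration (h).
#' @param n_doses Number of doses administered before/around sampling.
#' @param sample_dose_index Dose around which the trough/peak samples are
#'   drawn (the 5th dose: first dose at steady state after a 4-dose run-in).
#' @param trough_offset,peak_offset Sampling offsets (h) before the dose
#'   start / after the infusion end.
#' @param trough_only Fraction of subjects contributing a trough sample only.
#' @param calibration Assay calibration range (mg/L).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    margins = default_margins(),
    correlations = tibble(a = c("WT", "WT"), b = c("PMA", "DFI"),
                          r = c(0.8696, 0.7274)),
    prevalence = c(DA = 0.333, SEX = 0.683, PM = 0.738, RS = 0.302,
                   PTZ = 0.095, HA = 0.198, VAA = 0.317),
    ncis_probs = c(0.079, 0.699, 0.222),
    dose_mgkg = c(10, 15),
    intervals = c(8, 12),
    infusion_dur = 1,
    n_doses = 6,
    sample_dose_index = 5,
    trough_offset = 0.5,
    peak_offset = 0.5,
    trough_only = 0.52,
    calibration = CALIBRATION_RANGE) {
  stopifnot(nrow(margins) > 0, all(margins$q1 < margins$q3),
            all(prevalence >= 0 & prevalence <= 1),
            abs(sum(ncis_probs) - 1) < 1e-8,
            sample_dose_index <= n_doses)
  structure(as.list(environment()), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_margins <- function() {
  tibble(
    covariate = c("WT", "PMA", "SCR", "DFI", "DUV", "ALB", "ALT", "AST", "BUN"),
    median = c(1.98, 35.7, 32.48, 364, 200.5, 28.5, 10.69, 28.95, 3.57),
    q1 = c(1.35, 32.9, 24.54, 252.91, 156.75, 25.07, 6.46, 21.38, 2.31),
    q3 = c(2.98, 39.98, 42.31, 473.1, 283.25, 31.55, 15.53, 41.9, 5.86)
  )
}

# Pearson correlation between two log-normal variables induced by Gaussian
# copula correlation rho: r = (exp(rho s1 s2) - 1) / sqrt((e^{s1^2}-1)(e^{s2^2}-1)).
# Invert to get the copula rho that yields a target Pearson r.
copula_rho_for_pearson <- function(r, s1, s2) {
  arg <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  rho <- log(arg) / (s1 * s2)
  max(min(rho, 0.999), -0.999)
}

nearest_pd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values > 1e-10)) return(S)
  v <- pmax(e$values, 1e-8)
  S2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S2))
  S2 / outer(d, d)
}

#' Simulate baseline covariates for a virtual cohort
#'
#' @param n Number of subjects.
#' @param config A [cohort_config()].
#' @param seed Integer seed (set once; all draws flow from it).
#' @return Tibble with one row per subject: continuous covariates, binary
#'   comedication flags, the 3-level NCIS class and its two dummy indicators
#'   (`NCIS1` = 70–90, `NCIS2` = <70).
#' @export
#' @examples
#' sim_covariates(5, seed = 1)
sim_covariates <- function(n, config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$margins
  if (n == 0) {
    out <- as_tibble(setNames(rep(list(double()), nrow(m)), m$covariate))
    return(out)
  }
  sdlog <- log(m$q3 / m$q1) / (2 * qnorm(0.75))
  names(sdlog) <- m$covariate
  k <- nrow(m)
  R <- diag(k)
  dimnames(R) <- list(m$covariate, m$covariate)
  specified <- matrix(FALSE, k, k, dimnames = dimnames(R))
  for (i in seq_len(nrow(config$correlations))) {
    a <- config$correlations$a[i]
    b <- config$correlations$b[i]
    rho <- copula_rho_for_pearson(config$correlations$r[i], sdlog[[a]], sdlog[[b]])
    R[a, b] <- R[b, a] <- rho
    specified[a, b] <- specified[b, a] <- TRUE
  }
  # unspecified pairs sharing a correlated neighbour get the implied
  # (conditional-independence) correlation, keeping the matrix PD instead
  # of letting an eigenvalue repair attenuate the constrained pairs
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!specified[i, j]) {
      implied <- R[i, -c(i, j)] * R[j, -c(i, j)]
      implied <- implied[specified[i, -c(i, j)] & specified[j, -c(i, j)]]
      if (length(implied)) R[i, j] <- R[j, i] <- max(implied)
    }
  }
  R <- nearest_pd(R)
  z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = R)
  z <- matrix(z, nrow = n)
  x <- vapply(seq_len(k), function(j) {
    qlnorm(pnorm(z[, j]), meanlog = log(m$median[j]), sdlog = sdlog[j])
  }, double(n))
  x <- matrix(x, nrow = n)
  colnames(x) <- m$covariate
  out <- as_tibble(x)
  for (nm in names(config$prevalence)) {
    out[[nm]] <- rbinom(n, 1, config$prevalence[[nm]])
  }
  ncis <- sample(0:2, n, replace = TRUE, prob = config$ncis_probs)
  out$NCIS <- ncis
  out$NCIS1 <- as.integer(ncis == 1)
  out$NCIS2 <- as.integer(ncis == 2)
  out
}

#' Simulate a dosing regimen for one subject
#'
#' Per-dose amount is weight times a uniform draw from the mg/kg range,
#' rounded to 0.5 mg; the dosing interval is drawn uniformly from the
#' candidate intervals and held fixed within subject; all infusions share
#' the configured duration.
#'
#' @param wt Body weight (kg), positive.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return Tibble of dose events (`time`, `amt`, `dur`) plus an `interval`
#'   attribute (h).
#' @export
sim_regimen <- function(wt, config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (wt <= 0) abort("Weight must be positive.")
  interval <- sample(config$intervals, 1)
  amt <- round(wt * runif(config$n_doses, config$dose_mgkg[1], config$dose_mgkg[2]) * 2) / 2
  out <- tibble(time = interval * (seq_len(config$n_doses) - 1),
                amt = amt, dur = config$infusion_dur)
  attr(out, "interval") <- interval
  out
}

#' Simulate a complete PK study dataset
#'
#' Draws a virtual cohort, assigns regimens, samples per-subject random
#' effects, computes true concentrations at the steady-state trough and peak
#' sampling times, applies the residual-error model, and flags observations
#' outside the assay calibration range (flagged, never altered).
#'
#' @param n Number of subjects.
#' @param params Generating [pk_params()].
#' @param spec Generating [pk_model_spec()].
#' @param config A [cohort_config()].
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param trough_only Fraction of subjects contributing trough only
#'   (defaults to the config value).
#' @return Event-record tibble (see [read_pk_dataset()]) with the simulated
#'   random effects attached as attribute `"sim_eta"`.
#' @export
#' @examples
#' d <- sim_pk_dataset(4, seed = 7)
#' dplyr::filter(d, EVID == 0)
sim_pk_dataset <- function(n = 112,
                           params = vanco_final_params(),
                           spec = vanco_final_spec(),
                           config = cohort_config(),
                           seed = NULL,
                           trough_only = config$trough_only) {
  if (!is.null(seed)) set.seed(seed)
  covs <- sim_covariates(n, config)
  d <- length(spec$iiv)
  omega <- rep(0, d)
  names(omega) <- spec$iiv
  have <- intersect(spec$iiv, names(params$omega))
  omega[have] <- params$omega[have]
  eta <- matrix(rnorm(n * d, 0, rep(omega, each = n)), nrow = n, ncol = d,
                dimnames = list(NULL, spec$iiv))
  ip <- individual_params(covs, params, spec, eta = if (d) eta else NULL)

  trough_flag <- rbinom(n, 1, trough_only) == 1
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    reg <- sim_regimen(covs$WT[i], config)
    t_dose <- reg$time[config$sample_dose_index]
    t_trough <- t_dose - config$trough_offset
    t_peak <- t_dose + reg$dur[config$sample_dose_index] + config$peak_offset
    tt <- if (trough_flag[i]) t_trough else c(t_trough, t_peak)
    f <- pk_conc(tt, reg, ip$CL[i], ip$V[i])
    y <- simulate_observations(f, params$sigma, spec$residual)
    dose_rows <- tibble(ID = i, TIME = reg$time, EVID = 1L,
                        AMT = reg$amt, DUR = reg$dur,
                        DV = NA_real_, MDV = 1L)
    obs_rows <- tibble(ID = i, TIME = tt, EVID = 0L,
                       AMT = NA_real_, DUR = NA_real_, DV = y, MDV = 0L)
    sub <- dplyr::arrange(dplyr::bind_rows(dose_rows, obs_rows),
                          .data$TIME, dplyr::desc(.data$EVID))
    rows[[i]] <- dplyr::bind_cols(sub, covs[rep(i, nrow(sub)), ])
  }
  out <- dplyr::bind_rows(rows)
  out <- validate_pk_dataset(out, calibration = config$calibration)
  attr(out, "sim_eta") <- eta
  out
}

# Apply the residual-error model to noiseless predictions; redraws the rare
# draw that would produce a non-positive concentration (proportional error
# with sd ~0.18 makes this a ~1e-8 event).
simulate_observations <- function(f, sigma, residual) {
  nf <- length(f)
  draw <- function() {
    switch(residual,
      additive = f + rnorm(nf, 0, sigma[["add"]]),
      proportional = f * (1 + rnorm(nf, 0, sigma[["prop"]])),
      combined = f * (1 + rnorm(nf, 0, sigma[["prop"]])) + rnorm(nf, 0, sigma[["add"]]),
      abort(paste0("Unknown residual model: ", residual))
    )
  }
  y <- draw()
  for (tries in 1:50) {
    bad <- y <= 0
    if (!any(bad)) break
    y[bad] <- draw()[bad]
  }
  y
}

#' Split a dataset into modeling and validation cohorts
#'
#' Random subject-level split mirroring the study's 112/14 partition.
#'
#' @param data Event-record tibble.
#' @param n_validation Number of validation subjects.
#' @param seed Integer seed.
#' @return List with elements `model` and `validation`.
#' @export
split_cohort <- function(data, n_validation = 14, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data$ID)
  if (n_validation >= length(ids)) abort("n_validation must be < number of subjects.")
  val <- sample(ids, n_validation)
  list(model = dplyr::filter(data, !.data$ID %in% val),
       validation = dplyr::filter(data, .data$ID %in% val))
}
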