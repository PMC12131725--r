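# Model evaluation: nonparametric bootstrap, visual predictive check,
# normalized prediction distribution errors, external-validation prediction
# errors, and goodness-of-fit tables.

resolve_model <- function(fit, params, spec) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "pk_fit"))
    list(params = fit$params, spec = fit$spec)
  } else {
    if (is.null(params) || is.null(spec)) {
      abort("Supply either `fit` or both `params` and `spec`.")
    }
    list(params = params, spec = spec)
  }
}

# Simulate n_sim replicate observation vectors under the model for the
# exact design (doses, times, covariates) of the dataset. Returns a matrix
# (rows = non-excluded observations in subject order, cols = replicates)
# plus the row metadata.
simulate_replicates <- function(data, params, spec, n_sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- as_subject_list(data)
  d <- length(spec$iiv)
  om <- setNames(rep(0, d), spec$iiv)
  have <- intersect(spec$iiv, names(params$omega))
  om[have] <- params$omega[have]
  sig <- sigma_components(params, spec)

  meta <- list()
  sims <- list()
  for (s in subjects) {
    ip <- individual_params(s$covariates, params, spec)
    eta_cl <- if ("CL" %in% spec$iiv) rnorm(n_sim, 0, om[["CL"]]) else numeric(n_sim)
    eta_v <- if ("V" %in% spec$iiv) rnorm(n_sim, 0, om[["V"]]) else numeric(n_sim)
    f <- conc_grid_cpp(s$obs$time, s$doses$time, s$doses$amt, s$doses$dur,
                       ip$CL * exp(eta_cl), ip$V * exp(eta_v))
    n_i <- nrow(f)
    y <- f * (1 + matrix(rnorm(n_i * n_sim, 0, sig[1]), n_i, n_sim)) +
      matrix(rnorm(n_i * n_sim, 0, sig[2]), n_i, n_sim)
    sims[[length(sims) + 1]] <- y
    tad <- vapply(s$obs$time, function(t) {
      dt <- s$doses$time[s$doses$time <= t]
      if (length(dt)) t - max(dt) else NA_real_
    }, double(1))
    meta[[length(meta) + 1]] <- tibble(ID = s$id, TIME = s$obs$time,
                                       TAD = tad, DV = s$obs$dv,
                                       n_obs = n_i)
  }
  list(sim = do.call(rbind, sims), meta = dplyr::bind_rows(meta),
       subjects = subjects)
}

#' Nonparametric bootstrap of a population-PK model
#'
#' Resamples subjects with replacement (keeping the original cohort size),
#' refits the model on each replicate, and summarises each parameter by the
#' median and 2.5–97.5 percentile interval of the successful fits.
#'
#' @param data Event-record tibble.
#' @param spec Model [pk_model_spec()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param init Initial [pk_params()] for the replicate fits; defaults to the
#'   estimates from a fit of the original data (warm start).
#' @param control Passed to [pk_fit()].
#' @return A `pk_bootstrap` object: tibble `summary` (term, median, lower,
#'   upper), `estimates` matrix, `n_success`, `n_requested`, `reliable`
#'   flag (FALSE when more than 20% of replicate fits failed), and the
#'   original-fit estimates.
#' @export
pk_bootstrap <- function(data, spec, n_boot = 1000, seed = 1, init = NULL,
                         control = list()) {
  stopifnot(n_boot >= 1)
  orig_fit <- pk_fit(data, spec, init = init, se = FALSE, control = control)
  tpl <- orig_fit$tpl
  est0 <- natural_par(orig_fit$params, tpl)
  ids <- unique(data$ID)
  set.seed(seed)
  draws <- matrix(sample(ids, length(ids) * n_boot, replace = TRUE),
                  nrow = n_boot)
  out <- matrix(NA_real_, n_boot, length(est0),
                dimnames = list(NULL, names(est0)))
  for (b in seq_len(n_boot)) {
    # rebuild the event table with fresh IDs so duplicated subjects stay distinct
    boot_data <- purrr::imap_dfr(as.list(draws[b, ]), function(id, j) {
      rows <- data[data$ID == id, ]
      rows$ID <- j
      rows
    })
    f <- try(pk_fit(boot_data, spec, init = orig_fit$params, se = FALSE,
                    control = control), silent = TRUE)
    if (!inherits(f, "try-error") && is.finite(f$ofv) && f$convergence) {
      out[b, ] <- natural_par(f$params, tpl)
    }
  }
  ok <- stats::complete.cases(out)
  smry <- tibble(
    term = names(est0),
    estimate = unname(est0),
    median = apply(out[ok, , drop = FALSE], 2, median),
    lower = apply(out[ok, , drop = FALSE], 2, quantile, 0.025),
    upper = apply(out[ok, , drop = FALSE], 2, quantile, 0.975)
  )
  structure(list(summary = smry, estimates = out, n_success = sum(ok),
                 n_requested = n_boot, reliable = mean(!ok) <= 0.2),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("<pk_bootstrap>", x$n_success, "/", x$n_requested, "successful fits",
      if (!x$reliable) "(UNRELIABLE: >20% failures)", "\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under the model (same doses,
#' sampling times and covariates), then compares the observed 5th/50th/95th
#' concentration percentiles with the distribution of the same percentiles
#' across simulated replicates, within bins of time after the most recent
#' dose.
#'
#' @param data Event-record tibble.
#' @param fit A `pk_fit`, or else supply `params` + `spec`.
#' @param params,spec Model parameters and specification (if no `fit`).
#' @param n_sim Number of simulated replicates.
#' @param bins Numeric vector of bin edges on time-after-dose; default:
#'   decile edges of the observed TAD distribution.
#' @param min_bin Bins with fewer observations are merged with a neighbour.
#' @param seed Integer seed.
#' @return A `pk_vpc` object with the per-bin percentile table.
#' @export
pk_vpc <- function(data, fit = NULL, params = NULL, spec = NULL,
                   n_sim = 1000, bins = NULL, min_bin = 5, seed = 1) {
  mod <- resolve_model(fit, params, spec)
  rep <- simulate_replicates(data, mod$params, mod$spec, n_sim, seed = seed)
  tad <- rep$meta$TAD
  if (is.null(bins)) {
    bins <- unique(quantile(tad, probs = seq(0, 1, 0.1), names = FALSE))
  }
  if (length(bins) < 2) bins <- c(bins, bins)
  bins[1] <- -Inf
  bins[length(bins)] <- Inf
  grp <- cut(tad, bins, labels = FALSE, include.lowest = TRUE)
  # merge small bins with their left neighbour
  repeat {
    counts <- table(factor(grp, levels = sort(unique(grp))))
    small <- names(counts)[counts < min_bin]
    if (!length(small) || length(counts) == 1) break
    lvl <- as.integer(small[1])
    others <- sort(unique(grp[grp != lvl]))
    tgt <- if (any(others < lvl)) max(others[others < lvl]) else min(others[others > lvl])
    grp[grp == lvl] <- tgt
  }
  probs <- c(0.05, 0.5, 0.95)
  lv <- sort(unique(grp))
  res <- purrr::map_dfr(lv, function(g) {
    idx <- which(grp == g)
    obs_q <- quantile(rep$meta$DV[idx], probs, names = FALSE)
    simq <- apply(rep$sim[idx, , drop = FALSE], 2, quantile, probs = probs)
    band <- apply(simq, 1, quantile, c(0.025, 0.5, 0.975))
    tibble(bin = g, tad_mid = median(tad[idx]), n = length(idx),
           percentile = c(5, 50, 95),
           observed = obs_q,
           sim_lower = band[1, ], sim_median = band[2, ], sim_upper = band[3, ])
  })
  structure(list(table = res, n_sim = n_sim, bins = bins), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("<pk_vpc>", x$n_sim, "simulations\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates `n_sim` replicate observation vectors under
#' the model, decorrelates observed and simulated vectors with the inverse
#' Cholesky factor of the empirical simulation covariance, and transforms
#' the rank of each decorrelated observation among its simulations (with a
#' half-count correction of 1/(2·n_sim) at the extremes) through the
#' standard-normal quantile function. Under a correct model the NPDE are
#' iid standard normal; this is checked by a t-test (mean 0), a Fisher
#' variance test (variance 1, chi-square based) and a Shapiro-Wilk
#' normality test, with a Bonferroni-adjusted global p-value
#' (3 × min p, capped at 1).
#'
#' @inheritParams pk_vpc
#' @param n_sim Number of simulation replicates.
#' @return A `pk_npde` object: per-observation tibble (`ID`, `TIME`, `pd`,
#'   `npde`) and the test p-values.
#' @export
pk_npde <- function(data, fit = NULL, params = NULL, spec = NULL,
                    n_sim = 2000, seed = 1) {
  mod <- resolve_model(fit, params, spec)
  rep <- simulate_replicates(data, mod$params, mod$spec, n_sim, seed = seed)
  meta <- rep$meta
  npde <- numeric(nrow(meta))
  pd <- numeric(nrow(meta))
  offset <- 0
  for (s in rep$subjects) {
    n_i <- nrow(s$obs)
    idx <- offset + seq_len(n_i)
    offset <- offset + n_i
    Y <- rep$sim[idx, , drop = FALSE]           # n_i x n_sim
    m <- rowMeans(Y)
    S <- stats::cov(t(Y))
    L <- tryCatch(t(chol(S)), error = function(e) {
      # ridge-regularise a singular simulation covariance
      t(chol(S + diag(mean(diag(S)) * 1e-8 + 1e-12, n_i)))
    })
    ystar <- forwardsolve(L, s$obs$dv - m)
    sstar <- forwardsolve(L, Y - m)
    pdi <- rowMeans(matrix(sstar < ystar, n_i, n_sim))
    pdi <- pmin(pmax(pdi, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    pd[idx] <- pdi
    npde[idx] <- qnorm(pdi)
  }
  n <- length(npde)
  p_t <- tryCatch(t.test(npde)$p.value, error = function(e) NA_real_)
  s2 <- var(npde)
  chi <- (n - 1) * s2        # variance test against 1
  p_var <- 2 * min(pchisq(chi, n - 1), 1 - pchisq(chi, n - 1))
  p_sw <- if (n >= 3 && n <= 5000) {
    tryCatch(shapiro.test(npde)$p.value, error = function(e) NA_real_)
  } else NA_real_
  pvals <- c(t_test = p_t, variance = p_var, shapiro = p_sw)
  structure(list(table = dplyr::bind_cols(meta[, c("ID", "TIME", "TAD", "DV")],
                                          tibble(pd = pd, npde = npde)),
                 mean = mean(npde), variance = s2,
                 p_values = pvals,
                 p_global = min(1, 3 * min(pvals, na.rm = TRUE)),
                 n_sim = n_sim),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat("<pk_npde>", nrow(x$table), "observations,", x$n_sim, "simulations\n")
  cat(sprintf("  mean %.4f, variance %.4f\n", x$mean, x$variance))
  cat(sprintf("  t-test p = %.4f, variance-test p = %.4f, Shapiro-Wilk p = %.4f\n",
              x$p_values[1], x$p_values[2], x$p_values[3]))
  cat(sprintf("  global adjusted p = %.4f\n", x$p_global))
  invisible(x)
}

#' External-validation prediction errors
#'
#' Population-prediction (eta = 0) error metrics on a validation cohort:
#' relative prediction error PE = 100·(PRED − OBS)/OBS per observation,
#' summarised as mean prediction error (MPE), mean absolute prediction
#' error (MAPE) and the fractions of observations within ±20% (F20) and
#' ±30% (F30), boundaries inclusive.
#'
#' @param data Validation cohort (event-record tibble with dosing history
#'   and covariates).
#' @param params A [pk_params()].
#' @param spec A [pk_model_spec()].
#' @return One-row tibble: `mpe`, `mape`, `f20`, `f30` (all percent), `n`.
#' @export
prediction_errors <- function(data, params, spec) {
  pred <- pk_predict(data, params, spec)
  keep <- pred$DV > 0
  if (any(!keep)) warn(paste0(sum(!keep), " observation(s) with DV <= 0 skipped."))
  pe <- 100 * (pred$PRED[keep] - pred$DV[keep]) / pred$DV[keep]
  tibble(mpe = mean(pe), mape = mean(abs(pe)),
         f20 = 100 * mean(abs(pe) <= 20), f30 = 100 * mean(abs(pe) <= 30),
         n = sum(keep))
}

#' Goodness-of-fit table
#'
#' One row per fitted observation with `DV`, `PRED`, `IPRED`, `CWRES` and
#' time after dose, ready for the standard four-panel diagnostic display
#' (DV~IPRED, DV~PRED, CWRES~PRED, CWRES~TAD).
#'
#' @param fit A `pk_fit`.
#' @return Tibble.
#' @export
gof_table <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  fit$residuals
}

#' Empirical-Bayes individual parameters
#'
#' Per-subject clearance and volume at the empirical Bayes eta estimates,
#' joined with the subject covariates (for covariate–parameter scatter
#' displays).
#'
#' @param fit A `pk_fit`.
#' @return Tibble: `ID`, covariates, `eta_*`, `CL`, `V`.
#' @export
ebe_parameters <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  covs <- fit$flat$covariates
  d <- length(fit$spec$iiv)
  eta <- as.matrix(fit$etas[, -1, drop = FALSE])
  ip <- individual_params(covs, fit$params, fit$spec,
                          eta = if (d) eta else NULL)
  dplyr::bind_cols(tibble(ID = fit$etas$ID), covs, fit$etas[, -1, drop = FALSE], ip)
}
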