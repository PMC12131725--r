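# Shared fixtures, built in code. Fits are cached per test run so several
# test files can reuse the same (deterministic) fitted object.

fast_ctl <- list(reltol = 1e-9, maxit = 300)

# a small two-sample-per-subject cohort simulated from the published model
small_cohort <- function(n = 40, seed = 101, trough_only = 0, ...) {
  sim_pk_dataset(n, params = vanco_final_params(), spec = vanco_final_spec(),
                 seed = seed, trough_only = trough_only, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one medium fit reused across diagnostic tests
fixture_fit <- function() {
  cached("fit80", {
    d <- small_cohort(n = 80, seed = 202)
    pk_fit(d, vanco_final_spec(), se = FALSE, control = fast_ctl)
  })
}

fixture_fit_data <- function() {
  cached("data80", small_cohort(n = 80, seed = 202))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigen of the Jacobi matrix);
# independent oracle for marginal-likelihood integrals.
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# two subjects with two post-infusion samples each: a design with moderate
# sensitivity of the prediction to eta, where the FOCE linearisation should
# track the exact marginal likelihood closely
quadrature_toy <- function(params, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (i in 1:2) {
    doses <- tibble::tibble(time = 0, amt = 25, dur = 1)
    tt <- c(1.5, 4)
    eta <- rnorm(1, 0, params$omega[["CL"]])
    f <- pk_conc(tt, doses, params$theta[["tvCL"]] * exp(eta),
                 params$theta[["tvV"]])
    y <- f * (1 + rnorm(2, 0, params$sigma[["prop"]]))
    rows[[i]] <- dplyr::bind_rows(
      tibble::tibble(ID = i, TIME = 0, EVID = 1L, AMT = 25, DUR = 1,
                     DV = NA_real_, MDV = 1L),
      tibble::tibble(ID = i, TIME = tt, EVID = 0L, AMT = NA_real_,
                     DUR = NA_real_, DV = y, MDV = 0L))
  }
  validate_pk_dataset(dplyr::bind_rows(rows))
}

# exact -2 log marginal likelihood by adaptive-range GH quadrature for a
# model with a single eta on CL
exact_m2ll_quadrature <- function(data, params, spec, n_nodes = 64) {
  gh <- gauss_hermite(n_nodes)
  omega <- params$omega[["CL"]]
  sp <- params$sigma[["prop"]]
  sa <- params$sigma[["add"]]
  subjects <- neovanc:::as_subject_list(data)
  total <- 0
  for (s in subjects) {
    ip <- individual_params(s$covariates, params, spec)
    g <- vapply(gh$nodes, function(x) {
      eta <- sqrt(2) * omega * x
      f <- pk_conc(s$obs$time, s$doses, ip$CL * exp(eta), ip$V)
      r <- pmax(sa^2 + sp^2 * f^2, 1e-12)
      exp(sum(stats::dnorm(s$obs$dv, f, sqrt(r), log = TRUE)))
    }, double(1))
    lik <- sum(gh$weights * g) / sqrt(pi)
    total <- total - 2 * log(lik)
  }
  total
}
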