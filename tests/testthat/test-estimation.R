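test_that("FOCE objective equals the exact iid-normal -2LL when omega -> 0", {
  d <- small_cohort(n = 12, seed = 5)
  params <- vanco_final_params()
  p0 <- pk_params(theta = params$theta, omega = c(CL = 0),
                  sigma = params$sigma)
  ofv <- foce_ofv(d, p0, vanco_final_spec())
  # closed form: sum over observations of ln R + e^2/R + ln 2pi
  res <- pk_predict(d, p0, vanco_final_spec())
  r <- residual_variance(res$PRED, p0$sigma, "proportional")
  exact <- sum(log(r) + (res$DV - res$PRED)^2 / r + log(2 * pi))
  expect_equal(ofv, exact, tolerance = 1e-8)
})

test_that("FOCE objective agrees with 64-node quadrature on nonlinear toys", {
  spec <- pk_model_spec("proportional", iiv = "CL")
  for (om in c(0.1, 0.2, 0.3)) {
    params <- pk_params(theta = c(tvCL = 0.14, tvV = 1.04),
                        omega = c(CL = om), sigma = c(prop = 0.18))
    d <- quadrature_toy(params)
    ofv <- foce_ofv(d, params, spec)
    exact <- exact_m2ll_quadrature(d, params, spec, n_nodes = 64)
    expect_lt(abs(ofv - exact), 0.1)
  }
})

test_that("empirical Bayes etas match an independent R optimiser and shrink with omega", {
  d <- small_cohort(n = 8, seed = 23)
  params <- vanco_final_params()
  spec <- vanco_final_spec()
  etas <- estimate_etas(d, params, spec)
  # independent route: conditional objective built from pk_conc + optimize()
  subjects <- neovanc:::as_subject_list(d)
  for (s in subjects[1:4]) {
    ip <- individual_params(s$covariates, params, spec)
    obj <- function(eta) {
      f <- pk_conc(s$obs$time, s$doses, ip$CL * exp(eta), ip$V)
      r <- pmax(residual_variance(f, params$sigma, spec$residual), 1e-12)
      sum((s$obs$dv - f)^2 / r + log(r)) + eta^2 / params$omega[["CL"]]^2
    }
    ref <- optimize(obj, c(-2, 2), tol = 1e-10)$minimum
    expect_equal(etas$eta_CL[etas$ID == s$id], ref, tolerance = 1e-4)
  }
  # omega -> 0 limit: complete shrinkage
  p0 <- pk_params(theta = params$theta, omega = c(CL = 1e-9),
                  sigma = params$sigma)
  expect_true(all(abs(estimate_etas(d, p0, spec)$eta_CL) < 1e-6))
})

test_that("etas vanish for self-consistent data", {
  d <- sim_pk_dataset(5, params = pk_params(
    theta = vanco_final_params()$theta,
    omega = c(CL = 1e-12), sigma = c(prop = 1e-12)), seed = 31, trough_only = 0)
  # additive error (no interaction): observations at the typical prediction
  # give exactly eta = 0
  spec_add <- pk_model_spec("additive", iiv = "CL",
                            relations = vanco_final_spec()$relations)
  p_add <- pk_params(theta = vanco_final_params()$theta,
                     omega = c(CL = 0.0497), sigma = c(add = 1))
  expect_true(all(abs(estimate_etas(d, p_add, spec_add)$eta_CL) < 1e-6))
  # proportional error with interaction: the log R(eta) term shifts the
  # conditional mode by O(omega^2 * elasticity), small but nonzero
  etas <- estimate_etas(d, vanco_final_params(), vanco_final_spec())
  expect_true(all(abs(etas$eta_CL) < 0.03))
})

test_that("refitting from a converged solution leaves the OFV unchanged", {
  d <- small_cohort(n = 20, seed = 7)
  fit <- pk_fit(d, vanco_final_spec(), se = FALSE, control = fast_ctl)
  refit <- pk_fit(d, vanco_final_spec(), init = fit$params, se = FALSE,
                  control = fast_ctl)
  expect_lt(abs(refit$ofv - fit$ofv), 1e-4)
  expect_true(fit$convergence)
})

test_that("OFV is invariant to subject ordering", {
  d <- small_cohort(n = 15, seed = 13)
  params <- vanco_final_params()
  ids <- unique(d$ID)
  perm <- rev(ids)
  d2 <- dplyr::bind_rows(lapply(perm, function(i) d[d$ID == i, ]))
  expect_equal(foce_ofv(d, params, vanco_final_spec()),
               foce_ofv(d2, params, vanco_final_spec()), tolerance = 1e-10)
})

test_that("adding a truly active covariate lowers the OFV", {
  d <- small_cohort(n = 50, seed = 19)
  base <- pk_fit(d, vanco_base_spec(), se = FALSE, control = fast_ctl)
  wt_spec <- pk_model_spec("proportional", iiv = c("CL", "V"),
                           relations = covariate_relation("WT", "CL", "power", 2.12))
  wt_fit <- pk_fit(d, wt_spec, se = FALSE, control = fast_ctl)
  expect_lt(wt_fit$ofv, base$ofv)
})

test_that("CWRES behaves like iid standard normal under the generating model", {
  d <- sim_pk_dataset(120, seed = 41, trough_only = 0)
  res <- pk_residuals(d, vanco_final_params(), vanco_final_spec())
  expect_gte(nrow(res), 200)
  expect_lt(abs(mean(res$CWRES)), 0.15)
  expect_gt(var(res$CWRES), 0.7)
  expect_lt(var(res$CWRES), 1.3)
})

test_that("CWRES reduces to the weighted residual when omega -> 0, and IPRED = PRED at eta = 0", {
  d <- small_cohort(n = 10, seed = 47)
  params <- vanco_final_params()
  p0 <- pk_params(theta = params$theta, omega = c(CL = 0), sigma = params$sigma)
  res <- pk_residuals(d, p0, vanco_final_spec())
  expect_equal(res$IPRED, res$PRED)
  r <- residual_variance(res$PRED, p0$sigma, "proportional")
  expect_equal(res$CWRES, (res$DV - res$PRED) / sqrt(r), tolerance = 1e-8)
})

test_that("central-difference Hessian matches an analytic Hessian", {
  f <- function(x) 3 * x[1]^2 + 2 * x[1] * x[2] + 4 * x[2]^2 + x[1]^4
  x0 <- c(0.7, -0.4)
  H <- neovanc:::central_hessian(f, x0, h = c(1e-3, 1e-3))
  exact <- matrix(c(6 + 12 * x0[1]^2, 2, 2, 8), 2, 2)
  expect_equal(H, exact, tolerance = 1e-4)
})

test_that("standard errors are delta-method consistent and ordered as expected", {
  fit <- cached("fit80_se", add_standard_errors(fixture_fit()))
  rse <- fit$rse
  expect_true(all(is.finite(rse)))
  # typical clearance is the best-determined fixed effect; the weak Scr
  # exponent is the worst
  expect_lt(rse[["tvCL"]], rse[["SCR_CL"]])
  # reparameterisation check: recompute the Hessian in log(tvCL) coordinates;
  # the delta method says SE_log * tvCL should reproduce the natural SE
  est <- neovanc:::natural_par(fit$params, fit$tpl)
  flat <- fit$flat
  f_log1 <- function(v) {
    w <- v; w[1] <- exp(v[1])
    params <- neovanc:::natural_to_params(w, fit$tpl)
    neovanc:::foce_eval(flat, params, fit$spec)$ofv / 2
  }
  x_log <- est; x_log[1] <- log(est[1])
  H_log <- neovanc:::central_hessian(f_log1, x_log)
  se_log <- sqrt(diag(solve(H_log)))[1]
  se_nat <- sqrt(diag(fit$vcov))[1]
  expect_equal(se_log * est[[1]], se_nat, tolerance = 0.05,
               ignore_attr = TRUE)
})
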