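test_that("final covariate model reproduces typical values at the reference covariates", {
  refs <- tibble::tibble(WT = 2.12, SCR = 30.52, DFI = 367.18, DA = 0)
  ip <- individual_params(refs, vanco_final_params(), vanco_final_spec())
  expect_equal(ip$CL, 0.14)
  expect_equal(ip$V, 1.04)

  # diuretic indicator scales CL by exp(-0.20)
  ip_da <- individual_params(dplyr::mutate(refs, DA = 1),
                             vanco_final_params(), vanco_final_spec())
  expect_equal(ip_da$CL, 0.14 * exp(-0.20))
  expect_equal(ip_da$V, ip$V)

  # any theta returns its typical values exactly at the centering constants
  th <- pk_params(theta = c(tvCL = 0.2, tvV = 2, WT_CL = 0.7, SCR_CL = -0.4,
                            DFI_CL = 0.3, DA_CL = 0.5, WT_V = 1.4),
                  omega = c(CL = 0.1), sigma = c(prop = 0.2))
  ip2 <- individual_params(refs, th, vanco_final_spec())
  expect_equal(ip2$CL, 0.2)
  expect_equal(ip2$V, 2)
})

test_that("power terms are log-linear in the covariate", {
  refs <- tibble::tibble(WT = c(2.12, 2 * 2.12), SCR = 30.52,
                         DFI = 367.18, DA = 0)
  ip <- individual_params(refs, vanco_final_params(), vanco_final_spec())
  expect_equal(ip$CL[2] / ip$CL[1], 2^1.13)
  expect_equal(ip$V[2] / ip$V[1], 2^1.07)
})

test_that("individual parameters are monotone with the sign of each exponent", {
  params <- vanco_final_params()
  spec <- vanco_final_spec()
  scr <- seq(10, 90, length.out = 7)
  cl_scr <- individual_params(
    tibble::tibble(WT = 2, SCR = scr, DFI = 350, DA = 0), params, spec)$CL
  expect_true(all(diff(cl_scr) < 0))  # Scr exponent -0.15
  dfi <- seq(100, 700, length.out = 7)
  cl_dfi <- individual_params(
    tibble::tibble(WT = 2, SCR = 30, DFI = dfi, DA = 0), params, spec)$CL
  expect_true(all(diff(cl_dfi) > 0))  # DFI exponent +0.14
})

test_that("covariate model rejects invalid input", {
  params <- vanco_final_params()
  spec <- vanco_final_spec()
  expect_error(individual_params(tibble::tibble(WT = -1, SCR = 30, DFI = 300, DA = 0),
                                 params, spec), "positive")
  expect_error(individual_params(tibble::tibble(WT = 2, SCR = 30, DA = 0),
                                 params, spec), "Missing covariate")
})

test_that("concentration is zero before dosing and superposition is linear", {
  reg <- tibble::tibble(time = c(0, 8, 16), amt = c(25, 30, 25), dur = 1)
  expect_equal(pk_conc(0, reg, 0.14, 1.04), 0)
  t <- seq(0.25, 30, by = 0.25)
  c1 <- pk_conc(t, reg, 0.14, 1.04)
  c2 <- pk_conc(t, dplyr::mutate(reg, amt = 2 * amt), 0.14, 1.04)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  # additivity over dose events
  csum <- Reduce(`+`, lapply(1:3, function(k) pk_conc(t, reg[k, ], 0.14, 1.04)))
  expect_equal(csum, c1, tolerance = 1e-12)
  expect_error(pk_conc(-1, reg, 0.14, 1.04), "non-negative")
})

test_that("analytic profile matches an ODE-solver oracle on random regimens", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (rep in 1:5) {
    nd <- sample(1:10, 1)
    reg <- tibble::tibble(time = sort(runif(nd, 0, 48)),
                          amt = runif(nd, 10, 60),
                          dur = runif(nd, 0.5, 2))
    CL <- runif(1, 0.01, 1); V <- runif(1, 0.1, 5)
    rate_fun <- function(t) {
      sum(reg$amt / reg$dur * (t >= reg$time & t < reg$time + reg$dur))
    }
    deriv <- function(t, y, p) list(rate_fun(t) / V - CL / V * y)
    tout <- sort(c(seq(0.5, 60, by = 1.37), reg$time + reg$dur))
    ode <- deSolve::ode(c(C = 0), times = c(0, tout), func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12, hmax = 0.05)
    expect_equal(pk_conc(tout, reg, CL, V), unname(ode[-1, "C"]),
                 tolerance = 1e-6)
  }
})

test_that("residual-error variance follows the three error models", {
  expect_equal(residual_variance(10, c(prop = 0.18), "proportional"), 3.24)
  expect_equal(residual_variance(c(0, 5, 50), c(add = 0.5), "additive"),
               rep(0.25, 3))
  f <- c(1, 7, 23)
  expect_equal(residual_variance(f, c(prop = 0.18, add = 0.5), "combined"),
               residual_variance(f, c(prop = 0.18), "proportional") +
                 residual_variance(f, c(add = 0.5), "additive"))
  expect_error(residual_variance(1, c(prop = 0.1), "weird"), "Unknown residual")
})

test_that("steady-state AUC24 equals dose over clearance and matches integration", {
  expect_equal(auc24_ss(56, 0.14), 400)
  expect_equal(auc24_ss(0, 0.14), 0)
  # long-run superposition oracle: trapezoidal AUC over one day at steady state
  CL <- 0.14; V <- 1.04
  reg <- tibble::tibble(time = seq(0, 12 * 40, by = 12), amt = 28, dur = 1)
  t <- seq(12 * 38, 12 * 40, by = 0.01)
  conc <- pk_conc(t, reg, CL, V)
  auc24 <- sum((conc[-1] + conc[-length(conc)]) / 2 * diff(t))
  expect_equal(auc24, auc24_ss(2 * 28, CL), tolerance = 0.005)
})
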