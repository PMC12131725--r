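test_that("bootstrap of a cohort of cloned subjects has zero-width intervals", {
  one <- small_cohort(n = 1, seed = 83)
  clones <- dplyr::bind_rows(lapply(1:10, function(i) {
    x <- one
    x$ID <- i
    x
  }))
  bs <- pk_bootstrap(clones, vanco_final_spec(), n_boot = 5, seed = 1,
                     control = fast_ctl)
  expect_equal(bs$n_success, 5)
  width <- bs$summary$upper - bs$summary$lower
  expect_true(all(width < 1e-6))
})

test_that("bootstrap medians track the generating typical values and bracket the estimate", {
  d <- small_cohort(n = 40, seed = 89)
  bs <- cached("boot40", pk_bootstrap(d, vanco_final_spec(), n_boot = 30,
                                      seed = 2, control = fast_ctl))
  expect_true(bs$reliable)
  s <- bs$summary
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  for (term in c("tvCL", "tvV")) {
    row <- s[s$term == term, ]
    truth <- vanco_final_params()$theta[[term]]
    expect_lt(abs(row$median - truth) / truth, 0.10)
    expect_true(row$lower <= row$estimate && row$estimate <= row$upper)
  }
})

test_that("VPC is self-consistent under the generating model and detects misspecification", {
  d <- sim_pk_dataset(112, seed = 97, trough_only = 0.5)
  vpc <- pk_vpc(d, params = vanco_final_params(), spec = vanco_final_spec(),
                n_sim = 400, seed = 3)
  tb <- vpc$table
  # percentile ordering within every bin
  ord <- tb |>
    dplyr::group_by(bin) |>
    dplyr::summarise(ok = all(diff(observed[order(percentile)]) >= 0) &&
                       all(diff(sim_median[order(percentile)]) >= 0))
  expect_true(all(ord$ok))
  inside <- mean(tb$observed >= tb$sim_lower & tb$observed <= tb$sim_upper)
  expect_gte(inside, 0.9)
  # gross misspecification: observations scaled by 10 leave the bands
  d10 <- d
  d10$DV[d10$EVID == 0] <- d10$DV[d10$EVID == 0] * 10
  vpc10 <- pk_vpc(d10, params = vanco_final_params(), spec = vanco_final_spec(),
                  n_sim = 200, seed = 3)
  med <- vpc10$table[vpc10$table$percentile == 50, ]
  expect_gt(mean(med$observed > med$sim_upper), 0.5)
})

test_that("VPC band edges are estimated more precisely as the simulation count grows", {
  # the band converges to the predictive-percentile distribution; what
  # shrinks with n_sim is the Monte-Carlo error of its edges, measured here
  # as the edge discrepancy between two independent simulation seeds
  d <- sim_pk_dataset(60, seed = 101, trough_only = 0.5)
  edge_jitter <- function(n_sim) {
    v1 <- pk_vpc(d, params = vanco_final_params(), spec = vanco_final_spec(),
                 n_sim = n_sim, seed = 5)
    v2 <- pk_vpc(d, params = vanco_final_params(), spec = vanco_final_spec(),
                 n_sim = n_sim, seed = 6)
    mean(abs(v1$table$sim_lower - v2$table$sim_lower) +
           abs(v1$table$sim_upper - v2$table$sim_upper))
  }
  expect_lt(edge_jitter(1000), edge_jitter(100))
})

test_that("NPDE is calibrated under the generating model", {
  d <- sim_pk_dataset(150, seed = 103, trough_only = 0)
  npde <- pk_npde(d, params = vanco_final_params(), spec = vanco_final_spec(),
                  n_sim = 1000, seed = 7)
  expect_gte(nrow(npde$table), 250)
  expect_lte(abs(npde$mean), 0.1)
  expect_gte(npde$variance, 0.85)
  expect_lte(npde$variance, 1.15)
  expect_true(all(npde$p_values >= 0 & npde$p_values <= 1, na.rm = TRUE))
  expect_equal(npde$p_global, min(1, 3 * min(npde$p_values, na.rm = TRUE)))
})

test_that("an observation below every simulation gets the half-count pd", {
  # data generated at the published clearance, evaluated under a low-CL
  # model whose simulated troughs all exceed the observations
  d <- sim_pk_dataset(3, params = pk_params(
    theta = c(vanco_final_params()$theta), omega = c(CL = 1e-3),
    sigma = c(prop = 1e-3)), seed = 107, trough_only = 1)
  low_cl <- pk_params(theta = replace(vanco_final_params()$theta, 1, 0.05),
                      omega = c(CL = 1e-3), sigma = c(prop = 1e-3))
  n_sim <- 200
  npde <- pk_npde(d, params = low_cl, spec = vanco_final_spec(),
                  n_sim = n_sim, seed = 9)
  expect_true(all(npde$table$pd == 1 / (2 * n_sim)))
  expect_true(all(is.finite(npde$table$npde)))
  expect_true(all(npde$table$npde < 0))
})

test_that("the NPDE t-test holds its nominal level under the true model", {
  rejections <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    d <- sim_pk_dataset(12, seed = 1000 + r, trough_only = 0.5)
    npde <- pk_npde(d, params = vanco_final_params(), spec = vanco_final_spec(),
                    n_sim = 250, seed = 2000 + r)
    if (npde$p_values[["t_test"]] < 0.05) rejections <- rejections + 1
  }
  # nominal 5%: with 60 replicates, 10 rejections is already p < 1e-3
  expect_lte(rejections, 9)
})

test_that("prediction errors reproduce hand-computed cases and are scale-consistent", {
  # build a sigma-free dataset, then displace observations by exactly +/-20%
  d <- sim_pk_dataset(4, params = pk_params(
    theta = vanco_final_params()$theta, omega = c(CL = 1e-12),
    sigma = c(prop = 1e-12)), seed = 109, trough_only = 0)
  pred <- pk_predict(d, vanco_final_params(), vanco_final_spec())
  obs_rows <- which(d$EVID == 0)
  # PRED/OBS = 1 +/- 0.2 alternating -> PE = -16.67% / +25%
  d$DV[obs_rows] <- pred$PRED * rep(c(1.2, 0.8), length.out = length(obs_rows))
  d$EXCL <- FALSE
  pe <- prediction_errors(d, vanco_final_params(), vanco_final_spec())
  expect_equal(pe$mpe, mean(c(100 * (1 / 1.2 - 1), 100 * (1 / 0.8 - 1))),
               tolerance = 1e-8)
  expect_equal(pe$f20, 50)   # only the -16.67% errors are within 20%
  expect_equal(pe$f30, 100)  # +25% within 30%, inclusive convention
  expect_gte(pe$mape, abs(pe$mpe))

  # perfect predictions
  d2 <- d
  d2$DV[obs_rows] <- pred$PRED
  pe2 <- prediction_errors(d2, vanco_final_params(), vanco_final_spec())
  expect_equal(unlist(pe2[c("mpe", "mape")]), c(mpe = 0, mape = 0))
  expect_equal(unlist(pe2[c("f20", "f30")]), c(f20 = 100, f30 = 100))

  # scale consistency: double all amounts and observations
  d3 <- d
  d3$AMT <- d3$AMT * 2
  d3$DV[obs_rows] <- d3$DV[obs_rows] * 2
  pe3 <- prediction_errors(d3, vanco_final_params(), vanco_final_spec())
  expect_equal(as.data.frame(pe3), as.data.frame(pe), tolerance = 1e-10)
})

test_that("goodness-of-fit tables have one row per fitted observation", {
  fit <- fixture_fit()
  d <- fixture_fit_data()
  g <- gof_table(fit)
  expect_equal(nrow(g), sum(d$EVID == 0 & !d$EXCL))
  expect_true(all(c("DV", "PRED", "IPRED", "CWRES", "TAD") %in% names(g)))
  # near-noiseless data sit on the identity line
  dq <- sim_pk_dataset(10, params = pk_params(
    theta = vanco_final_params()$theta, omega = c(CL = 1e-12),
    sigma = c(prop = 1e-3)), seed = 113, trough_only = 0)
  rq <- pk_residuals(dq, vanco_final_params(), vanco_final_spec())
  expect_equal(rq$IPRED, rq$DV, tolerance = 0.02)
})

test_that("EBE clearance falls with serum creatinine in final-model data", {
  fit <- fixture_fit()
  ebe <- ebe_parameters(fit)
  expect_lt(cor(ebe$SCR, ebe$CL / ebe$WT^1.13, method = "spearman"), 0)
})

test_that("diagnostic plots build without error", {
  fit <- fixture_fit()
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_cl_covariate(fit, "SCR"), "ggplot")
  d <- fixture_fit_data()
  v <- pk_vpc(d, fit = fit, n_sim = 100, seed = 11)
  expect_s3_class(autoplot(v), "ggplot")
  np <- pk_npde(d, fit = fit, n_sim = 100, seed = 11)
  expect_s3_class(autoplot(np), "ggplot")
})
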