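# Dose derivation from the AUC24/MIC >= 400 efficacy target. At steady
# state AUC24 = daily dose / CL, so the target is met exactly by
# dose = 400 * MIC * CL (mg/day).

#' Daily dose achieving the AUC/MIC target
#'
#' @param CL Clearance (L/h), positive.
#' @param mic Minimum inhibitory concentration (mg/L), positive; default 1.
#' @param target_ratio Target AUC24/MIC; default 400.
#' @return Daily dose (mg/day) such that [auc24_ss()] at that dose equals
#'   `target_ratio * mic` exactly.
#' @export
#' @examples
#' daily_dose_for_target(0.14)  # 56 mg/day
daily_dose_for_target <- function(CL, mic = 1, target_ratio = 400) {
  if (any(CL <= 0)) abort("CL must be strictly positive.")
  if (any(mic <= 0)) abort("mic must be strictly positive.")
  target_ratio * mic * CL
}

round_half_up <- function(x) floor(x + 0.5)

#' Monte-Carlo initial-dose table
#'
#' For every combination of serum creatinine level, daily fluid input level
#' and diuretic status, simulates `n_sim` virtual neonates (body weight
#' uniform over `weight_range`, clearance random effect
#' \eqn{\eta_{CL} \sim N(0, \omega^2)}), computes each patient's
#' target-attaining per-kg daily dose \eqn{400 \cdot MIC \cdot CL / WT},
#' and reports the cell median rounded half-up to an integer mg/kg/day.
#' Residual (assay) error does not enter: steady-state AUC is a function of
#' clearance only.
#'
#' @param params Final-model [pk_params()].
#' @param spec Final-model [pk_model_spec()].
#' @param scr_levels Serum creatinine grid (µmol/L).
#' @param dfi_levels Daily fluid input grid (mL).
#' @param weight_range Simulated body-weight range (kg).
#' @param mic MIC (mg/L).
#' @param n_sim Simulated patients per cell (>= 100).
#' @param seed Integer seed.
#' @return A `pk_dose_table` object whose `table` is a tibble with one row
#'   per (SCR, DFI) and columns `dose_da` / `dose_nonda` (mg/kg/day).
#' @export
dose_table <- function(params = vanco_final_params(), spec = vanco_final_spec(),
                       scr_levels = c(10, 30, 50, 70, 90),
                       dfi_levels = c(100, 250, 400, 550, 700),
                       weight_range = c(1, 5), mic = 1,
                       n_sim = 5000, seed = 1) {
  stopifnot(length(scr_levels) >= 1, length(dfi_levels) >= 1, n_sim >= 100)
  set.seed(seed)
  om <- if ("CL" %in% names(params$omega)) params$omega[["CL"]] else 0
  grid <- tidyr::expand_grid(SCR = scr_levels, DFI = dfi_levels, DA = c(1, 0))
  doses <- vapply(seq_len(nrow(grid)), function(i) {
    wt <- runif(n_sim, weight_range[1], weight_range[2])
    eta <- matrix(rnorm(n_sim, 0, om), ncol = 1)
    covs <- tibble(WT = wt, SCR = grid$SCR[i], DFI = grid$DFI[i], DA = grid$DA[i])
    if (length(spec$iiv) > 1) {
      eta <- cbind(eta, matrix(0, n_sim, length(spec$iiv) - 1))
    }
    cl <- individual_params(covs, params, spec,
                            eta = if (length(spec$iiv)) eta else NULL)$CL
    median(daily_dose_for_target(cl, mic = mic) / wt)
  }, double(1))
  grid$dose <- round_half_up(doses)
  tab <- tidyr::pivot_wider(grid, names_from = "DA", values_from = "dose",
                            names_prefix = "da")
  tab <- dplyr::rename(tab, dose_da = "da1", dose_nonda = "da0")
  structure(list(table = tab, n_sim = n_sim, mic = mic,
                 weight_range = weight_range), class = "pk_dose_table")
}

#' @export
print.pk_dose_table <- function(x, ...) {
  cat("<pk_dose_table> mg/kg/day to reach AUC24/MIC >= 400 (MIC", x$mic, "mg/L)\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' @describeIn dose_table write the grid as CSV.
#' @param x A `pk_dose_table`.
#' @param path Output CSV path.
#' @export
write_dose_table <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
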