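#' Define a population-PK model specification
#'
#' A model specification couples the structural one-compartment IV-infusion
#' model with (i) a residual-error model, (ii) the set of parameters carrying
#' exponential inter-individual variability (IIV), and (iii) covariate
#' relations on clearance (`CL`) and volume (`V`).
#'
#' Continuous covariates enter as power terms
#' \eqn{(x/x_{ref})^{\theta}} with an explicit centering constant
#' \eqn{x_{ref}}; binary covariates enter as exponential indicators
#' \eqn{e^{\theta I}}. Centering constants are part of the specification and
#' are never recomputed silently.
#'
#' @param residual Residual-error model: `"proportional"`, `"additive"` or
#'   `"combined"`.
#' @param iiv Character vector of parameters with IIV, a subset of
#'   `c("CL", "V")`.
#' @param relations Tibble with columns `covariate`, `parameter`
#'   (`"CL"`/`"V"`), `form` (`"power"`/`"exp"`) and `ref` (centering constant
#'   for the power form, `NA` for indicators). `NULL` means no covariates.
#' @return An object of class `pk_model_spec`.
#' @seealso [vanco_final_spec()], [pk_params()], [individual_params()]
#' @export
#' @examples
#' pk_model_spec("proportional", iiv = "CL",
#'               relations = covariate_relation("WT", "CL", "power", 2.12))
pk_model_spec <- function(residual = c("proportional", "additive", "combined"),
                          iiv = "CL",
                          relations = NULL) {
  residual <- match.arg(residual)
  if (!all(iiv %in% c("CL", "V"))) {
    abort("`iiv` must be a subset of c(\"CL\", \"V\").")
  }
  iiv <- intersect(c("CL", "V"), iiv)  # canonical order
  if (is.null(relations)) {
    relations <- tibble(covariate = character(), parameter = character(),
                        form = character(), ref = double())
  }
  relations <- as_tibble(relations)
  stopifnot(all(c("covariate", "parameter", "form", "ref") %in% names(relations)))
  if (!all(relations$parameter %in% c("CL", "V"))) {
    abort("Covariate relations must target \"CL\" or \"V\".")
  }
  if (!all(relations$form %in% c("power", "exp"))) {
    abort("Covariate form must be \"power\" or \"exp\".")
  }
  bad <- relations$form == "power" & !(is.finite(relations$ref) & relations$ref > 0)
  if (any(bad)) {
    abort("Power-form relations need a positive centering constant `ref`.")
  }
  structure(list(residual = residual, iiv = iiv, relations = relations),
            class = "pk_model_spec")
}

#' @rdname pk_model_spec
#' @param covariate,parameter,form,ref Single covariate relation fields.
#' @export
covariate_relation <- function(covariate, parameter, form, ref = NA_real_) {
  tibble(covariate = covariate, parameter = parameter, form = form,
         ref = as.double(ref))
}

# canonical fixed-effect name for a covariate relation
relation_theta_names <- function(spec) {
  if (nrow(spec$relations) == 0) return(character())
  paste(spec$relations$covariate, spec$relations$parameter, sep = "_")
}

#' Parameter set for a population-PK model
#'
#' @param theta Named numeric vector of fixed effects: `tvCL` (L/h), `tvV`
#'   (L), plus one coefficient per covariate relation named
#'   `<covariate>_<parameter>` (e.g. `WT_CL`).
#' @param omega Named numeric vector of IIV standard deviations (SD of the
#'   log-normal random effect eta), named by parameter (`CL`, `V`).
#' @param sigma Named numeric vector `c(prop = , add = )`: proportional SD
#'   (unitless fraction) and additive SD (mg/L) of the residual model.
#' @return An object of class `pk_params`.
#' @export
#' @examples
#' pk_params(theta = c(tvCL = 0.14, tvV = 1.04),
#'           omega = c(CL = 0.05), sigma = c(prop = 0.18))
pk_params <- function(theta, omega = c(CL = 0), sigma = c(prop = 0.2, add = 0)) {
  theta <- unlist(theta)
  if (!all(c("tvCL", "tvV") %in% names(theta))) {
    abort("`theta` must contain tvCL and tvV.")
  }
  if (theta[["tvCL"]] <= 0 || theta[["tvV"]] <= 0) {
    abort("Typical values tvCL and tvV must be strictly positive.")
  }
  omega <- unlist(omega)
  if (any(omega < 0)) abort("`omega` entries must be non-negative.")
  sigma <- unlist(sigma)
  full <- c(prop = 0, add = 0)
  full[names(sigma)] <- sigma
  if (any(full < 0)) abort("`sigma` entries must be non-negative.")
  if (all(full == 0)) abort("At least one residual-error component must be positive.")
  structure(list(theta = theta, omega = omega, sigma = full),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params>\n")
  cat("  theta:", paste0(names(x$theta), "=", signif(x$theta, 4), collapse = ", "), "\n")
  cat("  omega (SD of eta):",
      if (length(x$omega)) paste0(names(x$omega), "=", signif(x$omega, 4), collapse = ", ") else "none", "\n")
  cat("  sigma:", paste0(names(x$sigma), "=", signif(x$sigma, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cat("<pk_model_spec>\n")
  cat("  residual error:", x$residual, "\n")
  cat("  IIV on:", if (length(x$iiv)) paste(x$iiv, collapse = ", ") else "none", "\n")
  if (nrow(x$relations)) {
    cat("  covariate relations:\n")
    for (i in seq_len(nrow(x$relations))) {
      r <- x$relations[i, ]
      cat("    ", r$covariate, "on", r$parameter,
          if (r$form == "power") sprintf("(power, ref %.4g)", r$ref) else "(indicator)", "\n")
    }
  } else {
    cat("  covariate relations: none\n")
  }
  invisible(x)
}

#' @export
tidy.pk_params <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = names(x$theta), type = "theta", estimate = unname(x$theta)),
    tibble(term = paste0("omega_", names(x$omega)), type = "omega",
           estimate = unname(x$omega)),
    tibble(term = paste0("sigma_", names(x$sigma)), type = "sigma",
           estimate = unname(x$sigma))
  )
}

#' Published vancomycin model for NICU neonates
#'
#' `vanco_final_spec()` / `vanco_final_params()` return the final covariate
#' model for intravenous vancomycin in non-extremely preterm NICU neonates:
#' \deqn{CL = 0.14 \cdot (WT/2.12)^{1.13} (Scr/30.52)^{-0.15}
#'   (DFI/367.18)^{0.14} e^{-0.20\,DA} e^{\eta_{CL}}}
#' \deqn{V = 1.04 \cdot (WT/2.12)^{1.07}}
#' with proportional residual error (18% CV) and IIV on CL (4.97% CV).
#' `vanco_base_spec()` / `vanco_base_params()` give the covariate-free base
#' model (IIV on CL and V).
#'
#' @return A [pk_model_spec()] or [pk_params()] object.
#' @export
vanco_final_spec <- function() {
  ref <- vanco_reference_covariates()
  pk_model_spec(
    residual = "proportional",
    iiv = "CL",
    relations = dplyr::bind_rows(
      covariate_relation("WT", "CL", "power", ref[["WT"]]),
      covariate_relation("SCR", "CL", "power", ref[["SCR"]]),
      covariate_relation("DFI", "CL", "power", ref[["DFI"]]),
      covariate_relation("DA", "CL", "exp"),
      covariate_relation("WT", "V", "power", ref[["WT"]])
    )
  )
}

#' @rdname vanco_final_spec
#' @export
vanco_final_params <- function() {
  pk_params(
    theta = c(tvCL = 0.14, tvV = 1.04,
              WT_CL = 1.13, SCR_CL = -0.15, DFI_CL = 0.14, DA_CL = -0.20,
              WT_V = 1.07),
    omega = c(CL = 0.0497),
    sigma = c(prop = 0.18, add = 0)
  )
}

#' @rdname vanco_final_spec
#' @export
vanco_base_spec <- function() {
  pk_model_spec(residual = "proportional", iiv = c("CL", "V"))
}

#' @rdname vanco_final_spec
#' @export
vanco_base_params <- function() {
  pk_params(theta = c(tvCL = 0.12, tvV = 0.95),
            omega = c(CL = 0.2484, V = 0.009),
            sigma = c(prop = 0.283, add = 0))
}

#' @rdname vanco_final_spec
#' @export
vanco_reference_covariates <- function() {
  c(WT = 2.12, SCR = 30.52, DFI = 367.18)
}
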