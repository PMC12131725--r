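# Stepwise covariate model building with likelihood-ratio gates on the OFV:
# forward addition requires a drop > 3.84 (chi-square, p < 0.05, df = 1),
# backward elimination retains a covariate only if its removal raises the
# OFV by more than 7.88 (p < 0.005, df = 1).

CONTINUOUS_COVS <- c("WT", "PMA", "SCR", "ALB", "ALT", "AST", "BUN", "DFI", "DUV")
BINARY_COVS <- c("SEX", "PM", "DA", "RS", "PTZ", "HA", "VAA", "NCIS1", "NCIS2")

#' Default covariate candidate set
#'
#' Builds the screening candidates from the columns present in a dataset:
#' every continuous covariate as a power relation (centered at the
#' per-subject median of the dataset) and every binary covariate as an
#' exponential indicator, each tested on both CL and V. The 3-level NCIS
#' class enters as its two dummy indicators.
#'
#' @param data Event-record tibble.
#' @param parameters Parameters to test covariates on.
#' @return Tibble of candidate relations (`covariate`, `parameter`, `form`,
#'   `ref`).
#' @export
default_candidates <- function(data, parameters = c("CL", "V")) {
  subjects <- as_subject_list(data)
  covs <- dplyr::bind_rows(lapply(subjects, function(s) s$covariates))
  cont <- intersect(CONTINUOUS_COVS, names(covs))
  bin <- intersect(BINARY_COVS, names(covs))
  out <- list()
  for (p in parameters) {
    for (cv in cont) {
      out[[length(out) + 1]] <- covariate_relation(cv, p, "power",
                                                  median(covs[[cv]]))
    }
    for (cv in bin) {
      out[[length(out) + 1]] <- covariate_relation(cv, p, "exp")
    }
  }
  dplyr::bind_rows(out)
}

add_relation_to_spec <- function(spec, rel) {
  pk_model_spec(residual = spec$residual, iiv = spec$iiv,
                relations = dplyr::bind_rows(spec$relations, rel))
}

drop_relation_from_spec <- function(spec, idx) {
  pk_model_spec(residual = spec$residual, iiv = spec$iiv,
                relations = spec$relations[-idx, ])
}

# init for an extended spec: carry over estimates, start new coefficients
# at the allometric prior for weight and at no-effect otherwise
extend_init <- function(params, new_spec) {
  need <- relation_theta_names(new_spec)
  th <- params$theta
  for (nm in setdiff(need, names(th))) {
    th[nm] <- if (grepl("^WT_", nm)) 1 else 0
  }
  th <- th[c("tvCL", "tvV", need)]
  pk_params(theta = th, omega = params$omega, sigma = params$sigma)
}

shrink_init <- function(params, new_spec) {
  need <- c("tvCL", "tvV", relation_theta_names(new_spec))
  pk_params(theta = params$theta[need], omega = params$omega,
            sigma = params$sigma)
}

#' Univariate covariate screening
#'
#' Fits the base model plus each candidate relation in turn and records the
#' OFV change (negative = improvement over the base model, the study's sign
#' convention).
#'
#' @param data Event-record tibble.
#' @param base_spec Base [pk_model_spec()].
#' @param candidates Tibble of candidate relations (see
#'   [default_candidates()]).
#' @param base_fit Optional pre-computed base-model `pk_fit`.
#' @param control Passed to [pk_fit()].
#' @return Tibble of screen records: `step`, `covariate`, `parameter`,
#'   `form`, `delta_ofv`, `decision`.
#' @export
screen_covariates <- function(data, base_spec, candidates = default_candidates(data),
                              base_fit = NULL, control = list()) {
  if (is.null(base_fit)) {
    base_fit <- pk_fit(data, base_spec, se = FALSE, control = control)
  }
  records <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    rel <- candidates[i, ]
    cand_spec <- add_relation_to_spec(base_spec, rel)
    fit <- try(pk_fit(data, cand_spec, init = extend_init(base_fit$params, cand_spec),
                      se = FALSE, control = control), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$ofv)) {
      records[[i]] <- tibble(step = "univariate", covariate = rel$covariate,
                             parameter = rel$parameter, form = rel$form,
                             delta_ofv = Inf, decision = "failed")
    } else {
      records[[i]] <- tibble(step = "univariate", covariate = rel$covariate,
                             parameter = rel$parameter, form = rel$form,
                             delta_ofv = fit$ofv - base_fit$ofv,
                             decision = "screened")
    }
  }
  dplyr::bind_rows(records)
}

#' Stepwise forward-addition / backward-elimination covariate selection
#'
#' Forward phase: repeatedly adds the candidate with the largest OFV
#' reduction, while that reduction exceeds `forward_gate`. Backward phase:
#' repeatedly removes the included relation whose removal raises the OFV the
#' least, while that rise is below `backward_gate`; a removed relation is
#' never re-tested. Ties are broken lexicographically by (parameter,
#' covariate).
#'
#' @inheritParams screen_covariates
#' @param forward_gate Minimum OFV drop for inclusion (3.84: chi-square,
#'   p < 0.05, df = 1).
#' @param backward_gate Minimum OFV rise for retention (7.88: p < 0.005,
#'   df = 1).
#' @param max_steps Oscillation guard.
#' @param final_refit Cold-start verification refit of the selected model?
#' @return A `pk_selection` list: `spec` (final model), `trail` (every test,
#'   mirroring a covariate-screening table), `final_fit`, `base_ofv`.
#' @export
stepwise_covariates <- function(data, base_spec,
                                candidates = default_candidates(data),
                                forward_gate = 3.84, backward_gate = 7.88,
                                base_fit = NULL, control = list(),
                                max_steps = 50, final_refit = TRUE) {
  if (nrow(candidates) == 0) abort("`candidates` must be nonempty.")
  if (is.null(base_fit)) {
    base_fit <- pk_fit(data, base_spec, se = FALSE, control = control)
  }
  candidates <- dplyr::arrange(candidates, .data$parameter, .data$covariate)
  trail <- list()
  spec <- base_spec
  cur_fit <- base_fit
  remaining <- candidates
  n_base_rel <- nrow(base_spec$relations)
  step_no <- 0

  # forward additions
  while (nrow(remaining) > 0 && step_no < max_steps) {
    step_no <- step_no + 1
    drops <- rep(NA_real_, nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      cs <- add_relation_to_spec(spec, remaining[i, ])
      f <- try(pk_fit(data, cs, init = extend_init(cur_fit$params, cs),
                      se = FALSE, control = control), silent = TRUE)
      if (!inherits(f, "try-error") && is.finite(f$ofv)) {
        drops[i] <- cur_fit$ofv - f$ofv
        fits[[i]] <- f
      } else {
        drops[i] <- -Inf
      }
      trail[[length(trail) + 1]] <- tibble(
        phase = "forward", step = step_no,
        covariate = remaining$covariate[i], parameter = remaining$parameter[i],
        delta_ofv = -drops[i], decision = "tested")
    }
    best <- which.max(drops)  # ties resolved by candidate ordering
    if (length(best) == 0 || drops[best] <= forward_gate) break
    spec <- add_relation_to_spec(spec, remaining[best, ])
    cur_fit <- fits[[best]]
    trail[[length(trail) + 1]] <- tibble(
      phase = "forward", step = step_no,
      covariate = remaining$covariate[best], parameter = remaining$parameter[best],
      delta_ofv = -drops[best], decision = "added")
    remaining <- remaining[-best, ]
  }

  # backward eliminations, restricted to forward-added relations
  repeat {
    step_no <- step_no + 1
    if (step_no >= max_steps) break
    removable <- seq_len(nrow(spec$relations))
    removable <- removable[removable > n_base_rel]
    if (length(removable) == 0) break
    rises <- rep(NA_real_, length(removable))
    fits <- vector("list", length(removable))
    for (k in seq_along(removable)) {
      cs <- drop_relation_from_spec(spec, removable[k])
      f <- try(pk_fit(data, cs, init = shrink_init(cur_fit$params, cs),
                      se = FALSE, control = control), silent = TRUE)
      rises[k] <- if (!inherits(f, "try-error") && is.finite(f$ofv))
        f$ofv - cur_fit$ofv else Inf
      fits[[k]] <- f
      trail[[length(trail) + 1]] <- tibble(
        phase = "backward", step = step_no,
        covariate = spec$relations$covariate[removable[k]],
        parameter = spec$relations$parameter[removable[k]],
        delta_ofv = rises[k], decision = "tested")
    }
    worst <- which.min(rises)
    if (rises[worst] >= backward_gate) {
      for (k in seq_along(removable)) {
        trail[[length(trail) + 1]] <- tibble(
          phase = "backward", step = step_no,
          covariate = spec$relations$covariate[removable[k]],
          parameter = spec$relations$parameter[removable[k]],
          delta_ofv = rises[k], decision = "retained")
      }
      break
    }
    trail[[length(trail) + 1]] <- tibble(
      phase = "backward", step = step_no,
      covariate = spec$relations$covariate[removable[worst]],
      parameter = spec$relations$parameter[removable[worst]],
      delta_ofv = rises[worst], decision = "removed")
    spec <- drop_relation_from_spec(spec, removable[worst])
    cur_fit <- fits[[worst]]
  }

  final_fit <- if (final_refit) {
    pk_fit(data, spec, se = FALSE, control = control)
  } else cur_fit
  if (final_fit$ofv > cur_fit$ofv + 1e-6) final_fit <- cur_fit

  structure(list(spec = spec, trail = dplyr::bind_rows(trail),
                 final_fit = final_fit, base_ofv = base_fit$ofv),
            class = "pk_selection")
}

#' @export
print.pk_selection <- function(x, ...) {
  cat("<pk_selection>\n")
  print(x$spec)
  cat("  final OFV:", format(x$final_fit$ofv, digits = 8),
      "(base", format(x$base_ofv, digits = 8), ")\n")
  invisible(x)
}
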