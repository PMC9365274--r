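# Calibration of the model's free parameters against EMSA-style occupancy
# tables (binding rates) and layer expression profiles (the WUS
# concentration scale).
#
# A structural fact shapes this module: stationary occupancy fractions
# depend on the rates only through the dissociation constants (Kd enters
# the stationary law; kon cancels), so an equilibrium table constrains Kd
# ratios but leaves the absolute kon unidentified (a "flat direction").
# Fits on equilibrium data therefore carry an explicit non-identifiability
# warning; supplying pre-equilibrium (kinetic) columns pins kon down.

#' Noise-free bound-fraction predictions
#'
#' For each functional element and dose, the exact stationary
#' probabilities of the unbound / monomer / dimer states from the CME
#' oracle of the full configured CRM (cooperativity included).  With
#' `kon_dimer = 0` the prediction is monomer-only, the model of a WUS
#' protein lacking its homodimerisation domain.
#'
#' @param config A [crm_config()] (binding subsystem only; `k_pol` is
#'   ignored).
#' @param doses WUS concentrations.
#' @return An `occupancy_table` tibble (`element`, `dose`,
#'   `fraction_unbound`, `fraction_monomer`, `fraction_dimer`,
#'   `n_trials = Inf`).
#' @export
predict_bound_fractions <- function(config, doses) {
  rows <- purrr::map(doses, function(d) {
    occ <- stationary_occupancy(config, d)
    occ <- occ[config$elements$functional[match(occ$element,
                                                config$elements$name)], ]
    tibble::tibble(element = occ$element, dose = d,
                   fraction_unbound = occ$p_empty,
                   fraction_monomer = occ$p_monomer,
                   fraction_dimer = occ$p_dimer,
                   n_trials = Inf)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("occupancy_table", class(out)), config = config)
}

#' Fit binding rates to an occupancy table
#'
#' Weighted least squares of predicted versus observed bound fractions
#' over `(kon_monomer, kon_dimer)` — or, equivalently on equilibrium
#' data, over the Kd scale — with weights `n_trials` (binomial-variance
#' motivated) and a deterministic 3-start bounded optimisation.
#'
#' Equilibrium fractions constrain only dissociation constants, so the
#' fit parameterises the two identifiable scale combinations
#' `s_m = kd_monomer_scale` and `s_d = kd_dimer_scale` (multipliers on
#' the template's Kd values, equivalent to `1/kon` rescalings) and flags
#' the absolute-rate flat direction with a warning unless the table has
#' kinetic information (a `time` column with pre-equilibrium rows).
#'
#' @param table An `occupancy_table` (e.g. from [synth_emsa_table()]):
#'   columns `element`, `dose`, `fraction_unbound`, `fraction_monomer`,
#'   `fraction_dimer`, `n_trials`.
#' @param template A [crm_config()] supplying the structure and starting
#'   parameter values.
#' @return A `crm_binding_fit` list: `kd_monomer_scale`,
#'   `kd_dimer_scale`, `kon_monomer`, `kon_dimer` (template kon, flagged
#'   non-identifiable on equilibrium data), `residual`, `identifiable`,
#'   `warnings`, `fitted_config`, `n_obs`.  Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
fit_binding_rates <- function(table, template) {
  stopifnot(inherits(template, "crm_config"))
  needed <- c("element", "dose", "fraction_unbound", "fraction_monomer",
              "fraction_dimer", "n_trials")
  if (!all(needed %in% names(table))) {
    stop("`table` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  warnings <- character(0)
  doses <- sort(unique(table$dose[table$dose > 0]))
  kds <- template$elements$kd_monomer[template$elements$functional]
  if (length(doses) < 3 || min(doses) >= min(kds) || max(doses) <= max(kds)) {
    warnings <- c(warnings, paste(
      "dose design is degenerate: need >= 3 positive doses spanning sub-",
      "and super-Kd concentrations; estimates may be unstable"))
  }
  has_kinetics <- "time" %in% names(table)
  if (!has_kinetics) {
    warnings <- c(warnings, paste(
      "equilibrium fractions constrain only Kd (kon cancels in the",
      "stationary law): absolute binding rates are not identifiable;",
      "reporting Kd scale factors and the template kon values"))
  }
  w <- ifelse(is.finite(table$n_trials), table$n_trials, 1)
  objective <- function(par) {
    s_m <- exp(par[1])
    s_d <- exp(par[2])
    cfg <- template
    cfg$elements$kd_monomer <- template$elements$kd_monomer * s_m
    cfg$elements$kd_dimer <- template$elements$kd_dimer * s_d
    pred <- predict_bound_fractions(cfg, unique(table$dose))
    joined <- dplyr::inner_join(
      table, pred,
      by = c("element", "dose"), suffix = c("", "_pred"))
    if (nrow(joined) == 0) return(1e10)
    wj <- ifelse(is.finite(joined$n_trials), joined$n_trials, 1)
    sum(wj * ((joined$fraction_unbound - joined$fraction_unbound_pred)^2 +
                (joined$fraction_monomer - joined$fraction_monomer_pred)^2 +
                (joined$fraction_dimer - joined$fraction_dimer_pred)^2)) /
      sum(wj)
  }
  dimer_free <- template$kinetics$kon_dimer > 0 &&
    any(table$fraction_dimer > 0)
  starts <- list(c(0, 0), c(log(0.3), log(0.3)), c(log(3), log(3)))
  best <- NULL
  for (st in starts) {
    fit <- stats::optim(st, objective, method = "L-BFGS-B",
                        lower = log(1e-3), upper = log(1e3))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  s_m <- exp(best$par[1])
  s_d <- if (dimer_free) exp(best$par[2]) else NA_real_
  fitted_config <- template
  fitted_config$elements$kd_monomer <- template$elements$kd_monomer * s_m
  if (dimer_free) {
    fitted_config$elements$kd_dimer <- template$elements$kd_dimer * s_d
  }
  for (msg in warnings) warning(msg, call. = FALSE)
  structure(
    list(kd_monomer_scale = s_m, kd_dimer_scale = s_d,
         kon_monomer = template$kinetics$kon_monomer,
         kon_dimer = template$kinetics$kon_dimer,
         residual = best$value, identifiable = has_kinetics,
         warnings = warnings, fitted_config = fitted_config,
         n_obs = nrow(table)),
    class = "crm_binding_fit"
  )
}

#' @export
print.crm_binding_fit <- function(x, ...) {
  cat("<crm_binding_fit>\n")
  cat(sprintf("  kd_monomer_scale = %.4g, kd_dimer_scale = %.4g\n",
              x$kd_monomer_scale, x$kd_dimer_scale))
  cat(sprintf("  residual = %.3g over %d observations\n", x$residual, x$n_obs))
  if (!x$identifiable) {
    cat("  note: absolute kon not identifiable from equilibrium fractions\n")
  }
  invisible(x)
}

#' Fit the WUS concentration scale to a layer expression profile
#'
#' One-dimensional weighted least squares over a scale factor `s`: the
#' model's mean mRNA evaluated at `dose * s` for each layer's dose is
#' aligned to the observed per-layer expression (up to a free amplitude,
#' profiled out analytically since fluorescence units are arbitrary).
#'
#' @param dose_response A [dose_response()] result covering the dose
#'   range of interest (its mean-mRNA curve is interpolated linearly).
#' @param layer_profile Tibble with columns `dose` (the layer's nominal
#'   WUS value in profile units) and `mean_expression` (>= 2 rows), e.g.
#'   from [synth_layer_profile()].
#' @param scale_grid Candidate scale factors for the global grid stage
#'   (refined locally afterwards).
#' @return A `crm_scale_fit` list: `scale`, `amplitude`, `residual`,
#'   `warnings`.  `scale` maps profile dose units into model WUS units
#'   (`model_dose = profile_dose * scale`).
#' @export
fit_concentration_scale <- function(dose_response, layer_profile,
                                    scale_grid = exp(seq(log(0.05), log(20),
                                                         length.out = 120))) {
  if (nrow(layer_profile) < 2) {
    stop("`layer_profile` must have at least 2 layers", call. = FALSE)
  }
  summ <- summary(dose_response)
  warnings <- character(0)
  if (stats::sd(summ$mean_mrna) < 1e-12) {
    warnings <- c(warnings,
                  "dose-response curve is flat: scale is not identifiable")
  }
  curve_fun <- stats::approxfun(summ$dose, summ$mean_mrna, rule = 2)
  obs <- layer_profile$mean_expression
  objective <- function(s) {
    pred <- curve_fun(layer_profile$dose * s)
    denom <- sum(pred^2)
    amp <- if (denom > 0) sum(obs * pred) / denom else 0
    sum((obs - amp * pred)^2)
  }
  vals <- vapply(scale_grid, objective, numeric(1))
  s0 <- scale_grid[which.min(vals)]
  opt <- stats::optimize(objective, interval = c(s0 / 2, s0 * 2))
  s_hat <- opt$minimum
  pred <- curve_fun(layer_profile$dose * s_hat)
  denom <- sum(pred^2)
  amp <- if (denom > 0) sum(obs * pred) / denom else 0
  for (msg in warnings) warning(msg, call. = FALSE)
  structure(
    list(scale = s_hat, amplitude = amp, residual = opt$objective,
         warnings = warnings),
    class = "crm_scale_fit"
  )
}

#' @export
print.crm_scale_fit <- function(x, ...) {
  cat(sprintf("<crm_scale_fit> scale = %.4g (amplitude %.4g, residual %.3g)\n",
              x$scale, x$amplitude, x$residual))
  invisible(x)
}
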