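# broom-style tidiers for the package's result and fit objects.

#' Tidy a dose-response result
#'
#' @param x A [dose_response()] result.
#' @param ... Unused.
#' @return The per-dose summary tibble (`dose`, `replicates`,
#'   `mean_mrna`, `sd_mrna`, `se_mrna`).
#' @export
tidy.crm_dose_response <- function(x, ...) {
  attr(x, "summary")
}

#' @rdname tidy.crm_dose_response
#' @export
glance.crm_dose_response <- function(x, ...) {
  summ <- attr(x, "summary")
  peak <- summ$dose[which.max(summ$mean_mrna)]
  tibble::tibble(
    label = attr(x, "config")$label,
    n_doses = nrow(summ),
    replicates = max(x$replicate),
    t_end = attr(x, "t_end"),
    peak_dose = peak,
    peak_mrna = max(summ$mean_mrna)
  )
}

#' Tidy a tissue-simulation result
#'
#' @param x A [simulate_tissue()] result.
#' @param ... Unused.
#' @return The per-layer summary tibble.
#' @export
tidy.crm_tissue_result <- function(x, ...) {
  layer_summary(x)
}

#' @rdname tidy.crm_tissue_result
#' @export
glance.crm_tissue_result <- function(x, ...) {
  summ <- layer_summary(x)
  tibble::tibble(
    label = attr(x, "config")$label,
    n_cells = nrow(x),
    n_layers = nrow(summ),
    t_end = attr(x, "t_end"),
    peak_layer = summ$layer[which.max(summ$mean_mrna)],
    total_mrna = sum(x$mrna)
  )
}

#' Tidy a binding-rate fit
#'
#' @param x A [fit_binding_rates()] result.
#' @param ... Unused.
#' @return One row per fitted quantity: `term`, `estimate`,
#'   `identifiable`.
#' @export
tidy.crm_binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd_monomer_scale", "kd_dimer_scale", "kon_monomer",
             "kon_dimer"),
    estimate = c(x$kd_monomer_scale, x$kd_dimer_scale, x$kon_monomer,
                 x$kon_dimer),
    identifiable = c(TRUE, !is.na(x$kd_dimer_scale), x$identifiable,
                     x$identifiable)
  )
}

#' @rdname tidy.crm_binding_fit
#' @export
glance.crm_binding_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, n_obs = x$n_obs,
                 identifiable = x$identifiable,
                 n_warnings = length(x$warnings))
}

#' Tidy a concentration-scale fit
#'
#' @param x A [fit_concentration_scale()] result.
#' @param ... Unused.
#' @return One row per fitted quantity.
#' @export
tidy.crm_scale_fit <- function(x, ...) {
  tibble::tibble(term = c("scale", "amplitude"),
                 estimate = c(x$scale, x$amplitude))
}

#' @rdname tidy.crm_scale_fit
#' @export
glance.crm_scale_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, n_warnings = length(x$warnings))
}
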