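# Synthetic-data generators: every input the pipeline needs, with known
# ground truth, so calibration and tissue analyses are testable without
# any external data.  All generators are pure functions of
# (parameters, seed) and carry their generating parameters as attributes.

#' Layered WUS gradient factory
#'
#' A geometric concentration ladder from the outermost layer inward:
#' `w_k = base * fold^(k-1)`, optionally plateauing from `plateau_layer`
#' on (deep-layer fold changes are not experimentally constrained).  The
#' default parameters place L1 on the rising limb of the wild-type
#' dose-response and the deep layers beyond its peak.
#'
#' @param base WUS concentration of L1 (>= 0).  Default 0.25.
#' @param fold Per-layer fold change (> 0).  Default 2 (dimerisation is
#'   promoted over a small two- to four-fold concentration increase, so
#'   neighbouring layers must sit within that scale of one another).
#' @param n_layers Number of layers (default 7).
#' @param plateau_layer Layer index from which the concentration stays
#'   constant (`NULL` for no plateau; default 5).
#' @return Numeric vector of length `n_layers` (class `wus_gradient`),
#'   L1 first, with the generating parameters attached.
#' @examples
#' synth_gradient(1, 2, n_layers = 3)  # 1 2 4
#' @export
synth_gradient <- function(base = 0.25, fold = 2, n_layers = 7,
                           plateau_layer = 5) {
  if (base < 0) stop("`base` must be >= 0", call. = FALSE)
  if (fold <= 0) stop("`fold` must be > 0", call. = FALSE)
  w <- base * fold^(seq_len(n_layers) - 1)
  if (!is.null(plateau_layer) && plateau_layer < n_layers) {
    w[plateau_layer:n_layers] <- w[plateau_layer]
  }
  structure(w, class = "wus_gradient",
            params = list(base = base, fold = fold, n_layers = n_layers,
                          plateau_layer = plateau_layer))
}

#' Synthetic EMSA-style occupancy table
#'
#' Emulates bound-fraction-versus-concentration measurements: for each
#' (element, dose), `n_trials` probe molecules are drawn from the exact
#' stationary occupancy law (multinomial over unbound / monomer-bound /
#' dimer-bound) of that element within the configured CRM.
#'
#' @param true_config The generating [crm_config()] (ground truth).
#' @param doses WUS concentrations assayed.
#' @param n_trials Probes per (element, dose) (>= 1).
#' @param seed Integer seed.
#' @return An `occupancy_table`: tibble with columns `element`, `dose`,
#'   `fraction_unbound`, `fraction_monomer`, `fraction_dimer`,
#'   `n_trials`; the generating config and seed are attached as
#'   attributes.
#' @examples
#' synth_emsa_table(build_variant("970i"), doses = c(0.5, 1, 2),
#'                  n_trials = 100, seed = 1)
#' @export
synth_emsa_table <- function(true_config, doses, n_trials, seed) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  probs <- predict_bound_fractions(true_config, doses)
  rows <- purrr::pmap(probs, function(element, dose, fraction_unbound,
                                      fraction_monomer, fraction_dimer,
                                      n_trials_ignored = NULL, ...) {
    counts <- withr::with_seed(
      derive_seed(seed, "emsa", element, format(dose)),
      stats::rmultinom(1, n_trials, c(fraction_unbound, fraction_monomer,
                                      fraction_dimer))
    )
    tibble::tibble(element = element, dose = dose,
                   fraction_unbound = counts[1] / n_trials,
                   fraction_monomer = counts[2] / n_trials,
                   fraction_dimer = counts[3] / n_trials,
                   n_trials = n_trials)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("occupancy_table", class(out)),
            true_config = true_config, seed = seed)
}

#' Synthetic per-layer fluorescence-like expression profile
#'
#' Stands in for reporter-fluorescence quantifications: simulates the
#' variant in the 3D tissue under the gradient, then perturbs each
#' pseudo-transformant's layer means with multiplicative log-normal noise
#' of coefficient of variation `noise_cv`, and reports mean +/- SE per
#' layer across transformants.
#'
#' @param variant Variant name (see [list_named_variants()]) or a
#'   [crm_config()].
#' @param gradient Per-layer WUS gradient (default [synth_gradient()]).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed Integer seed.
#' @param n_transformants Pseudo-transformants (default 4, the usual
#'   independent-transformant count in reporter assays).
#' @param tissue,t_end,burnin Tissue-simulation controls (a reduced dome
#'   by default).
#' @return Tibble: `layer`, `dose`, `mean_expression`, `se_expression`,
#'   `n_transformants`, with ground-truth metadata attached
#'   (`true_layer_means`, `params`).
#' @export
synth_layer_profile <- function(variant, gradient = synth_gradient(),
                                noise_cv = 0.1, seed = 1,
                                n_transformants = 4,
                                tissue = build_dome(7, cells_l1 = 36),
                                t_end = 2000, burnin = 0.2) {
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  config <- if (inherits(variant, "crm_config")) variant else {
    build_variant(variant)
  }
  res <- simulate_tissue(assign_gradient(tissue, gradient), config,
                         t_end = t_end, seed = derive_seed(seed, "profile"),
                         burnin = burnin)
  truth <- layer_summary(res)
  # log-normal with unit mean and CV = noise_cv
  sdlog <- sqrt(log(1 + noise_cv^2))
  draws <- purrr::map(seq_len(n_transformants), function(r) {
    noise <- if (noise_cv == 0) rep(1, nrow(truth)) else {
      withr::with_seed(derive_seed(seed, "transformant", r),
                       stats::rlnorm(nrow(truth), -sdlog^2 / 2, sdlog))
    }
    truth$mean_mrna * noise
  })
  m <- do.call(cbind, draws)
  out <- tibble::tibble(
    layer = truth$layer,
    dose = truth$dose,
    mean_expression = rowMeans(m),
    se_expression = if (n_transformants > 1) {
      apply(m, 1, stats::sd) / sqrt(n_transformants)
    } else 0,
    n_transformants = n_transformants
  )
  structure(out, class = c("layer_profile", class(out)),
            true_layer_means = truth$mean_mrna,
            params = list(variant = config$label, noise_cv = noise_cv,
                          seed = seed, n_transformants = n_transformants,
                          gradient = as.numeric(gradient)))
}
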