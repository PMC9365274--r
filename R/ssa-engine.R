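#' @useDynLib crmswitch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic sub-seed derivation: a counter-based hash of the master
# seed and arbitrary labels, so replicate/dose/cell streams are
# order-independent.  Always in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  abs(digest::digest2int(key)) %% 2147483646L + 1L
}

event_names <- c("monomer_bind", "monomer_unbind", "dimer_bind",
                 "dimer_unbind", "pol_recruit", "deactivate")

ssa_run <- function(config, dose, t_end, seed, burnin = 0,
                    record_events = TRUE, max_events = 5e6) {
  stopifnot(inherits(config, "crm_config"))
  if (dose < 0) stop("`dose` must be >= 0", call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be > 0", call. = FALSE)
  el <- config$elements
  res <- withr::with_seed(
    as.integer(seed),
    .ssa_run_cpp(el$position, el$kd_monomer, el$kd_dimer,
                 as.integer(el$functional),
                 unclass(config$kinetics), unclass(config$cooperativity),
                 reference_distance(config),
                 dose, t_end, burnin, record_events, as.integer(max_events))
  )
  res
}

#' Simulate one cell with the exact stochastic algorithm
#'
#' Runs the Gillespie direct method over all binding, unbinding and Pol II
#' recruitment channels of the CRM, interleaving the two deterministic
#' clocks (monomer deactivation at the residence-time limit; refractory
#' expiry `pol_gap` after each initiation) by advancing to whichever event
#' comes first and redrawing the exponential waiting time.  Identical
#' `(config, dose, t_end, seed)` give identical trajectories.
#'
#' @param config A [crm_config()].
#' @param dose WUS concentration, arbitrary units (constant over the run).
#' @param t_end Simulated seconds (> 0).
#' @param seed Integer seed.
#' @param record_events Keep the full event log (set `FALSE` for large
#'   sweeps; summaries are unaffected).
#' @return A `crm_trajectory`: a tibble of events (`time`, `event`,
#'   `element`) with attributes `final_state` (a [cell_state()]),
#'   `accumulators` (per-element time in empty/monomer/dimer/active
#'   states), `initiation_times`, `mrna`, `config`, `dose`, `t_end`,
#'   `seed`.
#' @examples
#' cfg <- build_variant("970i")
#' traj <- simulate_cell(cfg, dose = 1, t_end = 500, seed = 1)
#' occupancy_fractions(traj)
#' @export
simulate_cell <- function(config, dose, t_end, seed, record_events = TRUE) {
  res <- ssa_run(config, dose, t_end, seed, burnin = 0,
                 record_events = record_events)
  el <- config$elements
  events <- tibble::tibble(
    time = res$event_time,
    event = event_names[res$event_code],
    element = ifelse(res$event_element >= 1,
                     el$name[pmax(res$event_element, 1L)], NA_character_)
  )
  final_state <- cell_state(
    config, occupancy = res$occupancy, bind_time = res$bind_time,
    active = res$active, pol_ready_at = res$pol_ready_at,
    t = res$t, mrna = res$mrna
  )
  accum <- tibble::tibble(
    element = el$name,
    time_empty = res$time_empty,
    time_monomer = res$time_monomer,
    time_dimer = res$time_dimer,
    time_active = res$time_active
  )
  structure(events,
            class = c("crm_trajectory", class(events)),
            final_state = final_state,
            accumulators = accum,
            initiation_times = res$initiation_times,
            mrna = res$mrna,
            window = res$window,
            config = config, dose = dose, t_end = t_end, seed = seed)
}

#' @export
print.crm_trajectory <- function(x, ...) {
  cat(sprintf("<crm_trajectory> %s, dose %g, %g s, %d events, %d initiations\n",
              attr(x, "config")$label, attr(x, "dose"), attr(x, "t_end"),
              nrow(x), length(attr(x, "initiation_times"))))
  NextMethod()
}

#' Time-averaged occupancy fractions of a trajectory
#'
#' @param traj A [simulate_cell()] trajectory.
#' @return Tibble with one row per element: `frac_empty`, `frac_monomer`,
#'   `frac_dimer` (summing to 1) and `frac_active` (active-monomer time,
#'   `<= frac_monomer`).
#' @export
occupancy_fractions <- function(traj) {
  acc <- attr(traj, "accumulators")
  w <- attr(traj, "window")
  tibble::tibble(
    element = acc$element,
    frac_empty = acc$time_empty / w,
    frac_monomer = acc$time_monomer / w,
    frac_dimer = acc$time_dimer / w,
    frac_active = acc$time_active / w
  )
}

#' Intervals between successive transcription initiations
#'
#' Every interval is at least `pol_gap` — the refractory floor is a hard
#' guarantee of the engine, not a statistical tendency.
#'
#' @param traj A [simulate_cell()] trajectory.
#' @return Numeric vector of inter-initiation intervals (empty when fewer
#'   than two initiations occurred).
#' @export
initiation_gaps <- function(traj) {
  it <- attr(traj, "initiation_times")
  if (length(it) < 2) return(numeric(0))
  diff(it)
}

#' mRNA output across WUS concentrations
#'
#' For each dose, runs `replicates` independent cells (sub-seeds derived
#' deterministically from `seed`, so results do not depend on execution
#' order) and summarises the mRNA synthesised after a burn-in fraction of
#' the run is discarded.
#'
#' @param config A [crm_config()].
#' @param doses Numeric vector of WUS concentrations (non-empty).
#' @param t_end Simulated seconds per cell.
#' @param replicates Cells per dose (>= 1).
#' @param seed Integer master seed.
#' @param burnin Fraction of `t_end` discarded before counting (default
#'   0.2, enough to reach stationarity at the default rates).
#' @return A `crm_dose_response`: tibble with one row per
#'   `(dose, replicate)` (`mrna`, per-element mean occupancy fractions)
#'   plus a `summary` attribute (per-dose `mean_mrna`, `sd_mrna`,
#'   `se_mrna`).  With `replicates = 1` the SD is reported as 0 and a
#'   warning is recorded in the `warnings` attribute.
#' @examples
#' dr <- dose_response(build_variant("970i"), doses = c(0, 1, 2),
#'                     t_end = 200, replicates = 3, seed = 1)
#' summary(dr)
#' @export
dose_response <- function(config, doses, t_end = 2000, replicates = 20,
                          seed = 1, burnin = 0.2) {
  if (length(doses) == 0) stop("`doses` must be non-empty", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  warnings <- character(0)
  if (replicates == 1) {
    warnings <- c(warnings,
                  "replicates = 1: SD reported as 0 is not an error estimate")
  }
  el <- config$elements
  grid <- tidyr::expand_grid(dose_index = seq_along(doses),
                             replicate = seq_len(replicates))
  rows <- purrr::pmap(grid, function(dose_index, replicate) {
    d <- doses[dose_index]
    # sub-seed keyed by dose VALUE so dose ordering cannot matter
    res <- ssa_run(config, d, t_end,
                   seed = derive_seed(seed, "dose", format(d, digits = 15),
                                      "rep", replicate),
                   burnin = burnin, record_events = FALSE)
    fr_m <- stats::setNames(res$time_monomer / res$window,
                            paste0("frac_monomer_", el$name))
    fr_d <- stats::setNames(res$time_dimer / res$window,
                            paste0("frac_dimer_", el$name))
    min_gap <- if (length(res$initiation_times) >= 2) {
      min(diff(res$initiation_times))
    } else NA_real_
    tibble::tibble(dose = d, replicate = replicate,
                   mrna = res$mrna_post_burnin, min_initiation_gap = min_gap,
                   !!!fr_m, !!!fr_d)
  })
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mean_mrna = mean(.data$mrna),
      sd_mrna = if (dplyr::n() > 1) stats::sd(.data$mrna) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(se_mrna = .data$sd_mrna / sqrt(.data$replicates))
  structure(out,
            class = c("crm_dose_response", class(out)),
            summary = summ, warnings = warnings,
            config = config, t_end = t_end, burnin = burnin, seed = seed)
}

#' @export
summary.crm_dose_response <- function(object, ...) {
  attr(object, "summary")
}

#' @export
print.crm_dose_response <- function(x, ...) {
  cat(sprintf("<crm_dose_response> %s: %d doses x %d replicates, t_end %g s\n",
              attr(x, "config")$label, nrow(attr(x, "summary")),
              max(x$replicate), attr(x, "t_end")))
  for (w in attr(x, "warnings")) cat("  note: ", w, "\n", sep = "")
  print(attr(x, "summary"))
  invisible(x)
}
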