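# 3D half-dome multicellular model: the single-cell stochastic model runs
# independently in every cell of a hemispherical shell lattice, dosed by a
# layered WUS gradient (constant in time; CLV3 -> WUS feedback is out of
# scope).  Layers are numbered L1 (outermost shell) to L7 (innermost).

# Near-uniform points on the upper hemisphere of radius r via a Fibonacci
# lattice; deterministic.
fibonacci_hemisphere <- function(n_points, r) {
  if (n_points <= 1) {
    return(tibble::tibble(x = 0, y = 0, z = r))
  }
  golden <- (1 + sqrt(5)) / 2
  i <- seq_len(n_points) - 0.5
  z_unit <- i / n_points          # in (0, 1): upper hemisphere only
  theta <- 2 * pi * i / golden
  rho <- sqrt(pmax(0, 1 - z_unit^2))
  tibble::tibble(x = r * rho * cos(theta), y = r * rho * sin(theta),
                 z = r * z_unit)
}

#' Build the half-dome tissue geometry
#'
#' Cells are unit spheres whose centres lie on concentric hemispherical
#' shells: layer L1 is the outermost shell (radius `n_layers * spacing`)
#' and deeper layers have smaller radii, so outer shells hold more cells
#' (cell counts are proportional to shell area via a Fibonacci lattice).
#' The construction is deterministic; `seed` is accepted for interface
#' uniformity and recorded.
#'
#' @param n_layers Number of layers (default 7, L1..L7).
#' @param spacing Centre-to-centre distance between shells and the target
#'   in-shell packing distance (cell diameter), default 1.
#' @param seed Integer; recorded in the result.
#' @param cells_l1 Cell count of the outermost shell (default 196);
#'   deeper shells scale with shell area, with a minimum of 1 cell.
#' @return A `crm_tissue`: tibble with columns `cell_id`, `layer`
#'   (`"L1"` ...), `x`, `y`, `z`.
#' @examples
#' dome <- build_dome(n_layers = 3, cells_l1 = 30)
#' dplyr::count(dome, layer)
#' @export
build_dome <- function(n_layers = 7, spacing = 1, seed = 1, cells_l1 = 196) {
  if (n_layers < 1) stop("`n_layers` must be >= 1", call. = FALSE)
  radii <- spacing * (n_layers:1)
  counts <- pmax(1L, round(cells_l1 * (radii / radii[1])^2))
  shells <- purrr::map2(seq_len(n_layers), counts, function(l, n_pts) {
    pts <- fibonacci_hemisphere(n_pts, radii[l])
    dplyr::mutate(pts, layer = paste0("L", l), .before = 1)
  })
  out <- dplyr::bind_rows(shells)
  out <- dplyr::mutate(out, cell_id = seq_len(nrow(out)), .before = 1)
  structure(out, class = c("crm_tissue", class(out)),
            n_layers = n_layers, spacing = spacing, seed = seed)
}

#' Dose every cell with its layer's WUS concentration
#'
#' @param geometry A [build_dome()] tissue.
#' @param gradient Numeric vector of per-layer WUS concentrations, length
#'   equal to the number of layers, L1 first (all >= 0); or a
#'   [synth_gradient()] result.
#' @return The tissue with a `dose` column added.
#' @export
assign_gradient <- function(geometry, gradient) {
  n_layers <- attr(geometry, "n_layers")
  gradient <- as.numeric(gradient)
  if (length(gradient) != n_layers) {
    stop("gradient has ", length(gradient), " values but the tissue has ",
         n_layers, " layers", call. = FALSE)
  }
  if (any(gradient < 0)) stop("WUS concentrations must be >= 0", call. = FALSE)
  layer_index <- as.integer(sub("^L", "", geometry$layer))
  out <- dplyr::mutate(geometry, dose = gradient[layer_index])
  structure(out, class = class(geometry), n_layers = n_layers,
            spacing = attr(geometry, "spacing"), seed = attr(geometry, "seed"))
}

#' Simulate every cell of a dosed tissue
#'
#' Runs the single-cell stochastic model independently in each cell at its
#' local WUS dose.  Sub-seeds are derived deterministically from
#' `(seed, cell_id)`, so results are independent of the order in which
#' cells are simulated.
#'
#' @param tissue A dosed tissue from [assign_gradient()].
#' @param config A [crm_config()].
#' @param t_end Simulated seconds per cell.
#' @param seed Integer master seed.
#' @param burnin Burn-in fraction discarded before accumulating.
#' @return A `crm_tissue_result`: per-cell tibble (`cell_id`, `layer`,
#'   `x`, `y`, `z`, `dose`, `mrna`, `frac_monomer`, `frac_dimer`,
#'   `frac_active`, `min_initiation_gap`) with a `layer_summary` attribute
#'   (per-layer mean/SD of mRNA and mean occupancy fractions).
#' @examples
#' tis <- assign_gradient(build_dome(2, cells_l1 = 12),
#'                        synth_gradient(0.5, 2, n_layers = 2))
#' res <- simulate_tissue(tis, build_variant("WT"), t_end = 200, seed = 1)
#' layer_summary(res)
#' @export
simulate_tissue <- function(tissue, config, t_end = 2000, seed = 1,
                            burnin = 0.2) {
  if (!"dose" %in% names(tissue)) {
    stop("tissue has no `dose` column; call assign_gradient() first",
         call. = FALSE)
  }
  rows <- purrr::pmap(
    list(tissue$cell_id, tissue$dose),
    function(cell_id, dose) {
      res <- ssa_run(config, dose, t_end,
                     seed = derive_seed(seed, "cell", cell_id),
                     burnin = burnin, record_events = FALSE)
      fun <- config$elements$functional
      min_gap <- if (length(res$initiation_times) >= 2) {
        min(diff(res$initiation_times))
      } else NA_real_
      tibble::tibble(
        cell_id = cell_id,
        mrna = res$mrna_post_burnin,
        # occupancy averaged over functional elements (non-functional
        # elements are structurally empty and would dilute the signal)
        frac_monomer = mean(res$time_monomer[fun] / res$window),
        frac_dimer = mean(res$time_dimer[fun] / res$window),
        frac_active = mean(res$time_active[fun] / res$window),
        min_initiation_gap = min_gap
      )
    })
  cells <- dplyr::left_join(tibble::as_tibble(tissue), dplyr::bind_rows(rows),
                            by = "cell_id")
  summ <- cells |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      dose = .data$dose[1],
      mean_mrna = mean(.data$mrna),
      sd_mrna = if (dplyr::n() > 1) stats::sd(.data$mrna) else 0,
      mean_monomer = mean(.data$frac_monomer),
      mean_dimer = mean(.data$frac_dimer),
      .groups = "drop"
    ) |>
    dplyr::arrange(as.integer(sub("^L", "", .data$layer)))
  structure(cells, class = c("crm_tissue_result", class(cells)),
            layer_summary = summ, config = config, t_end = t_end,
            seed = seed, burnin = burnin)
}

#' Per-layer summary of a tissue simulation
#'
#' @param result A [simulate_tissue()] result.
#' @return Tibble: `layer`, `n_cells`, `dose`, `mean_mrna`, `sd_mrna`,
#'   `mean_monomer`, `mean_dimer`.
#' @export
layer_summary <- function(result) {
  attr(result, "layer_summary")
}

#' @export
print.crm_tissue_result <- function(x, ...) {
  cat(sprintf("<crm_tissue_result> %s: %d cells, t_end %g s\n",
              attr(x, "config")$label, nrow(x), attr(x, "t_end")))
  print(attr(x, "layer_summary"))
  invisible(x)
}

#' Per-layer monomer and dimer occupancy maps
#'
#' @param result A [simulate_tissue()] result.
#' @return Long tibble: `layer`, `species` (`"monomer"`/`"dimer"`),
#'   `mean_occupancy`.
#' @export
occupancy_maps <- function(result) {
  layer_summary(result) |>
    dplyr::select("layer", "mean_monomer", "mean_dimer") |>
    tidyr::pivot_longer(c("mean_monomer", "mean_dimer"),
                        names_to = "species", names_prefix = "mean_",
                        values_to = "mean_occupancy")
}

#' Factorial sweep over monomer and dimer cooperativity strengths
#'
#' Re-runs the tissue simulation for every combination of cooperativity
#' factors, holding everything else fixed.  Factors of 1 mean no
#' cooperativity in that channel.
#'
#' @param config A [crm_config()] (its cooperativity mode should be
#'   `"distance"` or `"equal"`; the factors are overridden by the grid).
#' @param gradient Per-layer WUS gradient.
#' @param c_mono_list,c_dim_list Factor grids, each within (0, 1].
#' @param tissue A [build_dome()] geometry (default: a reduced dome).
#' @param t_end,seed,burnin Passed to [simulate_tissue()]; the same seed
#'   is used in every grid cell so differences reflect the factors alone.
#' @return Tibble with one row per (c_monomer, c_dimer, layer):
#'   per-layer summaries, plus a `results` attribute holding the full
#'   [simulate_tissue()] objects keyed `"c_mono/c_dim"`.
#' @export
cooperativity_sweep <- function(config, gradient, c_mono_list, c_dim_list,
                                tissue = build_dome(7, cells_l1 = 36),
                                t_end = 2000, seed = 1, burnin = 0.2) {
  stopifnot(all(c_mono_list > 0 & c_mono_list <= 1),
            all(c_dim_list > 0 & c_dim_list <= 1))
  dosed <- assign_gradient(tissue, gradient)
  grid <- tidyr::expand_grid(c_monomer = c_mono_list, c_dimer = c_dim_list)
  results <- list()
  rows <- purrr::pmap(grid, function(c_monomer, c_dimer) {
    cfg <- config
    cfg$cooperativity$c_monomer <- c_monomer
    cfg$cooperativity$c_dimer <- c_dimer
    res <- simulate_tissue(dosed, cfg, t_end = t_end, seed = seed,
                           burnin = burnin)
    key <- paste0(c_monomer, "/", c_dimer)
    results[[key]] <<- res
    dplyr::mutate(layer_summary(res), c_monomer = c_monomer,
                  c_dimer = c_dimer, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("crm_coop_sweep", class(out)),
            results = results, config = config, seed = seed)
}
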