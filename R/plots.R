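# ggplot2 figures for the main result types.

#' Plot a dose-response curve
#'
#' Mean mRNA versus WUS concentration with a +/- 1 SE ribbon.
#'
#' @param object A [dose_response()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crm_dose_response <- function(object, ...) {
  summ <- attr(object, "summary")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$dose, y = .data$mean_mrna)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_mrna - .data$se_mrna,
                   ymax = .data$mean_mrna + .data$se_mrna),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "WUS concentration (arbitrary units)",
                  y = "mean CLV3 mRNA per cell",
                  title = attr(object, "config")$label) +
    ggplot2::theme_minimal()
}

#' Plot per-layer expression of a tissue simulation
#'
#' Layer-mean mRNA with a +/- 1 SD ribbon, L1 (outermost) to the deepest
#' layer.
#'
#' @param object A [simulate_tissue()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crm_tissue_result <- function(object, ...) {
  summ <- layer_summary(object)
  summ$layer_index <- as.integer(sub("^L", "", summ$layer))
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$layer_index,
                                     y = .data$mean_mrna)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_mrna - .data$sd_mrna),
                   ymax = .data$mean_mrna + .data$sd_mrna),
      alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = summ$layer_index,
                                labels = summ$layer) +
    ggplot2::labs(x = "cell layer (L1 = outermost)",
                  y = "mean CLV3 mRNA per cell",
                  title = attr(object, "config")$label) +
    ggplot2::theme_minimal()
}

#' Plot per-layer monomer and dimer occupancy
#'
#' @param result A [simulate_tissue()] result.
#' @return A ggplot of [occupancy_maps()].
#' @export
plot_occupancy_maps <- function(result) {
  maps <- occupancy_maps(result)
  maps$layer_index <- as.integer(sub("^L", "", maps$layer))
  ggplot2::ggplot(maps, ggplot2::aes(x = .data$layer_index,
                                     y = .data$mean_occupancy,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(maps$layer_index),
                                labels = unique(maps$layer)) +
    ggplot2::labs(x = "cell layer (L1 = outermost)",
                  y = "mean occupancy fraction", colour = NULL,
                  title = attr(result, "config")$label) +
    ggplot2::theme_minimal()
}
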