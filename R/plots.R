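#' Bar chart of ensemble-intersection cardinalities
#'
#' One horizontal bar per exact phenotype combination (labels concatenate
#' the condition digits, so `"12"` is the intersection of exp1 and exp2).
#'
#' @param object A `cardinality_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardinality_analysis <- function(object, ...) {
  tbl <- object$combinations
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$count,
                                    y = stats::reorder(.data$combination,
                                                       .data$count))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of solutions", y = "ensemble combination",
                  title = paste0("Ensemble cardinalities (by ", object$by, ")")) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-ensemble median fluxes (or constants)
#'
#' @param summary A tibble from [summarize_ensembles()].
#' @param value Column to display (`"flux_median"` or `"k_median"`).
#' @param log10 Show values on a log10 colour scale (zeros are floored at
#'   a small pseudo-count).
#' @return A ggplot object.
#' @export
plot_median_heatmap <- function(summary, value = "flux_median", log10 = TRUE) {
  tbl <- summary[!summary$empty, , drop = FALSE]
  v <- tbl[[value]]
  if (log10) v <- base::log10(pmax(v, 1e-13))
  tbl$display <- v
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$group_id, y = .data$reaction_id,
                                    fill = .data$display)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (log10) paste0("log10 ", value)
                                  else value) +
    ggplot2::labs(x = "ensemble", y = "reaction") +
    ggplot2::theme_minimal()
}

#' Tile plot of pairwise KS p-values
#'
#' @param object A `ks_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ks_report <- function(object, ...) {
  pw <- object$pairwise %>%
    mutate(pair = paste(.data$cond_a, .data$cond_b, sep = ":"))
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$pair, y = .data$reaction_id,
                                   fill = -base::log10(pmax(.data$p_value,
                                                            1e-16)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = "condition pair", y = "reaction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Trajectory plot for a simulated run
#'
#' @param object A `kin_trajectory`.
#' @param species Optional species ids to show (default: internal,
#'   unclamped species).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_trajectory <- function(object, species = NULL, ...) {
  keep <- species %||%
    object$species$id[object$species$internal & !object$species$clamped]
  tbl <- as_tibble(object) %>% filter(.data$species_id %in% keep)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$time, y = .data$concentration,
                                    colour = .data$species_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (mM)",
                  colour = "species") +
    ggplot2::theme_minimal()
}
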