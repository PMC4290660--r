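#' Plot cluster sizes
#'
#' @param object A [kclust()] result.
#' @param ... Ignored.
#' @return A ggplot: members per cluster, largest first.
#' @export
autoplot.cluster_set <- function(object, ...) {
  sizes <- object$assignments |>
    dplyr::count(.data$cluster, name = "members") |>
    dplyr::arrange(dplyr::desc(.data$members)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$members)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (by size)", y = "members",
                  title = paste0("RMSD-radius clustering (radius ",
                                 object$radius, " Å)"))
}

#' Plot the staged selection
#'
#' @param object A [select_top5()] result.
#' @param ... Ignored.
#' @return A ggplot of CS for all scored models, highlighting the final
#'   five.
#' @export
autoplot.selection_report <- function(object, ...) {
  d <- object$descriptors |>
    dplyr::mutate(stage = ifelse(.data$id %in% object$final$id,
                                 "final 5", "scored"))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$id, .data$CS),
                                  y = .data$CS, fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "decoy (by CS)", y = "cumulative score (CS)",
                  fill = NULL, title = "pcSM ranking")
}

#' Score-versus-error enrichment plot
#'
#' Scatter of the pcSM cumulative score against the known true C-alpha
#' RMSD of each decoy (synthetic pools carry this provenance), the visual
#' check that low CS picks out near-native models.
#'
#' @param descriptors A descriptor table with `id` and `CS` columns.
#' @param pool A pool tibble with a `true_ca_rmsd` provenance column.
#' @return A ggplot.
#' @export
plot_score_vs_rmsd <- function(descriptors, pool) {
  if (!"true_ca_rmsd" %in% names(pool)) {
    abort("pool has no 'true_ca_rmsd' provenance column")
  }
  d <- dplyr::inner_join(descriptors,
                         pool[, c("id", "true_ca_rmsd")], by = "id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true_ca_rmsd, y = .data$CS)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "true Cα RMSD to native (Å)",
                  y = "cumulative score (CS)",
                  title = "pcSM enrichment")
}

#' Plot evaluation records
#'
#' @param records A tibble from [evaluate()] (optionally with a `target`
#'   column).
#' @param tm_cut,rmsd_cut Reference thresholds drawn as dashed lines.
#' @return A ggplot of TM-score against C-alpha RMSD.
#' @export
plot_evaluation <- function(records, tm_cut = 0.5, rmsd_cut = 5.0) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$ca_rmsd,
                                        y = .data$tm_score)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = tm_cut, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = rmsd_cut, linetype = "dashed") +
    ggplot2::labs(x = "Cα RMSD (Å)", y = "TM-score")
}
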