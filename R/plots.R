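# ggplot2 views of each result type.

#' Histogram of the R_sum distribution
#'
#' @param cor_table A correlation table with an `r_sum` column.
#' @param quantile Optional tail fraction; when given, the positive-extreme
#'   threshold is drawn as a dashed line.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_rsum_distribution <- function(cor_table, quantile = 0.005, bins = 60) {
  p <- ggplot2::ggplot(cor_table, ggplot2::aes(x = .data$r_sum)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = expression(R[sum]), y = "genes") +
    ggplot2::theme_minimal()
  if (!is.null(quantile)) {
    thr <- attr(extreme(cor_table, quantile = quantile), "threshold_value")
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @method autoplot extreme_set
#' @export
autoplot.extreme_set <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(.data$gene_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_sum, y = .data$gene_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(R[sum]), y = NULL,
                  title = sprintf("Top %.2g%% of the R_sum distribution",
                                  100 * attr(object, "quantile"))) +
    ggplot2::theme_minimal()
}

#' Two-channel intensity traces along membrane profiles
#'
#' @param profiles Profile tibble (`profile_id`, `position`, `channel1`,
#'   `channel2`).
#' @param ids Optional subset of profile ids to show.
#' @return A ggplot object, one facet per profile.
#' @export
plot_profiles <- function(profiles, ids = NULL) {
  if (!is.null(ids)) profiles <- filter(profiles, .data$profile_id %in% ids)
  long <- tidyr::pivot_longer(profiles, c("channel1", "channel2"),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position,
                                     y = .data$intensity,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~profile_id, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(channel1 = "forestgreen",
                                            channel2 = "firebrick")) +
    ggplot2::labs(x = "position along membrane", y = "intensity") +
    ggplot2::theme_minimal()
}

#' @method autoplot ratio_trace
#' @export
autoplot.ratio_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~profile_id, scales = "free_x") +
    ggplot2::labs(x = "position along membrane", y = "channel1 / channel2") +
    ggplot2::theme_minimal()
}

#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "profiles", y = .data$r)) +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::annotate("pointrange", x = 1, y = object$mean_r,
                      ymin = object$mean_r - object$sem_r,
                      ymax = object$mean_r + object$sem_r,
                      colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "per-profile r",
                  subtitle = sprintf("mean %.3f +/- %.3f (SEM), p = %.3g vs 0",
                                     object$mean_r, object$sem_r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Map of motif hits in TSS-relative coordinates
#'
#' @param hits Hit table from [scan_motifs()] or [scan_promoter()].
#' @return A ggplot object: one point per hit, colour by motif, shape by
#'   strand, x at the signed TSS position.
#' @export
plot_motif_hits <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$tss_position,
                                     y = .data$motif,
                                     colour = .data$motif,
                                     shape = .data$strand)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
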