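#' Plotting helpers
#'
#' ggplot2-based views of the package's result types: MID bar charts,
#' distance heatmaps, labeling time courses and precision-recall curves.
#'
#' @name plots
NULL

#' Plot the MIDs of one peak across experiments
#'
#' @param table a `peak_tbl`.
#' @param peak_id the peak to show.
#' @param correct apply natural-13C correction for display (the usual
#'   convention: distances use uncorrected MIDs, figures corrected
#'   ones).
#' @param p13 natural 13C abundance.
#' @return a ggplot.
#' @export
plot_mid <- function(table, peak_id, correct = FALSE, p13 = 0.0107) {
  i <- match(peak_id, table$peak_id)
  if (is.na(i)) abort(paste0("unknown peak id: ", peak_id), class = "midtrace_error")
  m <- table$mids[[i]]
  df <- purrr::map_dfr(names(m), function(e) {
    x <- m[[e]]
    if (correct) x <- as.numeric(correct_natural_abundance(x, p13))
    tibble(experiment = e, mi = seq_along(x) - 1L, fraction = x)
  })
  df$experiment <- factor(df$experiment, levels = experiments(table))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mi, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$experiment)) +
    ggplot2::labs(x = "mass isotopomer (M+i)", y = "fraction",
                  title = peak_id) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mid_dist <- function(object, ...) {
  M <- dist_matrix(object)
  df <- tibble(peak_a = rep(rownames(M), ncol(M)),
               peak_b = rep(colnames(M), each = nrow(M)),
               distance = as.vector(M))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_a, y = .data$peak_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "MID distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision",
                  subtitle = sprintf("AUPR = %.3f (prevalence %.3f)",
                                     attr(object, "aupr"),
                                     attr(object, "prevalence"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mid_sim <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$fraction,
                                   color = factor(.data$mi))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metabolite)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(color = "M+i", x = "time", y = "MI fraction") +
    ggplot2::theme_minimal()
}
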