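#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-lifetime curve
#'
#' Points are per-bin mean lifetimes with SEM error bars; an optional fitted
#' dual-pathway curve is overlaid.
#'
#' @param object A `lifetime_curve`.
#' @param fit Optional `dual_pathway_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lifetime_curve <- function(object, fit = NULL, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$n > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$force_mid, y = .data$mean_s)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_s - .data$sem_s,
                                        ymax = .data$mean_s + .data$sem_s),
                           width = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Force (pN)", y = "Bond lifetime (s)") +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    ff <- seq(min(df$bin_lo), max(df$bin_hi), length.out = 200)
    fd <- tibble::tibble(force_mid = ff,
                         mean_s = dual_pathway_lifetime(ff, fit$k_c, fit$x_c,
                                                        fit$k_s, fit$x_s, fit$kBT))
    p <- p + ggplot2::geom_line(data = fd, colour = "firebrick")
  }
  p
}

#' Plot a trace with its phase segmentation
#'
#' Loading is drawn in black, the bond dwell in green, the post-rupture
#' baseline in red, and detected transitions as blue arrows, mirroring the
#' standard presentation of force-clamp traces.
#'
#' @param object A `trap_trace`.
#' @param segmentation Optional [segment_trace()] result (computed if
#'   missing).
#' @param transitions Optional [detect_transitions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trap_trace <- function(object, segmentation = NULL,
                                transitions = NULL, ...) {
  if (is.null(segmentation)) {
    segmentation <- tryCatch(segment_trace(object), error = function(e) NULL)
  }
  df <- tibble::as_tibble(object)
  if (!is.null(segmentation)) {
    rt <- if (segmentation$censored) Inf else segmentation$rupture_time
    df$phase <- dplyr::case_when(
      df$time_s < segmentation$t_clamp ~ "loading",
      df$time_s < rt ~ "dwell",
      TRUE ~ "ruptured")
  } else {
    df$phase <- "trace"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$separation_nm,
                                        colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(loading = "black", dwell = "forestgreen",
                                            ruptured = "firebrick", trace = "grey30")) +
    ggplot2::labs(x = "Time (s)", y = "Bead-trap separation (nm)") +
    ggplot2::theme_classic()
  if (!is.null(transitions) && nrow(transitions) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = transitions$time,
                                 colour = "blue", linetype = "dashed")
  }
  p
}

#' Bar plot of high-occupancy contact counts for one or more interfaces
#'
#' Mean counts of contacts above the occupancy threshold, split by contact
#' kind, with SD-over-windows error bars.
#'
#' @param summaries An `interface_summary` or list of them.
#' @return A ggplot.
#' @export
plot_interface_summary <- function(summaries) {
  if (inherits(summaries, "interface_summary")) summaries <- list(summaries)
  df <- purrr::map_dfr(summaries, function(s) {
    dplyr::mutate(s$stats, interface = s$interface, .before = 1)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interface, y = .data$mean_count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_count - .data$sd_count,
                                        ymax = .data$mean_count + .data$sd_count),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Contacts with occupancy > threshold",
                  fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot a sensitivity index across force bins
#'
#' @param object A `sensitivity_index`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_index <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$force_mid, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio - .data$se,
                                        ymax = .data$ratio + .data$se), width = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Force (pN)", y = "Lifetime ratio (specific / nonspecific)") +
    ggplot2::theme_classic()
}
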