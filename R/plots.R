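## ggplot2 graphics for the main result types.

#' Scree plot of a shared PCA model
#' @param object a `msw_pca`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msw_pca <- function(object, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$proportion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of variance",
                  title = "Shared backbone PCA") +
    ggplot2::theme_minimal()
}

#' Per-ensemble 2-D histogram panels of PC scores
#'
#' One panel per ensemble on shared axes, so positions are directly
#' comparable across binding states. Cluster centres can be overlaid.
#'
#' @param scores a `msw_scores` tibble.
#' @param pcs the two PC columns.
#' @param bins bins per axis.
#' @param clusters optional list of `msw_clusters` whose centres to mark.
#' @return a ggplot.
#' @export
plot_pc_histogram <- function(scores, pcs = c("pc0", "pc1"), bins = 100,
                              clusters = NULL) {
  p <- ggplot2::ggplot(scores,
                       ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::facet_wrap(~ensemble) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    if (inherits(clusters, "msw_clusters")) clusters <- list(clusters)
    cen <- dplyr::bind_rows(lapply(clusters, function(a) {
      d <- tidy(a)
      d$ensemble <- a$ensemble[1]
      d
    }))
    p <- p + ggplot2::geom_point(
      data = cen, ggplot2::aes(x = .data$center_pc0, y = .data$center_pc1),
      inherit.aes = FALSE, shape = 17, size = 2, colour = "black")
  }
  p
}

#' chi1 vs chi2 scatter coloured by rotamer state
#'
#' @param states a `msw_states` tibble (keeps the chi columns), ideally
#'   filtered to one residue.
#' @param thin plot at most this many points per residue (deterministic
#'   regular thinning).
#' @return a ggplot.
#' @export
plot_chi_scatter <- function(states, thin = 5000) {
  d <- states |>
    dplyr::group_by(.data$resno) |>
    dplyr::slice(unique(as.integer(round(
      seq(1, dplyr::n(), length.out = min(thin, dplyr::n())))))) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chi1, y = .data$chi2,
                                  colour = factor(.data$state_label))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::facet_wrap(~ paste0(.data$resid, .data$resno)) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "chi1 (deg)", y = "chi2 (deg)", colour = "state") +
    ggplot2::theme_minimal()
}

#' Rotamer state versus time, one panel per replica
#' @param states a `msw_states` tibble filtered to one residue.
#' @param dwells optional tibble from [dwell_segments()] to shade.
#' @return a ggplot.
#' @export
plot_state_trace <- function(states, dwells = NULL) {
  p <- ggplot2::ggplot(states, ggplot2::aes(x = .data$frame, y = .data$state)) +
    ggplot2::geom_step(linewidth = 0.2) +
    ggplot2::facet_grid(replica ~ ensemble) +
    ggplot2::labs(x = "frame", y = "rotamer state") +
    ggplot2::theme_minimal()
  if (!is.null(dwells) && nrow(dwells)) {
    p <- p + ggplot2::geom_rect(
      data = dwells,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue")
  }
  p
}

#' Per-residue ECC profile
#' @param results tibble from [ecc_scan()].
#' @param top_n label this many top-ranked residues.
#' @return a ggplot.
#' @export
plot_ecc <- function(results, top_n = 3) {
  lab <- results[order(-results$ecc), ][seq_len(min(top_n, nrow(results))), ]
  ggplot2::ggplot(results, ggplot2::aes(x = .data$resno, y = .data$ecc)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$resno, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = paste0(.data$resid, .data$resno)),
                       vjust = -0.6, size = 3) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "residue", y = "ECC") +
    ggplot2::theme_minimal()
}

#' Conditional histogram panels: one per rotamer state
#' @param object a `msw_conditional`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msw_conditional <- function(object, ...) {
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  d <- dplyr::bind_rows(lapply(names(object$histograms), function(s) {
    h <- object$histograms[[s]]
    g <- expand.grid(x = mids(h$xedges), y = mids(h$yedges))
    g$count <- as.vector(h$counts)
    f <- object$fractions$fraction[match(as.integer(s), object$fractions$state)]
    g$state <- sprintf("state %s (%.1f%%)", s, 100 * f)
    g
  }))
  ggplot2::ggplot(d[d$count > 0, ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::facet_wrap(~state) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = object$pcs[1], y = object$pcs[2]) +
    ggplot2::theme_minimal()
}

#' Rate/affinity response to shifting the competent population
#' @param object a `msw_tuning_curve` from [fine_tuning_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msw_tuning_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(dplyr::as_tibble(object),
                           c("k_on_eff", "K_d", "t_half"),
                           names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_competent, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "binding-competent population",
                  title = paste0("conformational selection (",
                                 attr(object, "scenario"), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
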