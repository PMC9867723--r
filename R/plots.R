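#' Plot an MDS embedding of donors or samples
#'
#' @param object a [classical_mds()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tc_mds
#' @export
autoplot.tc_mds <- function(object, ...) {
  dat <- tidy(object)
  pt <- if ("group" %in% names(dat)) {
    ggplot2::geom_point(size = 2.5, ggplot2::aes(colour = .data$group))
  } else {
    ggplot2::geom_point(size = 2.5)
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    pt +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(
      x = "MDS dimension 1", y = "MDS dimension 2", colour = "Group",
      title = sprintf("Classical MDS (GOF %.2f)", object$gof)
    ) +
    ggplot2::theme_minimal()
  p
}

#' Volcano plot of one time point of a differential table
#'
#' Core-gene gates (|median log2 FC| and adjusted-p thresholds) are drawn
#' as reference lines; features passing both are highlighted by direction.
#'
#' @param table a [differential_table()] result.
#' @param time_h the time point to show.
#' @param thresholds a [tc_thresholds()].
#' @return A ggplot.
#' @export
plot_volcano <- function(table, time_h, thresholds = tc_thresholds()) {
  dat <- table[table$time_h == time_h, ]
  if (!nrow(dat)) abort(sprintf("No rows at %s h.", format(time_h)))
  dat$status <- ifelse(
    dat$p_adj <= thresholds$alpha & dat$median_log2fc >= thresholds$grp_log2fc,
    "increased",
    ifelse(dat$p_adj <= thresholds$alpha &
             dat$median_log2fc <= -thresholds$grp_log2fc,
           "decreased", "ns"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$median_log2fc,
                                    y = -log10(.data$p_adj),
                                    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * thresholds$grp_log2fc,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(thresholds$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      increased = "#c0392b", decreased = "#2980b9", ns = "grey70")) +
    ggplot2::labs(x = "median log2 fold change (PD - HC)",
                  y = "-log10 adjusted p",
                  title = sprintf("PD vs HC at %s h", format(time_h))) +
    ggplot2::theme_minimal()
}

#' Plot activation-marker time courses per group
#'
#' Group medians over the activation time course with the per-group
#' expression range, mirroring a marker-induction QC view.
#'
#' @param qc a [marker_qc()] result.
#' @return A ggplot.
#' @export
plot_marker_qc <- function(qc) {
  stopifnot(inherits(qc, "marker_qc"))
  long <- qc$report |>
    tidyr::pivot_longer(
      cols = c("median_pd", "median_hc"),
      names_to = "group", values_to = "median"
    ) |>
    mutate(
      group = ifelse(.data$group == "median_pd", "PD", "HC"),
      lo = ifelse(.data$group == "PD", .data$min_pd, .data$min_hc),
      hi = ifelse(.data$group == "PD", .data$max_pd, .data$max_hc)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$median,
                                     colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$group),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~marker, scales = "free_y") +
    ggplot2::labs(x = "time after activation (h)", y = "log2 expression",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}
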