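#' Plot windowed effective-migration estimates along the genome
#'
#' @param results A [window_scan()] table with `chrom`, `start` and `me`
#'   (optionally `barrier` to colour barrier windows).
#' @return A ggplot object.
#' @export
plot_me_scan <- function(results) {
  res <- as_tibble(results)
  p <- ggplot2::ggplot(res, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                         y = .data$me))
  if ("barrier" %in% names(res)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$barrier),
                                 size = 0.8) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "firebrick"))
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, colour = "grey40")
  }
  p +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)",
                  y = expression(m[e] ~ "(per generation)")) +
    ggplot2::theme_minimal()
}

#' Plot the conditional lnCL profile over me for one window
#'
#' @param results A [window_scan()] table.
#' @param window_id Which window to plot.
#' @return A ggplot object.
#' @export
plot_me_profile <- function(results, window_id) {
  i <- match(window_id, results$window_id)
  if (is.na(i)) abort("unknown `window_id`")
  prof <- results$profile[[i]]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$me, y = .data$lnCL)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(m[e]), y = "conditional lnCL",
                  title = sprintf("window %s", window_id)) +
    ggplot2::theme_minimal()
}

#' Plot per-chromosome mean me against chromosome length
#'
#' @param chrom_summary The `chromosomes` tibble from
#'   [summarize_chromosomes()], optionally with a logical `rearranged`
#'   column.
#' @return A ggplot object.
#' @export
plot_chromosome_me <- function(chrom_summary) {
  cs <- as_tibble(chrom_summary)
  p <- ggplot2::ggplot(cs, ggplot2::aes(x = .data$length,
                                        y = .data$mean_me))
  if ("rearranged" %in% names(cs)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$rearranged),
                                 size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::geom_text(ggplot2::aes(label = .data$chromosome),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "chromosome length (bp)",
                  y = expression(mean ~ m[e])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of an observed bSFS tally
#'
#' @param object A [bsfs_tally].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsfs_tally <- function(object, ...) {
  df <- as_tibble(object)
  df$bin <- paste(df$hetA, df$hetB, df$hetAB, df$fixed, sep = ",")
  df <- arrange(df, dplyr::desc(.data$n))
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(utils::head(df, 40),
                  ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mutation-type vector (hetA,hetB,hetAB,fixed)",
                  y = "blocks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
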