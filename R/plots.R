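# ggplot2 display methods for the main result types.

#' Plot a trinucleotide signature matrix
#'
#' Bar plot of the 96 contexts, faceted by strand and replication arc.
#'
#' @param object An `mt_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mt_signature <- function(object, ...) {
  df <- dplyr::mutate(object,
    context = paste0(.data$five, ".", .data$three),
    stratum = paste(.data$strand, "strand,", .data$arc, "arc")
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$context, y = .data$frequency, fill = .data$substitution
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(stratum ~ substitution, scales = "free_x") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 4),
      legend.position = "none"
    ) +
    ggplot2::labs(
      x = "flanking context (5'.3')", y = "fraction of substitutions",
      title = "Trinucleotide substitution spectrum by strand and replication arc"
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.mt_region_scan <- function(object, ...) {
  df <- dplyr::filter(object, .data$tested)
  df$idx <- seq_len(nrow(df))
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = -log10(.data$p_skato))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "region", y = "-log10 p (SKAT-O)",
      title = sprintf(
        "Region burden scan (threshold %s)", format(signif(thr, 1))
      )
    )
}

#' ggplot2 autoplot generic
#'
#' Re-exported from ggplot2 so `autoplot()` works on this package's result
#' objects without attaching ggplot2.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @name autoplot
#' @rdname reexports
NULL

#' Burden against age
#'
#' Scatter of per-individual burden counts of one heteroplasmy class
#' against age with a Poisson-GLM smoother, coloured by group.
#'
#' @param burden An `mt_burden` table.
#' @param samples Sample tibble.
#' @param het_class Class to display.
#' @return A ggplot object.
#' @export
plot_burden_age <- function(burden, samples, het_class = "low") {
  d <- burden |>
    dplyr::filter(.data$het_class == !!het_class) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::inner_join(samples, by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$n, colour = .data$group)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(
      method = "glm", method.args = list(family = "poisson"),
      formula = y ~ x, se = TRUE
    ) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "age (years)", y = sprintf("%s heteroplasmy count", het_class)
    )
}

#' Length-normalised locus frequencies
#'
#' @param lf Tibble from [locus_frequency()].
#' @return A ggplot object.
#' @export
plot_locus_frequency <- function(lf) {
  ggplot2::ggplot(lf, ggplot2::aes(
    x = .data$locus, y = .data$frequency, fill = .data$het_class
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6)) +
    ggplot2::labs(
      x = NULL, y = "variant sites per bp",
      fill = "class"
    )
}
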