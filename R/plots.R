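#' Plot a stop-codon metagene profile
#'
#' Footprint density at each offset from the first nucleotide of the stop
#' codon; the stop codon itself spans offsets 0-2 (shaded).
#'
#' @param profile A `metagene_profile` from [stop_codon_metagene()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$count)) +
    ggplot2::annotate("rect", xmin = -0.5, xmax = 2.5, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "red") +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "offset from stop codon (nt)", y = "footprint count") +
    ggplot2::theme_minimal()
  if ("stop_codon" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$stop_codon), ncol = 1)
  }
  p
}

#' @rdname plot_metagene
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) plot_metagene(object)

#' Plot the eEF1A-binding scores of an enumerated variant set
#'
#' @param variants A `suppressor_variants` tibble from
#'   [enumerate_variants()].
#' @return A ggplot object: variants ordered by their additive T-stem
#'   free-energy score; identity violators highlighted.
#' @export
plot_variants <- function(variants) {
  df <- tidy.suppressor_variants(variants)
  df$id <- factor(df$id, levels = rev(df$id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ddg_eef1a, y = .data$id,
                                   fill = .data$n_violations > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                               name = "identity violation") +
    ggplot2::labs(x = expression(Delta * Delta * G ~ "(kcal/mol, eEF1A binding)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_variants
#' @param object A `suppressor_variants` tibble.
#' @param ... Unused.
#' @method autoplot suppressor_variants
#' @export
autoplot.suppressor_variants <- function(object, ...) plot_variants(object)

#' Plot RRTS against each other for two conditions
#'
#' @param comparison An `rrts_comparison` from [compare_conditions()].
#' @return A ggplot scatter of per-transcript RRTS, faceted by stop
#'   identity when available.
#' @export
plot_rrts_comparison <- function(comparison) {
  labels <- attr(comparison, "labels")
  x <- paste0("rrts_", labels[1]); y <- paste0("rrts_", labels[2])
  p <- ggplot2::ggplot(comparison,
                       ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = paste("RRTS,", labels[1]), y = paste("RRTS,", labels[2])) +
    ggplot2::theme_minimal()
  if ("stop_codon" %in% names(comparison)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$stop_codon))
  }
  p
}

#' @rdname plot_rrts_comparison
#' @param object An `rrts_comparison`.
#' @param ... Unused.
#' @method autoplot rrts_comparison
#' @export
autoplot.rrts_comparison <- function(object, ...) plot_rrts_comparison(object)
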