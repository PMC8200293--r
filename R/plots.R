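#' Volcano plot of a differential-expression result
#'
#' @param object A `tt_de` result from [de_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tt_de
#' @export
autoplot.tt_de <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$fdr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fold_change,
                                  y = -log10(pmax(.data$fdr, 1e-300)),
                                  colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2471a3", ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Metagene profile plot
#'
#' @param object A `tt_metagene_profile` from [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot object with TSS/TES guides at the body boundaries.
#' @method autoplot tt_metagene_profile
#' @export
autoplot.tt_metagene_profile <- function(object, ...) {
  n_flank <- attr(object, "n_flank_bins") %||% 50
  n_body <- attr(object, "n_body_bins") %||% 100
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_line(colour = "#1b4f72") +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5,
                                       n_flank + n_body + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::annotate("text", x = c(n_flank + 0.5, n_flank + n_body + 0.5),
                      y = Inf, label = c("TSS", "TES"), vjust = 1.5,
                      size = 3, colour = "grey30") +
    ggplot2::labs(x = "bin (upstream - scaled body - downstream)",
                  y = "mean normalized coverage") +
    ggplot2::theme_minimal()
}

#' TES base-composition bias plot
#'
#' @param object A `tt_base_profile` from [base_fraction_window()].
#' @param ... Unused.
#' @return A ggplot object (raw fractions as points, smoothed as a line).
#' @method autoplot tt_base_profile
#' @export
autoplot.tt_base_profile <- function(object, ...) {
  base <- attr(object, "base") %||% "A"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw), size = 0.5,
                        colour = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       colour = "#b03a2e") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from TES (bp)",
                  y = paste0("fraction ", base)) +
    ggplot2::theme_minimal()
}
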