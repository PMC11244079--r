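#' Plot harmonic reconstructions of an EFD set
#'
#' Overlays outline reconstructions truncated at increasing harmonic ranks,
#' a standard diagnostic of how much shape detail each harmonic adds.
#'
#' @param object a `pip_efd` object.
#' @param harmonics harmonic ranks to overlay (default: 1, 2, 3 and all).
#' @param n_points points per reconstruction.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pip_efd <- function(object, harmonics = NULL, n_points = 360L, ...) {
  harmonics <- harmonics %||%
    unique(pmin(c(1L, 2L, 3L, object$n_harmonics), object$n_harmonics))
  df <- purrr::map(harmonics, function(h) {
    e <- object
    e$coefficients <- e$coefficients[seq_len(h), , drop = FALSE]
    o <- efd_reconstruct(e, n_points)
    o$harmonics <- factor(h, levels = harmonics)
    o
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$harmonics)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "harmonics", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot example outlines of a synthetic population
#'
#' Traces and draws a few silhouettes per class, a quick visual check of
#' the generated morphotypes.
#'
#' @param object a `pip_population`.
#' @param n_per_class outlines drawn per class label.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pip_population <- function(object, n_per_class = 3L, ...) {
  picks <- object$truth |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = n_per_class) |>
    dplyr::ungroup()
  df <- purrr::map2(picks$sample_id, picks$label, function(id, lab) {
    o <- trace_outline(object$images[[id]])
    o$sample_id <- id
    o$label <- lab
    o
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$sample_id)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an allocation report
#'
#' Bar charts of the per-site percentage allocations: wild/domestic status,
#' berry colour of the assigned cultivars, or their geographic origin.
#'
#' @param object an `allocation_report`.
#' @param type which breakdown to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.allocation_report <- function(object,
                                       type = c("status", "colour", "region"),
                                       ...) {
  type <- match.arg(type)
  df <- object[[type]]
  fill_var <- switch(type, status = "status", colour = "colour",
                     region = "origin_region")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$site, .data$pct,
                                        fill = .data[[fill_var]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of pips", fill = NULL) +
    ggplot2::theme_minimal()
  if (type == "colour") {
    p <- p + ggplot2::scale_fill_manual(
      values = c(white = "grey85", red = "firebrick", pink = "lightpink"),
      na.value = "grey50")
  }
  p
}

#' Plot a LOOCV confusion matrix
#'
#' @param object a `pip_loocv` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pip_loocv <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(.data$assigned, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "assigned", y = "true") +
    ggplot2::theme_minimal()
}
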