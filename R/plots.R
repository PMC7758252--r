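#' Plot a decoding timecourse
#'
#' Accuracy against time with the 50% chance baseline; when the per-
#' iteration matrix was retained (`keep_iterations = TRUE`), a ribbon of
#' +/- 1 SE of the bootstrapped mean is added.
#'
#' @param object A `decoding_timecourse`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$accuracy))
  iter <- attr(object, "iterations")
  if (!is.null(iter)) {
    se <- apply(iter, 1, sd) / sqrt(ncol(iter))
    df$lo <- df$accuracy - se
    df$hi <- df$accuracy + se
    p <- p + ggplot2::geom_ribbon(
      data = df, ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25)
  }
  p +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy",
                  title = attr(object, "comparison"),
                  subtitle = attr(object, "participant")) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-corrected group test
#'
#' Pointwise t statistics with significant cluster extents shaded.
#'
#' @param object A `cluster_result` from [cluster_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, ...) {
  t <- attr(object, "tstats")
  times <- attr(object, "times") %||% seq_along(t)
  df <- tibble::tibble(time_ms = times, t = pmin(pmax(t, -T_CAP), T_CAP))
  sig <- tibble::as_tibble(object[object$significant, , drop = FALSE])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$t))
  if (nrow(sig) > 0L && "start_ms" %in% names(sig)) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms,
                   ymin = -Inf, ymax = Inf),
      fill = "tomato", alpha = 0.2)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "t statistic") +
    ggplot2::theme_minimal()
}

#' Plot one frame of a stimulus sequence
#'
#' Dot positions for both eyes at one frame, coloured by contrast polarity,
#' with the annulus outlined.
#'
#' @param seq A `stimulus_sequence`.
#' @param frame Frame index.
#' @return A ggplot object.
#' @export
plot_stimulus_frame <- function(seq, frame = 1L) {
  df <- dplyr::filter(seq$dots, .data$frame == !!frame)
  if (nrow(df) == 0L) abort("no dots at that frame")
  th <- seq(0, 2 * pi, length.out = 200)
  ri <- seq$spec$annulus_inner_deg; ro <- seq$spec$annulus_outer_deg
  ring <- dplyr::bind_rows(
    tibble::tibble(x = ri * cos(th), y = ri * sin(th), ring = "inner"),
    tibble::tibble(x = ro * cos(th), y = ro * sin(th), ring = "outer")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_deg, y = .data$y_deg)) +
    ggplot2::geom_path(data = ring,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$ring),
                       colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$polarity),
                                     alpha = .data$contrast_weight),
                        size = 1) +
    ggplot2::scale_colour_manual(values = c(`-1` = "black", `1` = "white"),
                                 name = "polarity") +
    ggplot2::facet_wrap(~eye) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.background =
                     ggplot2::element_rect(fill = "grey80")) +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = sprintf("%s %s, frame %d", seq$spec$cue_type,
                                  seq$spec$direction, frame))
}
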