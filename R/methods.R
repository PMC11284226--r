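# tidy()/glance() accessors and autoplot() figures for the result classes

#' @exportS3Method generics::tidy
tidy.calcium_result <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.calcium_result <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.spike_train_set <- function(x, ...) x$spikes

#' @exportS3Method generics::glance
glance.spike_train_set <- function(x, ...) x$qc

#' @exportS3Method generics::tidy
tidy.embedding_result <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.embedding_result <- function(x, ...) {
  tibble(n_components = x$n_components,
         explained_variance = sum(x$explained_variance[seq_len(x$n_components)]))
}

#' @exportS3Method generics::tidy
tidy.overlap_result <- function(x, ...) {
  tibble(area_a = x$area_a, area_b = x$area_b,
         intersection_area = x$intersection_area,
         overlap_percent = x$overlap_percent, degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.fingerprint_result <- function(x, ...) x$embedding$scores

#' @exportS3Method generics::glance
glance.fingerprint_result <- function(x, ...) {
  dplyr::bind_cols(tidy(x$overlap),
                   tibble(n_components = x$embedding$n_components))
}

#' Plot a normalized calcium trace with its detected peaks
#'
#' @param object A `normalized_trace`.
#' @param peaks Optional peak tibble from [detect_calcium_peaks()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.normalized_trace <- function(object, peaks = NULL, ...) {
  df <- tibble(time_s = object$time_s, dff = object$dff)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0]),
                  title = object$roi_id) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = peaks,
                                 ggplot2::aes(x = .data$time_s, y = .data$height),
                                 colour = "red", size = 1.5)
  }
  p
}

#' Spike raster of a spike-train set
#'
#' Retained channels in black, excluded channels in grey.
#'
#' @param object A `spike_train_set`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.spike_train_set <- function(object, ...) {
  df <- dplyr::left_join(object$spikes,
                         dplyr::select(object$qc, "channel", "retained"),
                         by = "channel")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spike_time_s, y = .data$channel,
                                   colour = .data$retained)) +
    ggplot2::geom_point(shape = "|", size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Principal-component score plot
#'
#' @param object An `embedding_result`.
#' @param components Length-2 vector of component indices to show.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.embedding_result <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  cx <- paste0("PC", components[1]); cy <- paste0("PC", components[2])
  ev <- 100 * object$explained_variance
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[cx]], y = .data[[cy]],
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", cx, ev[components[1]]),
                  y = sprintf("%s (%.1f%%)", cy, ev[components[2]])) +
    ggplot2::theme_minimal()
}

hull_df <- function(h, label) {
  tibble(x = h[, 1], y = h[, 2], group = label)
}

#' Group hulls and their intersection in the projection plane
#'
#' @param object An `overlap_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_result <- function(object, ...) {
  hulls <- dplyr::bind_rows(hull_df(object$hull_a, "A"),
                            hull_df(object$hull_b, "B"))
  p <- ggplot2::ggplot(hulls, ggplot2::aes(x = .data$x, y = .data$y,
                                           fill = .data$group)) +
    ggplot2::geom_polygon(alpha = 0.3, colour = "grey30") +
    ggplot2::labs(x = "projection axis 1", y = "projection axis 2") +
    ggplot2::theme_minimal()
  if (!object$degenerate && !is.null(object$intersection) &&
      nrow(object$intersection) >= 3) {
    p <- p + ggplot2::geom_polygon(data = hull_df(object$intersection, "intersection"),
                                   fill = "grey20", alpha = 0.4) +
      ggplot2::ggtitle(sprintf("overlap %.1f%%", object$overlap_percent))
  }
  p
}

#' Fingerprint overview: PC scores with group hulls
#'
#' @param object A `fingerprint_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fingerprint_result <- function(object, ...) {
  sc <- object$embedding$scores
  plane <- object$plane
  cx <- paste0("PC", plane[1]); cy <- paste0("PC", plane[2])
  hulls <- dplyr::bind_rows(
    hull_df(object$overlap$hull_a, levels(factor(sc$group))[1]),
    hull_df(object$overlap$hull_b, levels(factor(sc$group))[2]))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[cx]], y = .data[[cy]],
                                   colour = .data$group)) +
    ggplot2::geom_polygon(data = hulls,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$group, fill = .data$group),
                          alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      title = if (object$overlap$degenerate) "overlap undefined"
              else sprintf("overlap %.1f%%", object$overlap$overlap_percent),
      x = cx, y = cy) +
    ggplot2::theme_minimal()
}
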