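#' Plot a scalar map as a coordinate scatter
#'
#' Grayordinates are drawn at their x/y coordinates (a flat projection of the
#' synthetic or CIFTI geometry), coloured by value.
#'
#' @param object A [scalar_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalar_map <- function(object, ...) {
  df <- tibble(x = object$space$coords[, 1], y = object$space$coords[, 2],
               value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "x (mm)", y = "y (mm)")
}

#' Plot a label map as a coordinate scatter coloured by network
#'
#' @param object A [label_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.label_map <- function(object, ...) {
  df <- tidy(object)
  df$x <- object$space$coords[, 1]
  df$y <- object$space$coords[, 2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$network)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "network")
}

#' Tidy a probability atlas into a long tibble
#'
#' @param x A `probability_atlas`.
#' @param ... Unused.
#' @return Tibble with `grayordinate`, `network`, `probability` (nonzero
#'   entries only).
#' @export
tidy.probability_atlas <- function(x, ...) {
  idx <- which(x$probs > 0, arr.ind = TRUE)
  tibble(grayordinate = as.integer(idx[, 2L]),
         network = x$palette[idx[, 1L]],
         probability = x$probs[idx]) |>
    dplyr::arrange(.data$grayordinate, .data$network)
}
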