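# ggplot2 visualisations for the main result types.

#' @export
autoplot.degree_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$centre, y = .data$count)) +
    geom_col(width = attr(object, "bin_width") * 0.9, fill = "grey30") +
    labs(x = sprintf("%s-degree (DN partners)", attr(object, "kind")),
         y = "number of DNs") +
    theme_minimal()
  if (!is.null(fit)) {
    fits <- if (inherits(fit, "degree_fit")) list(fit) else fit
    for (f in fits) {
      p <- p + geom_line(
        data = tibble(centre = f$data$x, count = f$fitted),
        aes(x = .data$centre, y = .data$count),
        colour = if (f$model == "exponential") "forestgreen" else "steelblue",
        linewidth = 0.8
      )
    }
  }
  p
}

#' @export
autoplot.dn_cocluster <- function(object, order = NULL, ...) {
  ord <- order %||% order_by_hierarchy(object)
  C <- object$cocluster[ord, ord]
  df <- tibble(
    row = rep(seq_along(ord), times = length(ord)),
    col = rep(seq_along(ord), each = length(ord)),
    value = as.vector(C)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "black",
                        name = "co-clustering\nfrequency") +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
autoplot.roi_sta <- function(object, ...) {
  m <- object$masked
  df <- tibble(
    roi = rep(seq_len(nrow(m)), times = ncol(m)),
    time = rep(object$time, each = nrow(m)),
    dff = as.vector(m)
  )
  ggplot(df, aes(x = .data$time, y = .data$roi, fill = .data$dff)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         name = "dF/F") +
    annotate("rect", xmin = 0, xmax = object$stim_off_s,
             ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "orange") +
    labs(x = "time from stimulus onset (s)", y = "ROI") +
    theme_minimal()
}

#' Plot an inter-cluster signed synapse matrix
#'
#' @param M matrix from [intercluster_synapse_matrix()].
#' @return a ggplot.
#' @export
plot_intercluster_matrix <- function(M) {
  df <- tibble(
    pre = rep(rownames(M), times = ncol(M)),
    post = rep(colnames(M), each = nrow(M)),
    value = as.vector(M)
  )
  ggplot(df, aes(x = .data$post, y = .data$pre, fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         name = "normalised\nsynapses") +
    scale_y_discrete(limits = rev(rownames(M))) +
    labs(x = "postsynaptic cluster", y = "presynaptic cluster") +
    theme_minimal()
}

#' Plot behaviour probability curves
#'
#' @param probabilities tibble from [behaviour_probability()].
#' @param sample_rate optional Hz to put time in seconds.
#' @return a ggplot.
#' @export
plot_behaviour_probability <- function(probabilities, sample_rate = NULL) {
  df <- probabilities
  if (!is.null(sample_rate)) df$time <- df$time / sample_rate
  ggplot(df, aes(x = .data$time, y = .data$probability,
                 colour = .data$label)) +
    geom_line() +
    labs(x = if (is.null(sample_rate)) "time (samples)" else "time (s)",
         y = "P(behaviour)", colour = NULL) +
    theme_minimal()
}

#' Plot a multi-fly response density map
#'
#' @param x a [density_map()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.response_density <- function(x, ...) {
  df <- tibble(
    y = rep(seq_len(nrow(x)), times = ncol(x)),
    x = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(unclass(x))
  )
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "dF/F") +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "x (px)", y = "y (px, dorsal up)") +
    theme_minimal()
}
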