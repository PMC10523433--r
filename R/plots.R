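#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_tile labs
#'   scale_fill_manual theme_minimal facet_grid vars
NULL

series_autoplot <- function(object, ylab) {
  ggplot(as_tibble(object), aes(x = .data$frame, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_grid(rows = vars(.data$replica_id), labeller = "label_both") +
    labs(x = "frame", y = ylab) +
    theme_minimal()
}

#' Plot a torsion series
#' @param object A `torsion_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot torsion_tbl
#' @export
autoplot.torsion_tbl <- function(object, ...) {
  series_autoplot(object, "torsion (degrees)") +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90))
}

#' Plot a distance series
#' @param object A `distance_tbl`.
#' @param threshold Optional gate threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_tbl
#' @export
autoplot.distance_tbl <- function(object, threshold = NULL, ...) {
  p <- series_autoplot(object, "distance (Å)")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a ligand RMSD series
#' @param object An `rmsd_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rmsd_tbl
#' @export
autoplot.rmsd_tbl <- function(object, ...) {
  series_autoplot(object, "ligand RMSD (Å)")
}

#' Plot a circular torsion histogram
#' @param object A `circular_histogram`.
#' @param ... Unused.
#' @return A ggplot object (bar chart over (-180, 180]).
#' @method autoplot circular_histogram
#' @export
autoplot.circular_histogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$bin_mid, y = .data$count)) +
    geom_col(width = object$bin_hi[1] - object$bin_lo[1]) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    labs(x = "torsion (degrees)",
         y = if (isTRUE(attr(object, "normalized"))) "fraction" else "count") +
    theme_minimal()
}

#' Plot a replica-by-time state heatmap
#' @param object A `state_heatmap` matrix.
#' @param ... Unused.
#' @return A ggplot tile plot, one row per replica.
#' @method autoplot state_heatmap
#' @export
autoplot.state_heatmap <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    replica_id = rep(rownames(m), times = ncol(m)),
    window = rep(seq_len(ncol(m)), each = nrow(m)),
    state = as.vector(m)
  )
  ggplot(df, aes(x = .data$window, y = .data$replica_id,
                 fill = .data$state)) +
    geom_tile() +
    labs(x = "time window", y = "replica", fill = "state") +
    theme_minimal()
}
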