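#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a membrane-profile image with its boundary annotations
#'
#' @param object a `profile_image`.
#' @param show_boundaries overlay the annotated leaflet traces.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.profile_image <- function(object, show_boundaries = TRUE, ...) {
  img <- object$intensity
  p <- object$pixel_size_nm
  df <- expand.grid(x = (seq_len(ncol(img)) - 1) * p,
                    y = (seq_len(nrow(img)) - 1) * p)
  df$intensity <- as.vector(t(img))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = paste("state", object$truth_label)) +
    ggplot2::theme_minimal()
  if (show_boundaries && length(object$boundaries)) {
    bd <- purrr::imap(object$boundaries, function(tr, nm) {
      tibble::tibble(x = tr[, 1], y = tr[, 2], trace = nm)
    }) |> dplyr::bind_rows()
    g <- g + ggplot2::geom_path(
      data = bd, ggplot2::aes(.data$x, .data$y, colour = .data$trace),
      linewidth = 0.3)
  }
  g
}

#' Plot census fractions
#'
#' @param object a `census`.
#' @param ... unused.
#' @return a ggplot with synapse-group and event-state fractions.
#' @export
autoplot.census <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$table != "release")
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~table, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot the occupancy trajectories of a chain model
#'
#' @param object a `chain_model` or `msm_fit`.
#' @param t_max end of the time axis in ms (default: twice the observation
#'   window).
#' @param ... unused.
#' @return a ggplot of state occupancies over time.
#' @export
autoplot.chain_model <- function(object, t_max = NULL, ...) {
  if (is.null(t_max)) t_max <- 2 * object$T_ms
  ts <- seq(0, t_max, length.out = 121)
  occ <- occupancy(object, ts)
  df <- tibble::tibble(
    t_ms = rep(ts, ncol(occ)),
    state = rep(colnames(occ), each = length(ts)),
    p = as.vector(occ))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$p,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after AP (ms)", y = "occupancy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.chain_model
#' @export
autoplot.msm_fit <- function(object, t_max = NULL, ...) {
  autoplot.chain_model(object$model, t_max = t_max, ...)
}

#' Plot the SV-AZ gap trajectory of a docking simulation
#'
#' @param object a `docking_trajectory` from [run_docking()].
#' @param ... unused.
#' @return a ggplot of the gap time series with phase annotations.
#' @export
autoplot.docking_trajectory <- function(object, ...) {
  df <- object$gap_series
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$time_us, .data$gap_nm)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_hline(yintercept = object$config$curvature_trigger_gap_nm,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "time (us)", y = "SV-AZ gap (nm)") +
    ggplot2::theme_minimal()
  ev <- object$events
  if (!is.null(ev) && nrow(ev))
    g <- g + ggplot2::geom_vline(xintercept = ev$time_us, linetype = 3)
  g
}
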