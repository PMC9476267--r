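#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an elevation grid
#'
#' @param object a [dem_grid()].
#' @param ... unused.
#' @return A ggplot raster of elevation.
#' @method autoplot dem_grid
#' @export
autoplot.dem_grid <- function(object, ...) {
  ctr <- dem_centres(object)
  d <- tidyr::expand_grid(row = seq_along(ctr$y), col = seq_along(ctr$x))
  d$x <- ctr$x[d$col]; d$y <- ctr$y[d$row]
  d$elevation <- object$elevation[cbind(d$row, d$col)]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$elevation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "elevation (m)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Correlation heatmap of behaviour profiles
#'
#' @param object a `gp_correlation` from [correlation_matrix()].
#' @param ... unused.
#' @return A ggplot tile map of Pearson r with star annotation.
#' @method autoplot gp_correlation
#' @export
autoplot.gp_correlation <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     label = sprintf("%.2f%s", .data$r, .data$stars))
  ggplot2::ggplot(d, ggplot2::aes(.data$behaviour1, .data$behaviour2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}

#' Residuals-versus-fitted diagnostic plot
#'
#' @param object a `gp_resid` from [residual_diagnostics()].
#' @param ... unused.
#' @return A ggplot of scaled residuals with the acceptance limits.
#' @method autoplot gp_resid
#' @export
autoplot.gp_resid <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$fitted,
                                            .data$residual)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-object$limit, 0, object$limit),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = c("red", "grey40", "red")) +
    ggplot2::labs(
      x = "fitted value", y = "scaled residual",
      subtitle = sprintf("%.2f%% beyond +-%g (limit %.0f%%): %s",
                         100 * object$frac_beyond, object$limit,
                         100 * object$max_frac,
                         if (object$pass) "accepted" else "rejected"))
}

#' Plot cow trajectories
#'
#' @param fixes a fix or trajectory tibble.
#' @param colour_by column mapped to colour (default `cow_id`).
#' @return A ggplot of the paths.
#' @export
plot_trajectories <- function(fixes, colour_by = "cow_id") {
  ggplot2::ggplot(fixes, ggplot2::aes(.data$x, .data$y,
                                      colour = .data[[colour_by]],
                                      group = .data$cow_id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}

#' Marginal means with letter display
#'
#' @param posthoc a `gp_posthoc` carrying its marginal means (as produced
#'   inside [run_association_suite()]), or supply `mm` explicitly.
#' @param mm optional `gp_emm` to plot.
#' @return A ggplot of back-transformed means, standard errors and letters.
#' @export
plot_posthoc <- function(posthoc, mm = NULL) {
  mm <- mm %||% attr(posthoc, "marginal_means")
  if (is.null(mm)) stop("no marginal means available to plot", call. = FALSE)
  grouping <- attr(mm, "grouping")
  d <- dplyr::mutate(tibble::as_tibble(mm),
                     group = do.call(paste, mm[grouping]))
  d <- dplyr::left_join(d, posthoc$letters, by = "group")
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$response)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$response - .data$se,
                                          ymax = .data$response + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -1.2, size = 3) +
    ggplot2::labs(x = paste(grouping, collapse = " x "),
                  y = "marginal mean (measured units)")
}
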