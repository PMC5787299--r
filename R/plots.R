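# ggplot2 displays for the main result types

#' @export
autoplot.freelist_nmds <- function(object, data = NULL,
                                   colour = "interviewer_id",
                                   facet = FALSE, ...) {
  pts <- tidy(object)
  if (!is.null(data)) {
    meta <- if ("species_id" %in% names(data)) interview_meta(data)
            else tibble::as_tibble(data)
    pts <- dplyr::left_join(pts, meta, by = "interview_id")
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  if (!is.null(data) && colour %in% names(pts)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 alpha = 0.8)
    if (facet) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data[[colour]]))
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(caption = sprintf("stress-1 = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Interviewer-effect vector plot
#'
#' One pane per interviewer: the interviews of the repeat subset they
#' conducted versus the same informants interviewed by others, with the
#' effect vector drawn from the other-elicited centroid to the
#' interviewer-elicited centroid, and (when available) the interviewer's
#' own-answers location.
#'
#' @param effects Output of [interviewer_effects()].
#' @param coords The ordination the effects were computed in (optional
#'   background cloud of all interviews).
#' @return A ggplot object.
#' @export
plot_effect_vectors <- function(effects, coords = NULL) {
  p <- ggplot2::ggplot(effects)
  if (!is.null(coords)) {
    bg <- tidy(if (inherits(coords, "freelist_nmds")) coords else
               structure(list(points = as.matrix(coords)),
                         class = "freelist_nmds"))
    p <- p + ggplot2::geom_point(
      data = bg, ggplot2::aes(.data$NMDS1, .data$NMDS2),
      colour = "grey80", size = 0.6)
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$other_1, y = .data$other_2,
                   xend = .data$own_1, yend = .data$own_2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(.data$other_1, .data$other_2),
                        colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$interviewer_id)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "NMDS1", y = "NMDS2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.intra_inter <- function(object, ...) {
  ggplot2::ggplot(object$per_informant,
                  ggplot2::aes(stats::reorder(.data$informant_id,
                                              .data$intra_distance),
                               .data$intra_distance)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$mean_inter,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "informant (interviewed twice)",
                  y = "intra-informant distance",
                  caption = sprintf(
                    "dashed: mean inter-informant distance (%.3f); p = %.3f",
                    object$mean_inter, object$p_value)) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
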