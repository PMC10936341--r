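#' Plot category scores for a facility assessment or benchmark
#'
#' Bar chart of the six category percentages; a dashed line marks 100%
#' (scores above it come from bonus points).
#'
#' @param object A `pwat_assessment` or `pwat_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pwat_assessment
#' @export
autoplot.pwat_assessment <- function(object, ...) {
  plot_category_scores(
    object$scores,
    sprintf("Facility %s, %s", object$facility_id, object$period))
}

#' @rdname autoplot.pwat_assessment
#' @method autoplot pwat_benchmark
#' @export
autoplot.pwat_benchmark <- function(object, ...) {
  plot_category_scores(
    object$scores,
    sprintf("Facility %s, %s benchmark", object$facility_id, object$year))
}

plot_category_scores <- function(scores, title) {
  df <- scores |>
    dplyr::filter(.data$scope_kind == "category") |>
    dplyr::mutate(scope_name = factor(.data$scope_name,
                                      levels = pwat_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scope_name,
                                   y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::labs(title = title, x = NULL, y = "category score (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot overall scores across sites
#'
#' One bar per facility (anonymised label), ordered by rank, with the
#' cross-site mean as a dashed line.
#'
#' @param object A `pwat_cross_site` from [cross_site_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pwat_cross_site
#' @export
autoplot.pwat_cross_site <- function(object, ...) {
  df <- object$facilities |>
    dplyr::mutate(facility = factor(.data$facility,
                                    levels = .data$facility[
                                      order(.data$rank)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$facility,
                                   y = .data$overall_percentage)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::geom_hline(yintercept = mean(df$overall_percentage),
                        linetype = "dashed") +
    ggplot2::labs(x = "facility", y = "overall score (%)",
                  title = "Overall welfare score by site") +
    ggplot2::theme_minimal()
}
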