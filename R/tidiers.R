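#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a survey into a per-marker tibble
#'
#' @param x An `lgt_survey`.
#' @param distances If `TRUE`, return the long per-marker-per-lineage
#'   distance table instead of the per-marker verdict table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lgt_survey
#' @export
tidy.lgt_survey <- function(x, distances = FALSE, ...) {
  cl <- x$classifications
  if (distances) {
    cl |>
      dplyr::select("marker_id", "dataset", "distances") |>
      tidyr::unnest("distances")
  } else {
    dplyr::select(cl, -"sister_composition", -"distances")
  }
}

#' One-row summary of a survey
#'
#' @param x An `lgt_survey`.
#' @param ... Unused.
#' @return A one-row tibble: tree counts per focal-position category and
#'   the Asgard monophyly census.
#' @method glance lgt_survey
#' @export
glance.lgt_survey <- function(x, ...) {
  cl <- x$classifications
  tibble(
    n_trees = nrow(cl),
    n_no_focal = sum(cl$n_focal == 0),
    n_sister = sum(cl$focal_status == "sister"),
    n_nested = sum(cl$focal_status == "nested"),
    n_unresolved = sum(cl$focal_status %in%
                         c("unresolved", "paraphyletic_focal")),
    n_asgard_monophyletic = sum(cl$asgard_monophyly, na.rm = TRUE))
}

#' @method tidy distance_profile
#' @export
tidy.distance_profile <- function(x, ...) x$per_marker

#' @method glance distance_profile
#' @export
glance.distance_profile <- function(x, ...) {
  tibble(focal = x$focal, target = x$target, n_defined = x$n_defined,
         n_nested = x$n_nested, n_absent = x$n_absent,
         mode = profile_mode(x))
}

#' @method tidy lgt_call
#' @export
tidy.lgt_call <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lgt_call")
  out
}

#' Plot a nodal-distance profile
#'
#' Occurrence histogram of the per-marker nodal distance between the
#' focal clade and the target lineage, optionally overlaid with the mean
#' histogram of matched null profiles (dashed): a transfer-affected
#' marker set shows a near peak (distance 1-2) in excess of the null on
#' top of the far bulk.
#'
#' @param object A [distance_profile()].
#' @param nulls Optional list of null profiles to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_profile
#' @export
autoplot.distance_profile <- function(object, nulls = NULL, ...) {
  h <- object$histogram
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$distance, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.8) +
    ggplot2::labs(
      x = sprintf("nodes between %s and %s", object$focal, object$target),
      y = "trees (occurrences)",
      title = sprintf("Distance profile: %s vs %s", object$focal,
                      object$target)) +
    ggplot2::theme_minimal()
  if (!is.null(nulls) && length(nulls) > 0) {
    nh <- dplyr::bind_rows(lapply(nulls, function(z) z$histogram)) |>
      dplyr::group_by(.data$distance) |>
      dplyr::summarise(n = sum(.data$n) / length(nulls), .groups = "drop")
    p <- p + ggplot2::geom_line(data = nh, linetype = "dashed",
                                colour = "grey30") +
      ggplot2::geom_point(data = nh, colour = "grey30", size = 1)
  }
  p
}

#' Plot a survey's position census
#'
#' Bar chart of the per-dataset counts of each focal-position category
#' (sister/nesting lineage, not resolved, missing focal clade).
#'
#' @param object An `lgt_survey`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lgt_survey
#' @export
autoplot.lgt_survey <- function(object, ...) {
  long <- object$table1 |>
    tidyr::pivot_longer(-c("category", "total"), names_to = "dataset",
                        values_to = "n")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$category, .data$total),
                               y = .data$n, fill = .data$dataset)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "trees",
                  title = sprintf("Position of %s across gene trees",
                                  object$focal)) +
    ggplot2::theme_minimal()
}
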