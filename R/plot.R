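#' Bubble grid of rule results
#'
#' One panel per rule direction, factors on the vertical axis and strata
#' on the horizontal: circle size encodes confidence, colour intensity
#' encodes lift (blue for absence -> stable, red for presence ->
#' worsening), and cells whose lift is <= 1 or undefined are greyed out.
#' Undefined confidence renders as an empty cell.
#'
#' @param rules A `dkd_rules` table.
#' @param scheme Which scheme to draw (must be present in `rules`).
#' @param rule `"both"` (default; panels composed with patchwork) or a
#'   single direction.
#' @return A ggplot (single direction) or patchwork object.
#' @export
plot_rule_grid <- function(rules, scheme = "overall",
                           rule = c("both", "absence_stable",
                                    "presence_worsening")) {
  rule <- match.arg(rule)
  if (!scheme %in% rules$scheme) {
    stop("scheme `", scheme, "` not present in the rule table",
         call. = FALSE)
  }
  if (rule == "both") {
    p1 <- plot_rule_grid(rules, scheme, "absence_stable")
    p2 <- plot_rule_grid(rules, scheme, "presence_worsening")
    return(patchwork::wrap_plots(p1, p2, ncol = 2))
  }
  dat <- rules |>
    dplyr::filter(.data$scheme == !!scheme, .data$rule == !!rule) |>
    dplyr::mutate(
      factor = factor(.data$factor, levels = rev(unique(.data$factor))),
      stratum = factor(.data$stratum, levels = unique(.data$stratum))
    )
  hue <- if (rule == "absence_stable") "#2166ac" else "#b2182b"
  ttl <- if (rule == "absence_stable") {
    "Absence of risk factor → stable kidney function"
  } else {
    "Presence of risk factor → worsening kidney function"
  }
  ggplot2::ggplot(
    dplyr::filter(dat, !is.na(.data$confidence)),
    ggplot2::aes(x = .data$stratum, y = .data$factor,
                 size = .data$confidence)
  ) +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, !.data$significant),
      colour = "grey70", alpha = 0.8
    ) +
    ggplot2::geom_point(
      data = ~ dplyr::filter(.x, .data$significant),
      ggplot2::aes(colour = .data$lift)
    ) +
    ggplot2::scale_colour_gradient(low = "grey85", high = hue) +
    ggplot2::scale_size_area(max_size = 10, limits = c(0, 1)) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(title = ttl, x = NULL, y = NULL,
                  size = "confidence", colour = "lift") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 35, hjust = 1))
}

#' @rdname plot_rule_grid
#' @param object A `dkd_rules` table.
#' @param ... Passed to [plot_rule_grid()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.dkd_rules <- function(object, ...) {
  plot_rule_grid(object, ...)
}

#' @export
ggplot2::autoplot
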