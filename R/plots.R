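#' Rank-order plot of substitution outcomes at one position
#'
#' Plots the fold-change of every substitution at one (homolog, position),
#' rank-ordered from most-enhancing to most-diminishing, with the 2-fold
#' equivalence band and the DEL floor (MIN) marked — the standard way to
#' read rheostat (progressive) versus toggle (biphasic) behavior.
#'
#' @inheritParams classify_behavior
#' @param homolog,position The profile to plot.
#' @return A ggplot object.
#' @export
plot_rank_order <- function(measurements, contexts, homolog, position) {
  contexts <- validate_contexts(contexts)
  ctx <- contexts[contexts$homolog == homolog, ]
  if (nrow(ctx) != 1) abort(sprintf("Unknown homolog '%s'", homolog))
  d <- measurements %>%
    dplyr::filter(
      .data$homolog == .env$homolog,
      .data$position == as.character(.env$position),
      .data$condition == ctx$active_condition,
      !.data$excluded,
      .data$sub_aa != .data$wt_aa
    )
  if (nrow(d) == 0) abort("No scored substitutions for this profile")
  fc <- fold_change(ctx$parent_mean, ctx$parent_sd,
                    d$mean_miller, d$sd_miller,
                    ctx$del_mean, ctx$del_sd)
  d <- d %>%
    dplyr::mutate(fold = fc$value, at_min = fc$at_min) %>%
    dplyr::arrange(dplyr::desc(.data$fold)) %>%
    dplyr::mutate(rank = dplyr::row_number())
  min_fold <- ctx$parent_mean / ctx$del_mean
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$fold)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 0.5, ymax = 2, alpha = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = min_fold, linetype = "dotted") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$at_min)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sub_aa), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 name = "at MIN") +
    ggplot2::labs(
      x = "substitution rank",
      y = "fold-change vs parent (>1 = enhanced repression)",
      title = sprintf("%s position %s", homolog, position),
      subtitle = "shaded band: 2-fold equivalence; dotted line: DEL floor (MIN)"
    )
}

#' Entropy profile plot with tier labels
#'
#' Bar chart of per-position sequence entropies, coloured by the two-tier
#' toggle/rheostat separation.
#'
#' @param entropies A tibble with `position` and `entropy` columns, e.g.
#'   from [entropy_table()].
#' @inheritParams tier_separation
#' @return A ggplot object.
#' @export
plot_entropy_profile <- function(entropies, toggle_cut = 0.1,
                                 rheostat_cut = 0.6) {
  d <- tier_separation(entropies, toggle_cut, rheostat_cut) %>%
    dplyr::mutate(position = factor(.data$position,
                                    levels = unique(.data$position)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$entropy,
                                  fill = .data$tier)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(toggle_cut, rheostat_cut),
                        linetype = "dotted") +
    ggplot2::labs(x = "position", y = "sequence entropy (nats)",
                  fill = "tier")
}

#' @describeIn recovery_report Confusion-matrix heatmap.
#' @param object A `recovery_report`.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$code, y = .data$true_class,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "called code", y = "true class",
                  title = sprintf("recovery accuracy %.3f",
                                  object$accuracy))
}
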