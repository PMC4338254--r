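# broom-style tidiers and ggplot2 autoplot methods for result objects

#' Tidy a candidate screen report
#'
#' @param x a `zw_screen` tibble from [select_candidates()].
#' @param ... unused.
#' @return the per-contig tibble (already tidy), without the extra class.
#' @method tidy zw_screen
#' @export
tidy.zw_screen <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "zw_screen")
  out
}

#' One-row summary of a candidate screen
#'
#' @param x a `zw_screen` tibble from [select_candidates()].
#' @param ... unused.
#' @return one-row tibble: contigs screened, per-criterion pass counts,
#'   final candidates.
#' @method glance zw_screen
#' @export
glance.zw_screen <- function(x, ...) {
  tibble(n_contigs = nrow(x),
         n_exclusive = sum(x$exclusive),
         n_length_ok = sum(x$length_ok),
         n_posterior_ok = sum(x$posterior_ok),
         n_excluded = sum(x$excluded_as_contaminant),
         n_candidates = sum(x$final_candidate))
}

#' Tidy a concordance report
#'
#' @param x a `zw_concordance` from [concordance_report()].
#' @param ... unused.
#' @return the per-population summary tibble (overall row included).
#' @method tidy zw_concordance
#' @export
tidy.zw_concordance <- function(x, ...) x$by_population

#' One-row summary of a concordance report
#'
#' @param x a `zw_concordance` from [concordance_report()].
#' @param ... unused.
#' @return one-row tibble: `n_typed`, `n_concordant`, `n_discordant`,
#'   `concordance_fraction`.
#' @method glance zw_concordance
#' @export
glance.zw_concordance <- function(x, ...) {
  tibble(n_typed = x$n_typed,
         n_concordant = x$n_concordant,
         n_discordant = x$n_typed - x$n_concordant,
         concordance_fraction = x$concordance_fraction)
}

#' Plot a candidate screen
#'
#' Female expression total against the differential-expression posterior,
#' coloured by final candidacy; the posterior threshold and the length
#' criterion are encoded in shape.
#'
#' @param object a `zw_screen` tibble from [select_candidates()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot zw_screen
#' @export
autoplot.zw_screen <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$female_total + 1,
                               y = .data$posterior_de,
                               colour = .data$final_candidate,
                               shape = .data$length_ok)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total female-pool reads (+1, log scale)",
                  y = "posterior probability of differential expression",
                  colour = "final candidate", shape = "length > threshold") +
    ggplot2::theme_minimal()
}

#' Plot a concordance report
#'
#' Stacked per-population bars of concordant vs discordant individuals.
#'
#' @param object a `zw_concordance` from [concordance_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot zw_concordance
#' @export
autoplot.zw_concordance <- function(object, ...) {
  df <- object$by_population |>
    filter(.data$population != "(overall)") |>
    tidyr::pivot_longer(c("n_concordant", "n_discordant"),
                        names_to = "status", values_to = "n") |>
    mutate(status = dplyr::if_else(.data$status == "n_concordant",
                                   "concordant", "discordant"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "individuals", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a divergence estimate
#'
#' Age interval per locus implied by the clock-rate range.
#'
#' @param object a `zw_divergence` tibble (rows from
#'   [divergence_estimate()] may be bound together).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot zw_divergence
#' @export
autoplot.zw_divergence <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(y = .data$locus)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t_min_myr,
                                       xend = .data$t_max_myr,
                                       yend = .data$locus),
                          linewidth = 2, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(x = .data$t_min_myr)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$t_max_myr)) +
    ggplot2::labs(x = "divergence time (Myr)", y = NULL) +
    ggplot2::theme_minimal()
}
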