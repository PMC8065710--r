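# Tidier and plotting methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a staged repertoire into one motif-per-row tibble
#'
#' @param x a `gtp_repertoire`.
#' @param ... unused.
#' @return tibble with a `stage` column prepended to the motif columns.
#' @method tidy gtp_repertoire
#' @export
tidy.gtp_repertoire <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$generated, stage = "generated", .before = 1),
    dplyr::mutate(x$post_positive, stage = "post_positive", .before = 1),
    dplyr::mutate(x$released, stage = "released", .before = 1))
}

#' One-row summary of a staged repertoire
#'
#' @param x a `gtp_repertoire`.
#' @param ... unused.
#' @return one-row tibble with per-stage counts and the released fraction.
#' @method glance gtp_repertoire
#' @export
glance.gtp_repertoire <- function(x, ...) {
  tibble::tibble(generated = unname(x$counts[["generated"]]),
                 post_positive = unname(x$counts[["post_positive"]]),
                 released = unname(x$counts[["released"]]),
                 released_fraction = unname(x$counts[["released"]]) /
                   max(1L, unname(x$counts[["generated"]])))
}

#' Tidy a scenario report into its event log
#'
#' @param x a `scenario_report`.
#' @param ... unused.
#' @return the event tibble.
#' @method tidy scenario_report
#' @export
tidy.scenario_report <- function(x, ...) x$events

#' One-row summary of a scenario run
#'
#' @param x a `scenario_report`.
#' @param ... unused.
#' @return one-row tibble: scenario, seed, budget, stage counts, outcome.
#' @method glance scenario_report
#' @export
glance.scenario_report <- function(x, ...) {
  tibble::tibble(scenario = x$config$scenario, seed = x$config$seed,
                 budget = x$budget,
                 generated = unname(x$counts[["generated"]]),
                 post_positive = unname(x$counts[["post_positive"]]),
                 released = unname(x$counts[["released"]]),
                 rescued = x$rescued, outcome = x$outcome,
                 n_events = nrow(x$events))
}

#' Plot per-stage repertoire composition
#'
#' Bar chart of motif counts by selection stage, filled by motif form —
#' the visual of "positive selection removes input-change and self motifs,
#' negative selection removes program-change motifs".
#'
#' @param object a `gtp_repertoire`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gtp_repertoire
#' @export
autoplot.gtp_repertoire <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = c("generated", "post_positive", "released"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, fill = .data$form)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "selection stage", y = "receptor motifs", fill = "motif form",
                  title = "Thymic selection of V(D)J receptor motifs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the world's tissue phenotypes over an event log
#'
#' Timeline of events by tissue, coloured by event type.
#'
#' @param object a `scenario_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot scenario_report
#' @export
autoplot.scenario_report <- function(object, ...) {
  ev <- object$events
  if (nrow(ev) == 0L) {
    ev <- tibble::tibble(time = integer(0), tissue = character(0), type = character(0))
  }
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$time, y = .data$tissue,
                                   colour = .data$type)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "time step", y = "tissue", colour = "event",
                  title = paste0("Scenario '", object$config$scenario,
                                 "': ", object$outcome)) +
    ggplot2::theme_minimal()
}
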