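#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evolution result
#'
#' @param x An `evolution_result`.
#' @param ... Unused.
#' @return The per-generation history: generation, best and mean
#'   fitness, best novelty, archive size.
#' @export
tidy.evolution_result <- function(x, ...) x$history

#' @rdname tidy.evolution_result
#' @return For `glance()`: a one-row summary of the run.
#' @export
glance.evolution_result <- function(x, ...) {
  tibble::tibble(encoding = x$encoding,
                 generations = x$generations,
                 converged = x$converged,
                 best_fitness = x$champion$fitness,
                 archive_size = x$archive_size,
                 n_train = nrow(x$sets))
}

#' @rdname tidy.evolution_result
#' @export
tidy.gla_score <- function(x, ...) x$per_repeat

#' @rdname tidy.evolution_result
#' @export
glance.gla_score <- function(x, ...) {
  tibble::tibble(set_level = x$set_level,
                 association_level = x$association_level,
                 n_sets = x$n_sets, n_repeats = x$n_repeats)
}

#' Plot the fitness trajectory of an evolution run
#'
#' @param object An `evolution_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per generation.
#' @export
autoplot.evolution_result <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("best_fitness", "mean_fitness"),
                           names_to = "statistic", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(.data$generation, .data$fitness,
                                  color = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "lifetime learning fitness",
                  color = NULL,
                  title = sprintf("%s encoding", object$encoding)) +
    ggplot2::theme_minimal()
}

#' Plot a series: GLA score against training-set size per encoding
#'
#' @param object A `plastevo_series` tibble from [run_series()].
#' @param measure Column to plot (default `"gla_set"`).
#' @param ... Unused.
#' @return A ggplot with one box per (encoding, n_train) cell.
#' @export
autoplot.plastevo_series <- function(object, measure = "gla_set", ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$n_train),
                                  .data[[measure]],
                                  fill = .data$encoding)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "evolutionary training-set size", y = measure) +
    ggplot2::theme_minimal()
}
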