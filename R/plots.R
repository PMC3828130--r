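#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point
#'   geom_errorbar labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a bound-complex time series
#'
#' @param object A `cg_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$count)) +
    geom_line(colour = "#2b6cb0") +
    labs(x = "time (tau)", y = "bound complexes") +
    theme_minimal()
}

#' Plot a TER-abundance selectivity sweep
#'
#' Relative increment of equilibrium activity complexes versus the number of
#' targeting receptors.
#'
#' @param object A `cg_ter_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_ter_sweep <- function(object, ...) {
  base <- object$c_eq_mean[object$n_ter == 0]
  object$inc_sd <- 100 * object$c_eq_sd / (base * sqrt(object$n_replicates))
  ggplot(object, aes(x = .data$n_ter, y = .data$relative_increment)) +
    geom_line(colour = "grey50") +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$relative_increment - .data$inc_sd,
                      ymax = .data$relative_increment + .data$inc_sd),
                  width = 0) +
    labs(x = "number of targeting receptors",
         y = "increment in activity complexes (%)") +
    theme_minimal()
}

#' Plot a linker-length sweep
#'
#' Effective affinity rate versus linker mean extension, one line per
#' receptor spacing.
#'
#' @param object A `cg_linker_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cg_linker_sweep <- function(object, ...) {
  object$spacing <- factor(signif(object$receptor_distance, 3))
  ggplot(object, aes(x = .data$linker_length, y = .data$kon_eff,
                     colour = .data$spacing, group = .data$spacing)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$kon_eff - .data$kon_stderr,
                      ymax = .data$kon_eff + .data$kon_stderr), width = 0) +
    labs(x = "linker mean extension (sigma)",
         y = "effective kon (sigma^3/tau)", colour = "receptor distance d") +
    theme_minimal()
}
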