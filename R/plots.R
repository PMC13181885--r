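#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_col geom_errorbar geom_text labs theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Ordination plot
#'
#' Samples on the first two principal coordinates, colored by the group
#' extracted from the sample id (`treatment_year_replicate` convention)
#' or supplied explicitly.
#'
#' @param object An `ms_pcoa`.
#' @param groups Optional vector of group labels per sample.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ms_pcoa <- function(object, groups = NULL, ...) {
  pts <- object$points
  if (ncol(pts) < 3) abort("need at least two axes to plot",
                           class = "ms_domain_error")
  pts$group <- groups %||% sub("_.*$", "", pts$sample)
  ggplot(pts, aes(x = .data$Axis1, y = .data$Axis2,
                  color = .data$group)) +
    geom_point(size = 2) +
    labs(x = sprintf("PCoA1 (%.1f%%)", 100 * object$prop_explained[1]),
         y = sprintf("PCoA2 (%.1f%%)", 100 * object$prop_explained[2]),
         color = NULL) +
    theme_minimal()
}

#' Zi-Pi keystone plot
#'
#' Within-module degree z-score against participation coefficient with
#' the role-threshold guides; points colored by role.
#'
#' @param roles Output of [zipi()].
#' @param zi_threshold,pi_threshold Guide positions (defaults 2.5, 0.62).
#' @return A ggplot.
#' @export
plot_zipi <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  ggplot(roles, aes(x = .data$pi, y = .data$zi, color = .data$role)) +
    geom_point(size = 2, alpha = 0.8) +
    geom_hline(yintercept = zi_threshold, linetype = 2) +
    geom_vline(xintercept = pi_threshold, linetype = 2) +
    labs(x = "participation coefficient (Pi)",
         y = "within-module degree z-score (Zi)", color = NULL) +
    theme_minimal()
}

#' Duncan letters bar plot
#'
#' Group means with significance letters above the bars.
#'
#' @param object An `ms_duncan`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ms_duncan <- function(object, ...) {
  g <- object$groups
  ggplot(g, aes(x = stats::reorder(.data$group, -.data$mean),
                y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_text(aes(label = .data$letters),
              vjust = -0.5) +
    labs(x = NULL, y = "group mean") +
    theme_minimal()
}

#' Group means with standard errors
#'
#' Bar chart of per-treatment means with SE bars for one variable, split
#' by year.
#'
#' @param summary Group-summary tibble (`variable, year, treatment, mean,
#'   se`).
#' @param variable Which variable to plot.
#' @return A ggplot.
#' @export
plot_group_means <- function(summary, variable) {
  d <- dplyr::filter(tibble::as_tibble(summary),
                     .data$variable == !!variable)
  if (nrow(d) == 0) abort("variable not present in summary",
                          class = "ms_domain_error")
  ggplot(d, aes(x = .data$treatment, y = .data$mean,
                fill = factor(.data$year))) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  position = position_dodge(width = 0.8), width = 0.2) +
    labs(x = NULL, y = variable, fill = "year") +
    theme_minimal()
}
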