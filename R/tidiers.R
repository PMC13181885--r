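#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Duncan multiple-range result
#'
#' @param x An `ms_duncan` object.
#' @param ... Unused.
#' @return Tibble `group, mean, n, letters` sorted by descending mean.
#' @exportS3Method generics::tidy
tidy.ms_duncan <- function(x, ...) {
  x$groups
}

#' One-row summary of a Duncan result
#'
#' @param x An `ms_duncan` object.
#' @param ... Unused.
#' @return Tibble `f, p_value, mse, df_among, df_within, alpha`.
#' @exportS3Method generics::glance
glance.ms_duncan <- function(x, ...) {
  tibble::tibble(f = x$f, p_value = x$p_value, mse = x$mse,
                 df_among = x$df[1], df_within = x$df[2], alpha = x$alpha)
}

#' Tidy a PERMANOVA result
#'
#' @param x An `ms_permanova` object.
#' @param ... Unused.
#' @return Tibble with among/within sums of squares and the test.
#' @exportS3Method generics::tidy
tidy.ms_permanova <- function(x, ...) {
  tibble::tibble(term = c("among", "within"),
                 df = as.integer(x$df),
                 sum_sq = c(x$ss_among, x$ss_within),
                 statistic = c(x$f, NA_real_),
                 p_value = c(x$p_value, NA_real_))
}

#' One-row summary of a PERMANOVA result
#'
#' @param x An `ms_permanova` object.
#' @param ... Unused.
#' @return Tibble `statistic, p_value, n_perm, seed`.
#' @exportS3Method generics::glance
glance.ms_permanova <- function(x, ...) {
  tibble::tibble(statistic = x$f, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed)
}

#' Tidy a PCoA result
#'
#' @param x An `ms_pcoa` object.
#' @param ... Unused.
#' @return The sample-coordinates tibble.
#' @exportS3Method generics::tidy
tidy.ms_pcoa <- function(x, ...) {
  x$points
}

#' One-row summary of a PCoA result
#'
#' @param x An `ms_pcoa` object.
#' @param ... Unused.
#' @return Tibble with axis count and variance bookkeeping.
#' @exportS3Method generics::glance
glance.ms_pcoa <- function(x, ...) {
  tibble::tibble(axes = ncol(x$points) - 1L,
                 prop_axis1 = x$prop_explained[1],
                 prop_axis2 = if (length(x$prop_explained) > 1)
                   x$prop_explained[2] else NA_real_,
                 negative_eig = x$negative_eig)
}

#' Tidy a variance-partitioning result
#'
#' @param x An `ms_vpa` object.
#' @param ... Unused.
#' @return Tibble `component, adj_r2` including the residual row.
#' @exportS3Method generics::tidy
tidy.ms_vpa <- function(x, ...) {
  dplyr::bind_rows(x$fractions,
                   tibble::tibble(component = "residual",
                                  adj_r2 = x$residual))
}

#' Tidy a co-occurrence network
#'
#' @param x An `ms_network` object.
#' @param ... Unused.
#' @return The edge tibble.
#' @exportS3Method generics::tidy
tidy.ms_network <- function(x, ...) {
  x$edges
}

#' One-row topology summary of a network
#'
#' @param x An `ms_network` object.
#' @param ... Passed to [topology()].
#' @return One-row tibble of topology metrics.
#' @exportS3Method generics::glance
glance.ms_network <- function(x, ...) {
  topology(x, ...)
}

#' Tidy a fold-change report
#'
#' @param x An `ms_report` object.
#' @param ... Unused.
#' @return The per-variable/year ratio tibble.
#' @exportS3Method generics::tidy
tidy.ms_report <- function(x, ...) {
  x$ratios
}
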