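#' Min-max linear scoring of an indicator over its pool
#'
#' Scores x against the highest (H) and lowest (L) values of the pool:
#' `(x - L)/(H - L)` when more of the indicator is better, `(H - x)/(H - L)`
#' when less is better; results lie in `[0, 1]` for x inside the pool range.
#'
#' @param x Numeric values to score.
#' @param direction `"more_is_better"` or `"less_is_better"`.
#' @param pool Values over which H and L are taken (defaults to `x`).
#' @param constant One of `"midpoint"` (score 0.5 with a warning, default)
#'   or `"error"`, applied when H equals L.
#' @return Numeric scores.
#' @export
minmax_score <- function(x, direction = c("more_is_better",
                                          "less_is_better"),
                         pool = x, constant = c("midpoint", "error")) {
  direction <- match.arg(direction)
  constant <- match.arg(constant)
  if (length(pool) < 2) abort("scoring pool needs at least 2 values",
                              class = "ms_domain_error")
  H <- max(pool)
  L <- min(pool)
  if (H == L) {
    if (constant == "error") {
      abort("constant indicator: H equals L over the pool; drop the
indicator or score it 0.5", class = "ms_constant_indicator")
    }
    warn("constant indicator over the pool; assigning score 0.5")
    return(rep(0.5, length(x)))
  }
  s <- if (direction == "more_is_better") (x - L) / (H - L)
       else (H - x) / (H - L)
  s
}

default_directions <- function(indicators) {
  # All ten default indicators score as more-is-better, including pH:
  # on these alkaline soils the mineral control keeps the highest pH and
  # the published index assigns it a positive pH contribution.
  stats::setNames(rep("more_is_better", length(indicators)), indicators)
}

# Score every indicator for every sample, pooling H/L per year (default)
# or globally.
score_soil_indicators <- function(soil, indicators, directions, pool) {
  long <- tidyr::pivot_longer(soil[, c(ms_key_cols, indicators)],
                              all_of(indicators),
                              names_to = "variable", values_to = "value")
  pool_vars <- if (pool == "per_year") c("variable", "year") else "variable"
  long <- dplyr::group_by(long, across(all_of(pool_vars)))
  long <- dplyr::mutate(
    long, score = minmax_score(.data$value,
                               direction = directions[[unique(.data$variable)]],
                               pool = .data$value))
  dplyr::ungroup(long)
}

#' Radar-area soil quality index
#'
#' Each indicator is min-max scored over its pool (per year by default),
#' then combined as `SQI = 0.5 * sum(S^2) * sin(2*pi/n)` with n the number
#' of indicators — the area of the radar polygon spanned by the scores.
#' The formula degenerates for n <= 2 (`sin(2*pi/n) <= 0`), which is
#' rejected. Bounds: `0 <= SQI <= 0.5 * n * sin(2*pi/n)`.
#'
#' @param soil Replicate-level soil tibble.
#' @param indicators Indicator columns (default the ten physicochemical
#'   variables pH, SP, TC, TN, TP, TK, NH4, NO3, AP, AK).
#' @param directions Named vector of scoring directions per indicator;
#'   default all `"more_is_better"`.
#' @param pool `"per_year"` (default) or `"global"` H/L pooling.
#' @return Input keys plus an `SQI` column.
#' @export
compute_sqi <- function(soil, indicators = MS_SQI_INDICATORS,
                        directions = default_directions(indicators),
                        pool = c("per_year", "global")) {
  pool <- match.arg(pool)
  soil <- validate_soil_table(soil)
  n <- length(indicators)
  if (n < 3) {
    abort(sprintf("SQI needs at least 3 indicators: sin(2*pi/n) is
non-positive at n = %d", n), class = "ms_degenerate_formula")
  }
  miss <- setdiff(indicators, names(soil))
  if (length(miss) > 0) {
    abort(paste0("indicator(s) absent from table: ",
                 paste(miss, collapse = ", ")), class = "ms_schema_error")
  }
  scored <- score_soil_indicators(soil, indicators, directions, pool)
  out <- dplyr::summarise(
    dplyr::group_by(scored, across(all_of(ms_key_cols))),
    SQI = 0.5 * sum(.data$score^2) * sin(2 * pi / n), .groups = "drop")
  dplyr::left_join(soil[, ms_key_cols], out, by = ms_key_cols)
}

#' Ecological multifunctionality as averaged enzyme z-scores
#'
#' For each soil function (default the six enzyme activities CAT, INV,
#' NAG, URE, ALP, GLS), values are z-standardized over the pool (per year
#' by default, with sample SD), and EMF is the mean of the per-function
#' z-scores. By construction the mean EMF within each pool is zero, which
#' is also how the published per-year treatment means behave.
#'
#' @param soil Replicate-level soil tibble.
#' @param functions Function columns (default the six enzymes).
#' @param pool `"per_year"` (default) or `"global"` standardization pool.
#' @return Input keys plus an `EMF` column.
#' @export
compute_emf <- function(soil, functions = MS_EMF_FUNCTIONS,
                        pool = c("per_year", "global")) {
  pool <- match.arg(pool)
  soil <- validate_soil_table(soil)
  if (length(functions) < 2) {
    abort("EMF needs at least 2 functions", class = "ms_domain_error")
  }
  miss <- setdiff(functions, names(soil))
  if (length(miss) > 0) {
    abort(paste0("function(s) absent from table: ",
                 paste(miss, collapse = ", ")), class = "ms_schema_error")
  }
  long <- tidyr::pivot_longer(soil[, c(ms_key_cols, functions)],
                              all_of(functions),
                              names_to = "f", values_to = "value")
  pool_vars <- if (pool == "per_year") c("f", "year") else "f"
  long <- dplyr::group_by(long, across(all_of(pool_vars)))
  long <- dplyr::mutate(long, sdv = stats::sd(.data$value),
                        z = (.data$value - mean(.data$value)) / .data$sdv)
  long <- dplyr::ungroup(long)
  dropped <- unique(long$f[long$sdv == 0])
  if (length(dropped) > 0) {
    warn(paste0("dropping zero-variance function(s): ",
                paste(dropped, collapse = ", ")))
    long <- dplyr::filter(long, !.data$f %in% dropped)
    if (nrow(long) == 0) abort("no functions with nonzero variance",
                               class = "ms_domain_error")
  }
  out <- dplyr::summarise(
    dplyr::group_by(long, across(all_of(ms_key_cols))),
    EMF = mean(.data$z), .groups = "drop")
  dplyr::left_join(soil[, ms_key_cols], out, by = ms_key_cols)
}

#' N partial factor productivity
#'
#' Grain yield per unit of applied nitrogen, `PFP_N = Y_T / F_N`
#' (kg grain per kg N).
#'
#' @param y_t Grain yield, kg/ha (>= 0).
#' @param f_n N application rate, kg/ha (> 0; the trial applied 225).
#' @return `y_t / f_n`.
#' @export
compute_pfp <- function(y_t, f_n = 225) {
  if (any(f_n <= 0)) abort("f_n must be > 0", class = "ms_domain_error")
  if (any(y_t < 0)) abort("y_t must be >= 0", class = "ms_domain_error")
  y_t / f_n
}

#' N agronomic efficiency
#'
#' Yield gain over the unfertilized control per unit of applied nitrogen,
#' `AE_N = (Y_T - Y_0) / F_N`; may be negative if a plot underperforms
#' the control.
#'
#' @param y_t Grain yield, kg/ha.
#' @param y_0 Unfertilized-control yield, kg/ha.
#' @param f_n N application rate, kg/ha (> 0).
#' @return `(y_t - y_0) / f_n`.
#' @export
compute_aen <- function(y_t, y_0, f_n = 225) {
  if (any(f_n <= 0)) abort("f_n must be > 0", class = "ms_domain_error")
  (y_t - y_0) / f_n
}

#' Per-plot nitrogen-use-efficiency table
#'
#' @param yields Tibble `treatment, year, replicate, yield`.
#' @param y0 Tibble `year, y0` (unfertilized-control yield per year).
#' @param f_n N application rate, kg/ha.
#' @return `yields` plus `PFP_N` and `AE_N` columns.
#' @export
nue_table <- function(yields, y0, f_n = 225) {
  out <- dplyr::left_join(tibble::as_tibble(yields),
                          tibble::as_tibble(y0), by = "year")
  if (anyNA(out$y0)) abort("missing unfertilized-control yield for a year",
                           class = "ms_domain_error")
  out$PFP_N <- compute_pfp(out$yield, f_n)
  out$AE_N <- compute_aen(out$yield, out$y0, f_n)
  out$y0 <- NULL
  out
}

#' Group summary of soil indices
#'
#' Means and standard errors per (treatment, year) for any numeric
#' columns, tidy-style.
#'
#' @param data Tibble with `treatment`, `year` keys and numeric columns.
#' @param vars Columns to summarise (default all numeric non-key columns).
#' @return Tibble `variable, year, treatment, mean, se, n`.
#' @export
group_summary <- function(data, vars = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(vars)) {
    vars <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    ms_key_cols)
  }
  long <- tidyr::pivot_longer(data[, c("treatment", "year", vars)],
                              all_of(vars),
                              names_to = "variable", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$year, .data$treatment),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
}
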