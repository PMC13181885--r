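#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way ANOVA, then compares group means with Duncan's
#' procedure: means sorted descending, and two means r positions apart are
#' declared different when their difference exceeds the least significant
#' range `LSR_r = q(1 - (1 - alpha)^(r - 1), r, df) * sqrt(MSE / n_h)`,
#' with `q` the studentized-range quantile and `n_h` the harmonic mean
#' group size. Letters come from the standard sweep over the sorted means:
#' maximal runs of mutually non-different means share a letter, starting
#' at `a` for the largest mean. With zero residual variance everywhere,
#' letters group by exact equality of means.
#'
#' @param data Data frame with one measurement per row.
#' @param value Column of measurements (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param alpha Significance level (default 0.05).
#' @return An `ms_duncan` object; use [tidy()] for the per-group table.
#' @export
anova_duncan <- function(data, value, group, alpha = 0.05) {
  data <- tibble::as_tibble(data)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  tab <- table(g)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 replicates each",
          class = "ms_domain_error")
  }
  fit <- stats::aov(v ~ factor(g))
  # zero-residual input (e.g. pseudo-replicated group means) triggers a
  # harmless precision warning from anova.lm; the mse == 0 branch below
  # handles that case explicitly
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  means <- sort(tapply(v, g, mean), decreasing = TRUE)
  k <- length(means)
  n_h <- k / sum(1 / tab)   # harmonic mean group size
  if (mse <= .Machine$double.eps) {
    # degenerate: no residual noise; groups differ iff means differ
    diff_mat <- outer(means, means, function(a, b) abs(a - b) > 1e-12)
  } else {
    lsr <- vapply(2:k, function(r) {
      stats::qtukey((1 - alpha)^(r - 1), r, df_err) * sqrt(mse / n_h)
    }, numeric(1))
    diff_mat <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        r <- j - i + 1
        diff_mat[i, j] <- diff_mat[j, i] <-
          (means[i] - means[j]) > lsr[r - 1]
      }
    }
  }
  letters_vec <- range_letters(diff_mat)
  groups_tbl <- tibble::tibble(group = names(means),
                               mean = as.numeric(means),
                               n = as.numeric(tab[names(means)]),
                               letters = letters_vec)
  structure(list(groups = groups_tbl,
                 f = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 mse = mse, df = c(an[["Df"]][1], df_err),
                 alpha = alpha),
            class = "ms_duncan")
}

# Letter assignment by the descending-means sweep: for each position i
# extend the run while no pair inside [i, j] is significantly different;
# drop runs nested in earlier ones; label runs a, b, c, ...
range_letters <- function(diff_mat) {
  k <- nrow(diff_mat)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(diff_mat[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && keep[j] &&
          runs[[i]][1] >= runs[[j]][1] && runs[[i]][2] <= runs[[j]][2] &&
          !identical(runs[[i]], runs[[j]])) keep[i] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  out <- character(k)
  for (r in seq_along(runs)) {
    span <- runs[[r]][1]:runs[[r]][2]
    out[span] <- paste0(out[span], letters[r])
  }
  out
}

#' @export
print.ms_duncan <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4f, p = %.4g; Duncan letters at alpha = %g\n",
              x$f, x$p_value, x$alpha))
  print(x$groups)
  invisible(x)
}

#' Orthogonal (or any zero-sum) contrast among group means
#'
#' Estimate `sum(c_g * mean_g)` with
#' `t = estimate / sqrt(MSE * sum(c_g^2 / n_g))` on the one-way ANOVA
#' residual degrees of freedom; two-sided p.
#'
#' @param data Data frame with one measurement per row.
#' @param value Measurement column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @param coefficients Named numeric vector of contrast coefficients
#'   summing to zero, e.g. `c(NPK = 3, CM = -1, PM = -1, SM = -1)`.
#' @return Tibble `estimate, se, t, df, p_value`.
#' @export
orthogonal_contrast <- function(data, value, group, coefficients) {
  data <- tibble::as_tibble(data)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  if (abs(sum(coefficients)) > 1e-10) {
    abort("contrast coefficients must sum to zero",
          class = "ms_domain_error")
  }
  miss <- setdiff(names(coefficients), unique(g))
  if (length(miss) > 0) abort(paste0("unknown group(s) in coefficients: ",
                                     paste(miss, collapse = ", ")),
                              class = "ms_domain_error")
  fit <- stats::aov(v ~ factor(g))
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  means <- tapply(v, g, mean)[names(coefficients)]
  ns <- table(g)[names(coefficients)]
  est <- sum(coefficients * means)
  se <- sqrt(mse * sum(coefficients^2 / as.numeric(ns)))
  tval <- if (se == 0) ifelse(est == 0, 0, sign(est) * Inf) else est / se
  p <- 2 * stats::pt(-abs(tval), df = df_err)
  tibble::tibble(estimate = est, se = se, t = tval, df = df_err,
                 p_value = p)
}

#' Spearman correlation grid between two variable blocks
#'
#' Pairwise Spearman rho (average ranks for ties) between every variable
#' of `block_a` and every variable of `block_b` over aligned samples,
#' with Benjamini-Hochberg adjustment across the whole grid and the
#' conventional significance stars (* <= 0.05, ** <= 0.01, *** <= 0.001,
#' **** <= 0.0001 on adjusted p). Constant variables yield `NA` cells
#' flagged in `note`.
#'
#' @param block_a,block_b Data frames, samples in rows, variables in
#'   columns, rows aligned.
#' @return Tibble `var_a, var_b, rho, p, p_adj, stars, note`.
#' @export
spearman_matrix <- function(block_a, block_b) {
  a <- as.data.frame(block_a)
  b <- as.data.frame(block_b)
  if (nrow(a) != nrow(b)) abort("blocks must have aligned samples",
                                class = "ms_domain_error")
  if (nrow(a) < 4) abort("need >= 4 samples", class = "ms_domain_error")
  grid <- tidyr::crossing(var_a = names(a), var_b = names(b))
  res <- purrr::pmap(grid, function(var_a, var_b) {
    x <- a[[var_a]]
    y <- b[[var_b]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(var_a = var_a, var_b = var_b,
                            rho = NA_real_, p = NA_real_,
                            note = "constant variable"))
    }
    rho <- stats::cor(x, y, method = "spearman")
    n <- length(x)
    r_c <- min(max(rho, -1 + 1e-12), 1 - 1e-12)
    tstat <- r_c * sqrt((n - 2) / (1 - r_c^2))
    tibble::tibble(var_a = var_a, var_b = var_b, rho = rho,
                   p = 2 * stats::pt(-abs(tstat), df = n - 2),
                   note = NA_character_)
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$stars <- dplyr::case_when(
    is.na(out$p_adj) ~ "",
    out$p_adj <= 1e-4 ~ "****",
    out$p_adj <= 1e-3 ~ "***",
    out$p_adj <= 0.01 ~ "**",
    out$p_adj <= 0.05 ~ "*",
    TRUE ~ "")
  out[, c("var_a", "var_b", "rho", "p", "p_adj", "stars", "note")]
}

# Multivariate redundancy R^2 of a (centered) response on a predictor
# block, with Ezekiel adjustment.
rda_r2 <- function(y, x) {
  y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  x <- as.matrix(x)
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    abort("collinear predictors within a block; remove redundant
variables", class = "ms_collinear_error")
  }
  fitted <- qr.fitted(qrx, y)
  r2 <- sum(fitted^2) / sum(y^2)
  m <- ncol(x)
  n <- nrow(y)
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  list(r2 = r2, adj = adj, m = m)
}

#' Variance partitioning of community composition
#'
#' Redundancy-analysis R^2 of the (by default Hellinger-transformed)
#' composition on every subset of the named predictor groups, Ezekiel-
#' adjusted, decomposed into unique and shared fractions by
#' inclusion-exclusion. Small negative fractions (an artifact of the
#' adjustment) are reported as-is; `unique + shared + residual = 1`.
#'
#' @param response Samples-by-features matrix or data frame (community
#'   composition).
#' @param predictors Named list of data frames (samples aligned with
#'   `response`), one per predictor group.
#' @param hellinger Apply the Hellinger transform to the response
#'   (default TRUE; standard for compositional responses).
#' @return An `ms_vpa` list: `fractions` tibble (component, adj_r2),
#'   `subsets` tibble of all subset fits, `residual`.
#' @export
variance_partition <- function(response, predictors, hellinger = TRUE) {
  y <- as.matrix(response)
  if (hellinger) y <- vegan::decostand(y, method = "hellinger")
  if (is.null(names(predictors)) || any(names(predictors) == "")) {
    abort("predictor groups must be named", class = "ms_config_error")
  }
  gnames <- names(predictors)
  n_g <- length(gnames)
  if (n_g < 2) abort("need >= 2 predictor groups", class = "ms_domain_error")
  total_p <- sum(vapply(predictors, ncol, numeric(1)))
  if (nrow(y) < total_p + 2) {
    abort("too few samples for the predictor count",
          class = "ms_domain_error")
  }
  subsets <- unlist(lapply(seq_len(n_g), function(k) {
    utils::combn(gnames, k, simplify = FALSE)
  }), recursive = FALSE)
  fits <- purrr::map(subsets, function(s) {
    x <- do.call(cbind, lapply(predictors[s], as.matrix))
    rda_r2(y, x)
  })
  sub_tbl <- tibble::tibble(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj"))
  key <- function(s) paste(sort(s), collapse = "+")
  adj_lookup <- stats::setNames(
    sub_tbl$adj_r2,
    vapply(subsets, key, character(1)))
  # r_contained(V): variance attributable only to groups inside V,
  # i.e. R(all) - R(all \ V); Moebius inversion over subsets of S then
  # isolates the fraction shared by exactly the groups in S.
  r_all <- adj_lookup[[key(gnames)]]
  r_contained <- function(v) {
    if (length(v) == 0) return(0)
    rest <- setdiff(gnames, v)
    r_all - (if (length(rest) == 0) 0 else adj_lookup[[key(rest)]])
  }
  frac <- list()
  for (s in subsets) {
    val <- 0
    for (k in 0:length(s)) {
      vs <- if (k == 0) list(character(0)) else
        utils::combn(s, k, simplify = FALSE)
      for (v in vs) {
        val <- val + (-1)^(length(s) - k) * r_contained(v)
      }
    }
    frac[[key(s)]] <- val
  }
  fractions <- tibble::tibble(component = names(frac),
                              adj_r2 = unname(unlist(frac)))
  residual <- unname(1 - adj_lookup[[key(gnames)]])
  structure(list(fractions = fractions, subsets = sub_tbl,
                 residual = residual, groups = gnames),
            class = "ms_vpa")
}

#' @export
print.ms_vpa <- function(x, ...) {
  cat("variance partitioning (adjusted R^2):\n")
  print(x$fractions)
  cat(sprintf("residual: %.4f\n", x$residual))
  invisible(x)
}

# Round half away from zero to `digits`, matching printed-report style
# (base round() is banker's). A tiny epsilon counters binary
# representation error at .5 boundaries.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Fold-change report against the mineral control
#'
#' For every variable and year, the organic-over-NPK mean ratio (and, for
#' pH, the NPK-minus-organic difference), plus min-max ranges across
#' treatments and years. Ratios and differences are rounded half-up to
#' two decimals for reporting, matching the conventional printed style.
#'
#' @param summary Group-summary tibble `variable, year, treatment, mean`
#'   (e.g. [millet_table1()] or [group_summary()] output).
#' @param control Control treatment code (default `"NPK"`).
#' @return An `ms_report` list: `ratios` tibble (variable, year,
#'   treatment, ratio, difference), `ranges` tibble (variable, min_ratio,
#'   max_ratio, min_difference, max_difference).
#' @export
fold_change_report <- function(summary, control = "NPK") {
  summary <- tibble::as_tibble(summary)
  ctrl <- dplyr::filter(summary, .data$treatment == control)
  if (nrow(ctrl) == 0) abort("no control means available",
                             class = "ms_domain_error")
  ctrl <- dplyr::select(ctrl, "variable", "year", control_mean = "mean")
  organics <- dplyr::filter(summary, .data$treatment != control)
  ratios <- dplyr::inner_join(organics, ctrl, by = c("variable", "year"))
  if (nrow(ratios) < nrow(organics)) {
    abort("missing control mean for some variable-year cells",
          class = "ms_domain_error")
  }
  ratios <- dplyr::mutate(
    ratios,
    ratio = round_half_up(.data$mean / .data$control_mean, 2),
    difference = round_half_up(.data$control_mean - .data$mean, 2))
  ranges <- dplyr::summarise(
    dplyr::group_by(ratios, .data$variable),
    min_ratio = min(.data$ratio), max_ratio = max(.data$ratio),
    min_difference = min(.data$difference),
    max_difference = max(.data$difference), .groups = "drop")
  structure(list(
    ratios = ratios[, c("variable", "year", "treatment", "ratio",
                        "difference")],
    ranges = ranges, control = control),
    class = "ms_report")
}

#' @export
print.ms_report <- function(x, ...) {
  cat(sprintf("fold changes vs %s (rounded to 2 decimals):\n", x$control))
  print(x$ranges)
  invisible(x)
}
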