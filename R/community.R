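#' Alpha diversity per sample
#'
#' Observed species (count of taxa present), Shannon index
#' `-sum(p * log(p))` (natural log by default), and the Chao1 richness
#' estimator. Chao1 uses the bias-corrected form
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` by default (F1 singletons, F2
#' doubletons); the classic form `S_obs + F1^2 / (2 * F2)` is selectable
#' and falls back to the bias-corrected form when F2 = 0.
#'
#' @param counts Abundance tibble of counts, or a taxa-by-samples count
#'   matrix.
#' @param base Logarithm base for Shannon (default `exp(1)`).
#' @param chao1 `"bias_corrected"` (default) or `"classic"`.
#' @return Tibble `sample, observed, shannon, chao1`.
#' @export
alpha_diversity <- function(counts, base = exp(1),
                            chao1 = c("bias_corrected", "classic")) {
  chao1 <- match.arg(chao1)
  m <- if (is.matrix(counts)) counts else {
    a <- attr(counts, "counts")
    if (!is.null(a)) a else abund_matrix(counts)
  }
  if (any(m < 0)) abort("counts must be non-negative",
                        class = "ms_validation_error")
  out <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (sum(x) == 0) abort(sprintf("sample '%s' has all-zero counts",
                                   colnames(m)[j]),
                           class = "ms_validation_error")
    p <- x[x > 0] / sum(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    s_obs <- sum(x > 0)
    ch <- if (chao1 == "classic" && f2 > 0) s_obs + f1^2 / (2 * f2)
          else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    tibble::tibble(sample = colnames(m)[j] %||% as.character(j),
                   observed = s_obs,
                   shannon = -sum(p * log(p, base = base)),
                   chao1 = ch)
  })
  dplyr::bind_rows(out)
}

#' Bray-Curtis dissimilarity
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` between sample rows; symmetric,
#' zero on the diagonal, in `[0, 1]` for non-negative data.
#'
#' @param x Samples-by-taxa numeric matrix (or abundance tibble, which is
#'   transposed internally).
#' @return A `stats::dist` object over samples.
#' @export
bray_curtis <- function(x) {
  m <- if (is.matrix(x)) x else t(abund_matrix(x))
  if (any(m < 0)) abort("abundances must be non-negative",
                        class = "ms_validation_error")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[which(rs == 0)[1]] %||% which(rs == 0)[1]
    abort(sprintf("sample '%s' has zero total abundance", bad),
          class = "ms_validation_error")
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / (rs[i] + rs[j])
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it.
#' Negative eigenvalues (non-Euclidean distances) are reported, never
#' silently dropped; no Lingoes/Cailliez correction is applied.
#' Proportions explained use the sum of positive eigenvalues.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of axes to return (default 2; truncated to the number
#'   of positive eigenvalues, with a warning).
#' @return An `ms_pcoa` list: `points` tibble (sample, Axis1..Axisk),
#'   `eig` all eigenvalues (non-increasing), `prop_explained`, and
#'   `negative_eig` flag.
#' @export
pcoa <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  # Gower double-centering: sweeping rows then columns of -d^2/2 already
  # restores the grand mean
  g <- -0.5 * dm^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12)
  k_avail <- length(pos)
  if (k > k_avail) {
    warn(sprintf("only %d positive axes available; returning %d",
                 k_avail, k_avail))
    k <- k_avail
  }
  pts <- if (k > 0) {
    e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(k)]), k)
  } else matrix(0, n, 0)
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  points <- tibble::as_tibble(pts, .name_repair = "minimal")
  if (k > 0) names(points) <- paste0("Axis", seq_len(k))
  points <- tibble::add_column(points, sample = labs, .before = 1)
  pos_sum <- sum(e$values[e$values > 0])
  structure(list(points = points, eig = e$values,
                 prop_explained = if (pos_sum > 0) e$values / pos_sum
                                  else rep(0, n),
                 negative_eig = any(e$values < -1e-8 * max(abs(e$values)))),
            class = "ms_pcoa")
}

#' Permutational multivariate ANOVA (one-way)
#'
#' Partitions the sum of squared distances into among- and within-group
#' components and forms the pseudo-F statistic
#' `F = (SS_A / (a - 1)) / (SS_W / (N - a))`. Significance comes from
#' random permutations of the group labels:
#' `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`, so p is bounded below
#' by `1 / (n_perm + 1)`. Deterministic under `seed`.
#'
#' @param d A `dist` object over samples.
#' @param groups Group labels aligned with the distance object.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (required: permutation p-values must be
#'   reproducible).
#' @param exhaustive Enumerate all label permutations instead of sampling
#'   (only sensible for tiny n).
#' @return An `ms_permanova` list: `f`, `p_value`, `n_perm`, `seed`,
#'   `ss_among`, `ss_within`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed, exhaustive = FALSE) {
  if (missing(seed) && !exhaustive) {
    abort("permanova requires an explicit seed", class = "ms_config_error")
  }
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) abort("groups length must match distance size",
                                 class = "ms_domain_error")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 samples each",
          class = "ms_domain_error")
  }
  if (!exhaustive && n_perm < 1) abort("n_perm must be >= 1",
                                       class = "ms_domain_error")
  d2 <- as.matrix(d)^2
  a <- length(tab)
  f_stat <- function(g) {
    ssw <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sst <- sum(d2) / (2 * n)
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  if (exhaustive) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(ix) f_stat(groups[ix]))
    # observed ordering is one of the enumerated permutations
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- nrow(perms)
    seed <- NA_integer_
  } else {
    set.seed(seed)
    f_perm <- replicate(n_perm, f_stat(sample(groups)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(f = f_obs, p_value = p, n_perm = n_perm, seed = seed,
                 ss_among = sum(d2) / (2 * n) -
                   sum(vapply(unique(groups), function(lev) {
                     idx <- which(groups == lev)
                     sum(d2[idx, idx]) / (2 * length(idx))
                   }, numeric(1))),
                 ss_within = sum(vapply(unique(groups), function(lev) {
                   idx <- which(groups == lev)
                   sum(d2[idx, idx]) / (2 * length(idx))
                 }, numeric(1))),
                 df = c(among = a - 1, within = n - a)),
            class = "ms_permanova")
}

# All permutations of seq_len(n) as rows (n! grows fast; guard small n).
all_permutations <- function(n) {
  if (n > 8) abort("exhaustive enumeration limited to n <= 8",
                   class = "ms_domain_error")
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
  unname(out)
}

#' @export
print.ms_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$f, x$df[1], x$df[2], x$p_value, x$n_perm))
  invisible(x)
}

#' @export
print.ms_pcoa <- function(x, ...) {
  k <- ncol(x$points) - 1
  cat(sprintf("PCoA: %d axes returned; first axes explain %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$prop_explained[seq_len(k)]),
                    collapse = ", ")))
  if (x$negative_eig) cat("note: negative eigenvalues present\n")
  invisible(x)
}
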