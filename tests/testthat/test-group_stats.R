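test_that("studentized-range quantiles reproduce published Duncan
          critical values", {
  # classical table excerpt (alpha = 0.05, error df = 10): significant
  # ranges for p = 2, 3, 4 means
  q <- vapply(2:4, function(p) {
    stats::qtukey((1 - 0.05)^(p - 1), p, 10)
  }, numeric(1))
  expect_equal(round(q, 3), c(3.151, 3.293, 3.376))
})

test_that("Duncan letters behave on degenerate and extreme groups", {
  d_same <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                           y = rep(c(5, 5), each = 3))
  r <- anova_duncan(d_same, y, g)
  expect_equal(unique(generics::tidy(r)$letters), "a")

  set.seed(1)
  d_far <- tibble::tibble(g = rep(c("lo", "hi"), each = 3),
                          y = c(rnorm(3, 0, 0.1), rnorm(3, 100, 0.1)))
  r2 <- anova_duncan(d_far, y, g)
  td <- generics::tidy(r2)
  expect_equal(td$letters, c("a", "b"))
  expect_equal(td$group, c("hi", "lo"))
  expect_error(anova_duncan(d_far[c(1, 4), ], y, g),
               class = "ms_domain_error")
})

test_that("Duncan letters equal an exhaustive pairwise-range oracle", {
  set.seed(19)
  for (rep in 1:5) {
    k <- 4
    n <- 3
    mu <- sample(c(0, 0.5, 2, 8), k)
    d <- tibble::tibble(
      g = rep(letters[1:k], each = n),
      y = rnorm(k * n, rep(mu, each = n), 1))
    res <- anova_duncan(d, y, g, alpha = 0.05)
    td <- generics::tidy(res)

    # oracle: independent pairwise range tests and letter construction
    fit <- stats::aov(y ~ factor(g), data = d)
    mse <- stats::anova(fit)[["Mean Sq"]][2]
    dfe <- stats::anova(fit)[["Df"]][2]
    means <- sort(tapply(d$y, d$g, mean), decreasing = TRUE)
    sig <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        p <- j - i + 1
        crit <- stats::qtukey(0.95^(p - 1), p, dfe) * sqrt(mse / n)
        sig[i, j] <- sig[j, i] <- means[i] - means[j] > crit
      }
    }
    # groups sharing a letter must be pairwise non-significant and
    # letter order must follow the mean order
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        share <- any(strsplit(td$letters[i], "")[[1]] %in%
                       strsplit(td$letters[j], "")[[1]])
        expect_equal(share, !sig[i, j],
                     label = sprintf("pair %d-%d share letters", i, j))
      }
    }
  }
})

test_that("higher means never get strictly later letters", {
  set.seed(29)
  for (rep in 1:10) {
    d <- tibble::tibble(g = rep(letters[1:4], each = 3),
                        y = rnorm(12, rep(runif(4, 0, 6), each = 3)))
    td <- generics::tidy(anova_duncan(d, y, g))
    first_letter <- substr(td$letters, 1, 1)
    expect_true(all(diff(match(first_letter, letters)) >= 0))
  }
})

test_that("orthogonal contrasts match the closed-form t", {
  d_eq <- tibble::tibble(g = rep(c("NPK", "CM", "PM", "SM"), each = 3),
                         y = rep(10, 12) + rep(c(0, 1e-9, -1e-9), 4))
  r <- orthogonal_contrast(d_eq, y, g,
                           c(NPK = 3, CM = -1, PM = -1, SM = -1))
  expect_equal(r$estimate, 0, tolerance = 1e-6)
  expect_gt(r$p_value, 0.99)

  set.seed(10)
  d <- tibble::tibble(
    g = rep(c("NPK", "CM", "PM", "SM"), each = 3),
    y = c(rnorm(3, 10, 0.01), rnorm(9, 12, 0.01)))
  r2 <- orthogonal_contrast(d, y, g,
                            c(NPK = 3, CM = -1, PM = -1, SM = -1))
  expect_equal(r2$estimate, -6, tolerance = 0.05)
  expect_lt(r2$p_value, 0.01)
  expect_equal(r2$df, 8)

  # scale invariance: doubling the data doubles the estimate, not t or p
  d2 <- d
  d2$y <- 2 * d2$y
  r3 <- orthogonal_contrast(d2, y, g,
                            c(NPK = 3, CM = -1, PM = -1, SM = -1))
  expect_equal(r3$estimate, 2 * r2$estimate, tolerance = 1e-10)
  expect_equal(r3$t, r2$t, tolerance = 1e-10)
  expect_equal(r3$p_value, r2$p_value, tolerance = 1e-10)

  expect_error(orthogonal_contrast(d, y, g, c(NPK = 1, CM = 1)),
               class = "ms_domain_error")
})

test_that("Spearman grids handle monotone maps, ties and constants", {
  x <- c(-2, -1, 0.5, 1, 2, 3)
  a <- data.frame(x = x)
  b <- data.frame(cube = x^3, neg = -x, const = rep(1, 6))
  g <- spearman_matrix(a, b)
  expect_equal(g$rho[g$var_b == "cube"], 1)
  expect_equal(g$rho[g$var_b == "neg"], -1)
  expect_true(is.na(g$rho[g$var_b == "const"]))
  expect_equal(g$note[g$var_b == "const"], "constant variable")

  tie <- spearman_matrix(data.frame(x = c(1, 2, 2, 3)),
                         data.frame(y = c(1, 3, 2, 4)))
  # average ranks: x -> 1, 2.5, 2.5, 4; y -> 1, 3, 2, 4
  expect_equal(tie$rho, 1.5 / sqrt(1.5 * 5 / 3), tolerance = 1e-12)

  expect_error(spearman_matrix(data.frame(x = 1:3), data.frame(y = 1:3)),
               class = "ms_domain_error")
})

test_that("BH adjustment preserves the raw p-value ordering", {
  set.seed(6)
  a <- as.data.frame(matrix(rnorm(10 * 6), nrow = 10))
  g <- spearman_matrix(a, a)
  g <- g[!is.na(g$p), ]
  ord <- order(g$p)
  expect_true(all(diff(g$p_adj[ord]) >= -1e-12))
})

test_that("variance partitioning recovers orthogonal and perfect-fit
          designs", {
  set.seed(33)
  n <- 24
  x1 <- scale(rnorm(n))
  x2 <- scale(stats::resid(lm(rnorm(n) ~ x1)))  # orthogonal to x1
  y <- matrix(2 * x1 + rnorm(n, 0, 0.3), ncol = 1)
  vp <- variance_partition(y, list(A = data.frame(a = x1),
                                   B = data.frame(b = x2)),
                           hellinger = FALSE)
  td <- generics::tidy(vp)
  shared <- td$adj_r2[td$component == "A+B"]
  expect_lt(abs(shared), 0.05)
  expect_gt(td$adj_r2[td$component == "A"], 0.9)
  expect_lt(td$adj_r2[td$component == "B"], 0.05)
  # fractions sum to one with the residual
  expect_equal(sum(td$adj_r2), 1, tolerance = 1e-9)

  # exact linear map: everything is explained, essentially all of it
  # uniquely by A (the B-only fit contributes adjustment noise only)
  y2 <- cbind(as.numeric(x1), as.numeric(2 * x1))
  vp2 <- variance_partition(y2, list(A = data.frame(a = x1),
                                     B = data.frame(b = x2)),
                            hellinger = FALSE)
  td2 <- generics::tidy(vp2)
  expect_gt(td2$adj_r2[td2$component == "A"], 0.95)
  expect_lt(abs(td2$adj_r2[td2$component == "B"]), 0.1)
  expect_equal(td2$adj_r2[td2$component == "residual"], 0,
               tolerance = 1e-9)
})

test_that("three-group variance partitioning equals brute-force
          inclusion-exclusion and vegan::varpart", {
  set.seed(44)
  n <- 30
  xa <- data.frame(a1 = rnorm(n), a2 = rnorm(n))
  xb <- data.frame(b1 = rnorm(n))
  xc <- data.frame(c1 = rnorm(n))
  comp <- abs(matrix(rnorm(n * 5, 5), ncol = 5))
  comp[, 1] <- comp[, 1] + 3 * xa$a1
  comp <- abs(comp)
  vp <- variance_partition(comp, list(A = xa, B = xb, C = xc))

  # brute force: adjusted R^2 of every subset via lm on the Hellinger
  # response, then explicit inclusion-exclusion
  h <- vegan::decostand(comp, "hellinger")
  hc <- scale(h, center = TRUE, scale = FALSE)
  adj <- function(x) {
    x <- as.matrix(x)
    f <- lm(hc ~ x)
    r2 <- 1 - sum(stats::resid(f)^2) / sum(hc^2)
    1 - (1 - r2) * (n - 1) / (n - ncol(x) - 1)
  }
  rA <- adj(xa); rB <- adj(xb); rC <- adj(xc)
  rAB <- adj(cbind(xa, xb)); rAC <- adj(cbind(xa, xc))
  rBC <- adj(cbind(xb, xc)); rABC <- adj(cbind(xa, xb, xc))
  want <- c(
    A = rABC - rBC, B = rABC - rAC, C = rABC - rAB,
    `A+B` = rAC + rBC - rC - rABC,
    `A+C` = rAB + rBC - rB - rABC,
    `B+C` = rAB + rAC - rA - rABC,
    `A+B+C` = rA + rB + rC - rAB - rAC - rBC + rABC)
  got <- stats::setNames(vp$fractions$adj_r2, vp$fractions$component)
  expect_equal(got[names(want)], want, tolerance = 1e-10)
  expect_equal(vp$residual, 1 - rABC, tolerance = 1e-10)

  # unique fractions agree with vegan::varpart
  ref <- vegan::varpart(comp, xa, xb, xc, transfo = "hel")
  indfract <- ref$part$indfract
  expect_equal(unname(got["A"]), indfract$Adj.R.square[1],
               tolerance = 1e-6)
  expect_equal(unname(got["B"]), indfract$Adj.R.square[2],
               tolerance = 1e-6)
  expect_equal(unname(got["C"]), indfract$Adj.R.square[3],
               tolerance = 1e-6)

  # order of predictor groups is irrelevant
  vp_r <- variance_partition(comp, list(C = xc, B = xb, A = xa))
  got_r <- stats::setNames(vp_r$fractions$adj_r2,
                           vp_r$fractions$component)
  expect_equal(unname(got_r["A"]), unname(got["A"]), tolerance = 1e-12)
  expect_equal(unname(got_r["A+B+C"]), unname(got["A+B+C"]),
               tolerance = 1e-12)
})

test_that("variance partitioning rejects collinear blocks", {
  n <- 20
  x <- rnorm(n)
  expect_error(
    variance_partition(matrix(abs(rnorm(n * 2)), ncol = 2),
                       list(A = data.frame(a = x, a2 = 2 * x),
                            B = data.frame(b = rnorm(n)))),
    class = "ms_collinear_error")
})

test_that("fold-change report reproduces trivial and published ranges", {
  flat <- tidyr::crossing(variable = c("pH", "TC"), year = 2022L,
                          treatment = c("NPK", "CM", "PM", "SM"))
  flat$mean <- 5
  rep_flat <- fold_change_report(flat)
  expect_true(all(rep_flat$ratios$ratio == 1))
  expect_true(all(rep_flat$ratios$difference == 0))

  rep1 <- fold_change_report(millet_table1())
  rg <- rep1$ranges
  expect_equal(rg$max_ratio[rg$variable == "SQI"], 4.73)
  expect_equal(rg$min_ratio[rg$variable == "SQI"], 2.85)
  expect_equal(rg$max_difference[rg$variable == "pH"], 0.26)
  expect_equal(rg$min_difference[rg$variable == "pH"], 0.05)

  expect_error(fold_change_report(flat[flat$treatment != "NPK", ]),
               class = "ms_domain_error")
})

test_that("report rounding is half-up at two decimals", {
  expect_equal(milletsoil:::round_half_up(c(1.005, 2.675, -1.005)),
               c(1.01, 2.68, -1.01))
})
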