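test_that("abundance filtering honors kingdom thresholds", {
  m <- cbind(s1 = c(0.007, 0.003, 0.99), s2 = c(0.005, 0.005, 0.99))
  tbl <- abund_from_matrix(m, taxa = c("A|keep", "A|drop", "A|big"),
                           kingdom = "bacteria")
  kept <- filter_taxa(tbl)   # means: 0.6%, 0.4%, 99%
  expect_setequal(kept$taxon, c("A|keep", "A|big"))

  arch <- abund_from_matrix(cbind(s1 = c(2e-4, 0.9998),
                                  s2 = c(2e-4, 0.9998)),
                            taxa = c("T|rare", "T|big"),
                            kingdom = "archaea")
  expect_true("T|rare" %in% filter_taxa(arch)$taxon)  # 0.02% > 0.01%

  none <- abund_from_matrix(cbind(s1 = c(0.001, 0.999)),
                            taxa = c("A|x", "A|y"), kingdom = "bacteria")
  expect_error(filter_taxa(none, threshold = 0.9999),
               class = "ms_empty_network")
  no_kingdom <- abund_from_matrix(m)
  attr(no_kingdom, "kingdom") <- NULL
  expect_error(filter_taxa(no_kingdom), class = "ms_config_error")
})

test_that("perfectly concordant taxa produce a positive unit edge", {
  m <- rbind(c(1, 2, 3, 4, 5), c(10, 20, 30, 40, 50),
             c(5, 3, 4, 1, 2))
  net <- build_network(abund_from_matrix(m / sum(m)), r_min = 0.9,
                       alpha = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$rho, 1)
  expect_equal(net$edges$sign, "positive")
})

test_that("edge sets equal a brute-force cor.test enumeration on a toy", {
  set.seed(23)
  m <- matrix(runif(5 * 12), nrow = 5)
  tbl <- abund_from_matrix(m, taxa = sprintf("P|t%d", 1:5))
  net <- build_network(tbl, r_min = 0.3, alpha = 0.4)
  # oracle: loop over all pairs with cor + t-distribution p, then BH
  pairs <- t(utils::combn(5, 2))
  rho <- p <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rho[i] <- cor(m[pairs[i, 1], ], m[pairs[i, 2], ],
                  method = "spearman")
    tt <- rho[i] * sqrt((12 - 2) / (1 - rho[i]^2))
    p[i] <- 2 * pt(-abs(tt), 10)
  }
  padj <- p.adjust(p, "BH")
  keep <- abs(rho) >= 0.3 & padj < 0.4
  want <- sprintf("P|t%d--P|t%d", pairs[keep, 1], pairs[keep, 2])
  got <- sprintf("%s--%s", net$edges$from, net$edges$to)
  expect_setequal(got, want)
  expect_equal(sort(net$edges$rho), sort(rho[keep]), tolerance = 1e-12)
})

test_that("constant taxa are excluded with a warning", {
  m <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(4, 3, 2, 1))
  expect_warning(net <- build_network(abund_from_matrix(m), r_min = 0.5,
                                      alpha = 1),
                 "constant")
  expect_equal(nrow(net$nodes), 2)
})

test_that("topology metrics match hand computations", {
  k4 <- network_from_edges(
    expand.grid(from = paste0("n", 1:4), to = paste0("n", 1:4),
                stringsAsFactors = FALSE) |>
      dplyr::filter(from < to),
    nodes = paste0("n", 1:4))
  t4 <- topology(k4)
  expect_equal(t4$density, 1)
  expect_equal(t4$average_degree, 3)
  expect_equal(t4$average_path_length, 1)

  two <- network_from_edges(
    data.frame(from = c("a", "c"), to = c("b", "d")),
    nodes = letters[1:4])
  t2 <- topology(two)
  expect_equal(t2$density, 1 / 3, tolerance = 1e-12)
  expect_equal(t2$average_degree, 1)
  expect_equal(t2$average_path_length, 1)  # connected pairs only

  empty <- network_from_edges(data.frame(from = character(),
                                         to = character()),
                              nodes = c("a", "b"))
  te <- topology(empty)
  expect_equal(te$density, 0)
  expect_true(is.nan(te$average_path_length))
  expect_true(te$path_length_connected_pairs_only)
})

test_that("adding an edge never decreases density or average degree", {
  set.seed(41)
  nodes <- paste0("n", 1:8)
  all_pairs <- t(utils::combn(nodes, 2))
  for (rep in 1:5) {
    k <- sample(2:(nrow(all_pairs) - 1), 1)
    sel <- sample(nrow(all_pairs), k)
    e1 <- data.frame(from = all_pairs[sel[-k], 1],
                     to = all_pairs[sel[-k], 2])
    e2 <- data.frame(from = all_pairs[sel, 1], to = all_pairs[sel, 2])
    t1 <- topology(network_from_edges(e1, nodes))
    t2 <- topology(network_from_edges(e2, nodes))
    expect_gte(t2$density, t1$density)
    expect_gte(t2$average_degree, t1$average_degree)
  }
})

test_that("module detection separates two cliques joined by one edge", {
  clique <- function(v) {
    p <- t(utils::combn(v, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  edges <- rbind(clique(paste0("a", 1:5)), clique(paste0("b", 1:5)),
                 data.frame(from = "a1", to = "b1"))
  net <- network_from_edges(edges, c(paste0("a", 1:5), paste0("b", 1:5)))
  mods <- detect_modules(net, seed = 1)
  expect_equal(length(unique(mods$membership)), 2)
  expect_gt(mods$modularity, 0.3)
  expect_equal(length(unique(mods$membership[paste0("a", 1:5)])), 1)
  # determinism
  mods2 <- detect_modules(net, seed = 1)
  expect_identical(mods$membership, mods2$membership)

  k5 <- network_from_edges(clique(paste0("k", 1:5)), paste0("k", 1:5))
  mk <- detect_modules(k5, seed = 1)
  expect_equal(length(unique(mk$membership)), 1)
  expect_equal(mk$modularity, 0, tolerance = 1e-12)

  empty <- network_from_edges(data.frame(from = character(),
                                         to = character()), c("a", "b"))
  expect_error(detect_modules(empty, seed = 1),
               class = "ms_empty_network")
})

test_that("Zi-Pi formulas match direct arithmetic", {
  # node x: 2 edges into module A (its own), 2 into module B
  edges <- data.frame(from = c("x", "x", "x", "x", "a1", "b1"),
                      to = c("a1", "a2", "b1", "b2", "a2", "b2"))
  nodes <- c("x", "a1", "a2", "b1", "b2")
  net <- network_from_edges(edges, nodes)
  modules <- list(membership = c(x = 1L, a1 = 1L, a2 = 1L, b1 = 2L,
                                 b2 = 2L))
  roles <- zipi(net, modules)
  x <- roles[roles$taxon == "x", ]
  expect_equal(x$pi, 1 - (0.5^2 + 0.5^2))  # 0.5
  # a2: both edges inside its own module
  expect_equal(roles$pi[roles$taxon == "a2"], 0)
})

test_that("Zi-Pi roles equal the exhaustive oracle on a 12-node graph", {
  # two 5-cliques plus two satellite connectors
  clique_pairs <- function(v) t(utils::combn(v, 2))
  a <- paste0("a", 1:5)
  b <- paste0("b", 1:5)
  edges <- rbind(
    data.frame(from = clique_pairs(a)[, 1], to = clique_pairs(a)[, 2]),
    data.frame(from = clique_pairs(b)[, 1], to = clique_pairs(b)[, 2]),
    data.frame(from = c("c1", "c1", "c2", "c2", "a1", "c2"),
               to = c("a1", "b1", "a2", "b2", "b1", "c1")))
  nodes <- c(a, b, "c1", "c2")
  net <- network_from_edges(edges, nodes)
  membership <- c(stats::setNames(rep(1L, 5), a),
                  stats::setNames(rep(2L, 5), b),
                  c1 = 1L, c2 = 2L)
  roles <- zipi(net, list(membership = membership))
  adj <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  adj <- adj[nodes, nodes]
  oracle <- zipi_oracle(adj, membership[nodes])
  expect_equal(roles$zi, oracle$zi, tolerance = 1e-12)
  expect_equal(roles$pi, oracle$pi, tolerance = 1e-12)
  expect_equal(roles$role, oracle$role)
  # roles bounded: Pi in [0, 1)
  expect_true(all(roles$pi >= 0 & roles$pi < 1))
})

test_that("Pi is invariant to module relabeling and isolated nodes are
          peripheral", {
  edges <- data.frame(from = c("x", "x"), to = c("a", "b"))
  nodes <- c("x", "a", "b", "lonely")
  net <- network_from_edges(edges, nodes)
  m1 <- list(membership = c(x = 1L, a = 1L, b = 2L, lonely = 3L))
  m2 <- list(membership = c(x = 9L, a = 9L, b = 4L, lonely = 7L))
  r1 <- zipi(net, m1)
  r2 <- zipi(net, m2)
  expect_equal(r1$pi, r2$pi, tolerance = 1e-12)
  lone <- r1[r1$taxon == "lonely", ]
  expect_equal(lone$zi, 0)
  expect_equal(lone$pi, 0)
  expect_equal(lone$role, "peripheral")
})

test_that("phylum enrichment raises that phylum's network involvement", {
  # a doubled Proteobacteria concentration under CM recruits more of the
  # phylum's taxa past the abundance filter and raises its total
  # connectivity, aggregated over replicate simulations
  prof <- symmetric_profiles()
  prof$bacteria$CM[prof$bacteria$phylum == "Proteobacteria"] <- 2
  cc <- community_config(profiles = prof)
  totals <- matrix(0, 2, 2,
                   dimnames = list(c("NPK", "CM"), c("nodes", "degsum")))
  for (seed in 1:5) {
    comms <- simulate_communities(cc, seed = seed, kingdoms = "bacteria")
    ab <- comms$bacteria
    for (trt in c("NPK", "CM")) {
      cols <- c("taxon", "phylum",
                grep(paste0("^", trt, "_"), names(ab), value = TRUE))
      sub <- ab[, cols]
      attr(sub, "kingdom") <- "bacteria"
      net <- suppressWarnings(build_network(filter_taxa(sub)))
      ok <- net$nodes$phylum == "Proteobacteria"
      totals[trt, ] <- totals[trt, ] + c(sum(ok),
                                         sum(net$nodes$degree[ok]))
    }
  }
  expect_gt(totals["CM", "nodes"], totals["NPK", "nodes"])
  expect_gt(totals["CM", "degsum"], totals["NPK", "degsum"])
})
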