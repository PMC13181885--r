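# Shared fixtures and independent oracles. Oracles are deliberately
# written in a plain, loop-heavy style, independent of the package's
# vectorized implementations.

# A tiny deterministic replicate-level soil table: 2 treatments x 1 year
# x 3 replicates with hand-picked values.
toy_soil <- function() {
  tibble::tibble(
    treatment = rep(c("NPK", "CM"), each = 3),
    year = 2022L,
    replicate = rep(1:3, 2),
    pH = c(8.7, 8.6, 8.8, 8.1, 8.0, 8.2),
    TC = c(9, 10, 11, 12, 13, 14),
    TN = c(1.5, 1.6, 1.7, 1.8, 1.9, 2.0),
    CAT = c(0.8, 0.9, 1.0, 1.1, 1.2, 1.3),
    INV = c(17, 18, 19, 20, 21, 22))
}

# Abundance tibble from a taxa x samples matrix.
abund_from_matrix <- function(m, taxa = NULL, kingdom = "bacteria") {
  taxa <- taxa %||% sprintf("PhyA|sp%02d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  tbl <- tibble::as_tibble(m, .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, taxon = taxa, .before = 1)
  attr(tbl, "kingdom") <- kingdom
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force SQI oracle: explicit loops, no shared code with compute_sqi.
sqi_oracle <- function(values_by_indicator, directions) {
  n <- length(values_by_indicator)
  n_samples <- length(values_by_indicator[[1]])
  out <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    acc <- 0
    for (i in seq_len(n)) {
      pool <- values_by_indicator[[i]]
      H <- max(pool)
      L <- min(pool)
      x <- pool[s]
      sc <- if (directions[i] == "more_is_better") (x - L) / (H - L)
            else (H - x) / (H - L)
      acc <- acc + sc^2
    }
    out[s] <- 0.5 * acc * sin(2 * pi / n)
  }
  out
}

# Exhaustive Zi-Pi oracle from an adjacency matrix and module labels.
zipi_oracle <- function(adj, modules) {
  k <- nrow(adj)
  mods <- unique(modules)
  zi <- numeric(k)
  pi_ <- numeric(k)
  k_within <- numeric(k)
  for (i in seq_len(k)) {
    k_within[i] <- sum(adj[i, modules == modules[i]])
  }
  for (i in seq_len(k)) {
    peers <- which(modules == modules[i])
    mu <- mean(k_within[peers])
    sdv <- stats::sd(k_within[peers])
    zi[i] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[i] - mu) / sdv
    ki <- sum(adj[i, ])
    if (ki == 0) {
      pi_[i] <- 0
    } else {
      acc <- 0
      for (s in mods) acc <- acc + (sum(adj[i, modules == s]) / ki)^2
      pi_[i] <- 1 - acc
    }
  }
  role <- character(k)
  for (i in seq_len(k)) {
    role[i] <- if (zi[i] > 2.5 && pi_[i] > 0.62) "network hub"
      else if (zi[i] > 2.5) "module hub"
      else if (pi_[i] > 0.62) "connector"
      else "peripheral"
  }
  list(zi = zi, pi = pi_, role = role)
}

# Minimal ms_network wrapper around an explicit edge list, for topology
# and Zi-Pi tests on hand-built graphs.
network_from_edges <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  if (nrow(edges) > 0) {
    igraph::E(g)$weight <- edges$weight %||% rep(1, nrow(edges))
    igraph::E(g)$sign <- edges$sign %||% rep("positive", nrow(edges))
  }
  ed <- tibble::as_tibble(edges)
  if (nrow(ed) > 0 && !"sign" %in% names(ed)) ed$sign <- "positive"
  if (nrow(ed) > 0 && !"rho" %in% names(ed)) ed$rho <- 1
  structure(list(
    nodes = tibble::tibble(taxon = nodes, phylum = NA_character_,
                           degree = as.numeric(igraph::degree(g)[nodes])),
    edges = ed, graph = g, r_min = 0, alpha = 1, kingdom = "bacteria"),
    class = "ms_network")
}

# Phylum profiles with identical concentrations for every treatment
# (community null model).
symmetric_profiles <- function() {
  prof <- milletsoil:::default_phylum_profiles()
  for (k in names(prof)) prof[[k]][, c("NPK", "CM", "PM", "SM")] <- 1
  prof
}
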