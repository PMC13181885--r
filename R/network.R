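# Kingdom-specific mean relative-abundance thresholds used before
# network construction: 0.5% for bacteria and fungi, 0.01% for archaea.
MS_FILTER_THRESHOLDS <- c(bacteria = 0.005, fungi = 0.005,
                          archaea = 1e-4)

#' Filter taxa by mean relative abundance
#'
#' Retains taxa whose mean relative abundance across the table's samples
#' exceeds the kingdom threshold (bacteria/fungi 0.5%, archaea 0.01%).
#'
#' @param abund Relative-abundance tibble (attribute `kingdom` used for
#'   the default threshold).
#' @param threshold Override the abundance threshold (proportion).
#' @return Filtered abundance tibble; errors if nothing survives.
#' @export
filter_taxa <- function(abund, threshold = NULL) {
  abund <- validate_abundance_table(abund)
  kingdom <- attr(abund, "kingdom")
  if (is.null(threshold)) {
    if (is.null(kingdom) || !kingdom %in% names(MS_FILTER_THRESHOLDS)) {
      abort("no kingdom attribute: supply `threshold` explicitly",
            class = "ms_config_error")
    }
    threshold <- MS_FILTER_THRESHOLDS[[kingdom]]
  }
  samples <- setdiff(names(abund), c("taxon", "phylum"))
  mean_ra <- rowMeans(as.matrix(abund[, samples]))
  keep <- mean_ra > threshold
  if (!any(keep)) {
    abort(sprintf("no taxa exceed the %.4g abundance threshold; network
would be empty", threshold), class = "ms_empty_network")
  }
  out <- abund[keep, ]
  attr(out, "kingdom") <- kingdom
  out
}

#' Build a signed co-occurrence network
#'
#' Computes Spearman rank correlation for every taxon pair across samples
#' and keeps edges with `|rho| >= r_min` and Benjamini-Hochberg-adjusted
#' p < `alpha` (two-sided p from the t approximation). Edge sign is the
#' sign of rho. Constant taxa (correlation undefined) are excluded with a
#' warning.
#'
#' @param abund Filtered relative-abundance tibble (>= 4 samples, >= 2
#'   taxa).
#' @param r_min Correlation magnitude threshold (default 0.6).
#' @param alpha FDR level for edge retention (default 0.05).
#' @return An `ms_network` list: `nodes` tibble (taxon, phylum, degree),
#'   `edges` tibble (from, to, rho, p, p_adj, sign), and `graph`
#'   (an igraph object with `weight = |rho|`).
#' @export
build_network <- function(abund, r_min = 0.6, alpha = 0.05) {
  abund <- validate_abundance_table(abund)
  m <- abund_matrix(abund)   # taxa x samples
  if (ncol(m) < 4) abort("need >= 4 samples to estimate correlations",
                         class = "ms_domain_error")
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warn(paste0("excluding constant taxa: ",
                paste(rownames(m)[const], collapse = ", ")))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need >= 2 non-constant taxa",
                         class = "ms_domain_error")
  n_s <- ncol(m)
  rho <- stats::cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r_c <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tstat <- r_c * sqrt((n_s - 2) / (1 - r_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n_s - 2)
  p_adj <- stats::p.adjust(p, method = "BH")
  keep <- abs(r) >= r_min & p_adj < alpha
  edges <- tibble::tibble(from = rownames(m)[idx[, 1]],
                          to = rownames(m)[idx[, 2]],
                          rho = r, p = p, p_adj = p_adj)[keep, ]
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  nodes <- tibble::tibble(taxon = rownames(m),
                          phylum = taxon_phylum(rownames(m)))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$taxon)
  if (nrow(edges) > 0) {
    igraph::E(g)$weight <- abs(edges$rho)
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$sign <- edges$sign
  }
  nodes$degree <- as.numeric(igraph::degree(g)[nodes$taxon])
  structure(list(nodes = nodes, edges = edges, graph = g,
                 r_min = r_min, alpha = alpha,
                 kingdom = attr(abund, "kingdom")),
            class = "ms_network")
}

#' Topology metrics of a co-occurrence network
#'
#' Node and edge counts, density `2E / (N(N-1))`, average degree `2E/N`,
#' average path length over connected pairs only (flagged `NaN` when the
#' edge set is empty), modularity of the supplied or freshly detected
#' partition, and the proportion of positive edges.
#'
#' @param net An `ms_network`.
#' @param modules Optional module assignment from [detect_modules()]; if
#'   absent and the network has edges, modules are detected with seed 1.
#' @return One-row tibble of metrics.
#' @export
topology <- function(net, modules = NULL) {
  stopifnot(inherits(net, "ms_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  apl <- if (e > 0) igraph::mean_distance(g, weights = NA) else NaN
  q <- if (e > 0) {
    if (is.null(modules)) modules <- detect_modules(net, seed = 1L)
    modules$modularity
  } else NA_real_
  tibble::tibble(
    nodes = n, edges = e,
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    average_degree = if (n > 0) 2 * e / n else 0,
    average_path_length = apl,
    path_length_connected_pairs_only = TRUE,
    modularity = q,
    positive_edge_proportion = if (e > 0) mean(net$edges$sign == "positive")
                               else NaN)
}

#' Detect network modules (Louvain)
#'
#' Greedy modularity maximization on absolute edge weights (modularity is
#' defined for non-negative weights; edge signs stay as metadata).
#' Deterministic under `seed`.
#'
#' @param net An `ms_network` with >= 1 edge.
#' @param seed Integer seed.
#' @return List with `membership` (named integer vector) and
#'   `modularity` Q.
#' @export
detect_modules <- function(net, seed = 1L) {
  stopifnot(inherits(net, "ms_network"))
  if (igraph::ecount(net$graph) < 1) {
    abort("module detection needs at least one edge",
          class = "ms_empty_network")
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(net$graph)
  membership <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(membership),
                                    names(membership)),
       modularity = igraph::modularity(net$graph,
                                       membership = membership,
                                       weights = igraph::E(net$graph)$weight))
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score
#' `Zi = (k_is - mean_s(k)) / sd_s(k)` (0 where the module's within-degree
#' SD is zero) and participation coefficient
#' `Pi = 1 - sum_s (k_is / k_i)^2` over modules s. Roles follow the
#' conventional thresholds: module hub `Zi > 2.5`, connector `Pi > 0.62`,
#' network hub both, else peripheral. Isolated nodes get Zi = Pi = 0.
#'
#' @param net An `ms_network`.
#' @param modules Module assignment from [detect_modules()].
#' @param zi_threshold Module-hub threshold (default 2.5).
#' @param pi_threshold Connector threshold (default 0.62).
#' @return Tibble `taxon, phylum, module, degree, zi, pi, role`.
#' @export
zipi <- function(net, modules, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "ms_network"))
  g <- net$graph
  memb <- modules$membership
  taxa <- net$nodes$taxon
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  adj <- adj[taxa, taxa, drop = FALSE]
  mod_of <- memb[taxa]
  k_total <- rowSums(adj > 0)
  mods <- sort(unique(mod_of))
  # within-module degree of every node toward every module
  k_to_mod <- sapply(mods, function(s) {
    rowSums(adj[, mod_of == s, drop = FALSE] > 0)
  })
  if (is.null(dim(k_to_mod))) k_to_mod <- matrix(k_to_mod, ncol = 1)
  colnames(k_to_mod) <- as.character(mods)
  k_within <- k_to_mod[cbind(seq_along(taxa),
                             match(mod_of, mods))]
  zi <- numeric(length(taxa))
  for (s in mods) {
    in_s <- which(mod_of == s)
    mu <- mean(k_within[in_s])
    sdv <- stats::sd(k_within[in_s])
    zi[in_s] <- if (is.na(sdv) || sdv == 0) 0 else
      (k_within[in_s] - mu) / sdv
  }
  pi <- unname(ifelse(k_total == 0, 0,
                      1 - rowSums((k_to_mod / pmax(k_total, 1))^2)))
  zi <- unname(zi)
  role <- dplyr::case_when(
    zi > zi_threshold & pi > pi_threshold ~ "network hub",
    zi > zi_threshold ~ "module hub",
    pi > pi_threshold ~ "connector",
    TRUE ~ "peripheral")
  tibble::tibble(taxon = taxa, phylum = net$nodes$phylum,
                 module = unname(as.integer(mod_of)),
                 degree = unname(as.numeric(k_total)), zi = zi, pi = pi,
                 role = role)
}

#' Write a network's edge list to TSV
#'
#' @param net An `ms_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' @export
print.ms_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (|rho| >= %.2f, FDR < %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$r_min, x$alpha))
  invisible(x)
}
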