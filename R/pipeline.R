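#' Configure an end-to-end analysis run
#'
#' Bundles the stage configurations and seeds. Every stochastic stage has
#' an explicit seed; the config round-trips to YAML losslessly via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param trial A [trial_config()] (used when no soil CSV is supplied).
#' @param community A [community_config()].
#' @param soil_path Optional CSV of an existing replicate-level soil
#'   table; when set, the simulate stage is skipped for soil.
#' @param indicators SQI indicator set.
#' @param emf_functions EMF function set.
#' @param r_min,edge_alpha Network edge thresholds.
#' @param stats_alpha Significance level for treatment statistics.
#' @param n_perm PERMANOVA permutations.
#' @param seeds Named list of integer seeds (`simulate`, `permanova`,
#'   `modules`); all required.
#' @return An `ms_pipeline_config` list.
#' @export
pipeline_config <- function(trial = trial_config(),
                            community = community_config(),
                            soil_path = NULL,
                            indicators = MS_SQI_INDICATORS,
                            emf_functions = MS_EMF_FUNCTIONS,
                            r_min = 0.6, edge_alpha = 0.05,
                            stats_alpha = 0.05, n_perm = 999,
                            seeds = list(simulate = 1L, permanova = 1L,
                                         modules = 1L)) {
  needed <- c("simulate", "permanova", "modules")
  miss <- setdiff(needed, names(seeds))
  if (length(miss) > 0 || any(vapply(seeds[needed], is.null, logical(1)))) {
    abort(paste0("missing seed(s): ", paste(miss, collapse = ", ")),
          class = "ms_config_error")
  }
  structure(list(trial = trial, community = community,
                 soil_path = soil_path, indicators = indicators,
                 emf_functions = emf_functions, r_min = r_min,
                 edge_alpha = edge_alpha, stats_alpha = stats_alpha,
                 n_perm = n_perm, seeds = seeds),
            class = "ms_pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' @param config An `ms_pipeline_config`.
#' @param path YAML path.
#' @return `path` (write) or the restored config (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  plain <- rapply(unclass(config), function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  }, classes = "ANY", how = "replace")
  plain$trial <- unclass(plain$trial)
  plain$trial$means <- as.list(config$trial$means)
  plain$trial$yield_multipliers <- as.list(config$trial$yield_multipliers)
  plain$community <- unclass(plain$community)
  plain$community$n_taxa <- as.list(config$community$n_taxa)
  plain$community$profiles <- lapply(config$community$profiles, as.list)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  trial <- trial_config(
    treatments = raw$trial$treatments,
    years = raw$trial$years,
    replicates = raw$trial$replicates,
    means = tibble::as_tibble(raw$trial$means),
    yield_baseline = raw$trial$yield_baseline,
    pm_multiplier = unlist(raw$trial$pm_multiplier) %||%
      c("2022" = 1.0481, "2023" = 1.0787),
    yield_cv = raw$trial$yield_cv,
    y0_frac = raw$trial$y0_frac,
    n_rate = raw$trial$n_rate)
  community <- community_config(
    n_taxa = unlist(raw$community$n_taxa),
    depth = raw$community$depth,
    overdispersion = raw$community$overdispersion,
    replicates = raw$community$replicates,
    profiles = lapply(raw$community$profiles, tibble::as_tibble))
  pipeline_config(trial = trial, community = community,
                  soil_path = raw$soil_path,
                  indicators = raw$indicators,
                  emf_functions = raw$emf_functions,
                  r_min = raw$r_min, edge_alpha = raw$edge_alpha,
                  stats_alpha = raw$stats_alpha, n_perm = raw$n_perm,
                  seeds = raw$seeds)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> soil indices -> community diversity/ordination ->
#' co-occurrence networks -> treatment statistics -> fold-change report.
#' All stage outputs are written under `out_dir` as CSV/TSV/JSON; a
#' manifest records the config hash and seeds, so a rerun with the same
#' config is bit-identical.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param skip_community Skip diversity, ordination and network stages
#'   (soil-only analysis, e.g. when working from published group means).
#' @param soil Optional in-memory soil table overriding simulation.
#' @param quiet Suppress progress messages.
#' @return An invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         skip_community = FALSE, soil = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "ms_stage_error")
    })
  }

  say("stage: simulate/load")
  soil <- stage("simulate", {
    if (!is.null(soil)) validate_soil_table(soil)
    else if (!is.null(config$soil_path)) read_soil_table(config$soil_path)
    else simulate_soil(config$trial, seed = config$seeds$simulate)
  })
  write_soil_table(soil, file.path(out_dir, "soil.csv"))
  yields <- stage("simulate", simulate_yields(config$trial,
                                              seed = config$seeds$simulate))

  say("stage: indices")
  indices <- stage("indices", {
    sqi <- compute_sqi(soil, indicators = config$indicators)
    emf <- compute_emf(soil, functions = config$emf_functions)
    nue <- nue_table(yields$yields, yields$y0, f_n = config$trial$n_rate)
    idx <- dplyr::left_join(sqi, emf, by = ms_key_cols)
    idx <- dplyr::left_join(idx, nue, by = ms_key_cols)
    idx
  })
  readr::write_csv(indices, file.path(out_dir, "sqi_emf_nue.csv"))
  idx_summary <- group_summary(indices)
  readr::write_csv(idx_summary, file.path(out_dir, "sqi_emf_nue_summary.csv"))

  community_out <- NULL
  if (!skip_community) {
    say("stage: community")
    comms <- stage("community",
                   simulate_communities(config$community,
                                        seed = config$seeds$simulate))
    community_out <- list()
    for (k in names(comms)) {
      ab <- comms[[k]]
      write_abundance_table(ab, file.path(out_dir,
                                          paste0("abundance_", k, ".tsv")))
      counts <- attr(ab, "counts")
      alpha <- alpha_diversity(counts)
      readr::write_csv(alpha, file.path(out_dir, paste0("alpha_", k, ".csv")))
      d <- bray_curtis(t(abund_matrix(ab)))
      ord <- pcoa(d, k = 2)
      readr::write_csv(ord$points, file.path(out_dir,
                                             paste0("pcoa_", k, ".csv")))
      grp <- sub("_.*$", "", ord$points$sample)
      perm <- permanova(d, grp, n_perm = config$n_perm,
                        seed = config$seeds$permanova)
      jsonlite::write_json(
        list(pseudo_F = perm$f, p_value = perm$p_value,
             n_perm = perm$n_perm, seed = perm$seed),
        file.path(out_dir, paste0("permanova_", k, ".json")),
        auto_unbox = TRUE, digits = NA)

      say("stage: network (%s)", k)
      nets <- stage("network", {
        per_treat <- list()
        for (tr in MS_TREATMENTS) {
          cols <- c("taxon", "phylum",
                    grep(paste0("^", tr, "_"),
                         setdiff(names(ab), c("taxon", "phylum")),
                         value = TRUE))
          sub <- ab[, cols]
          attr(sub, "kingdom") <- attr(ab, "kingdom")
          filt <- filter_taxa(sub)
          net <- suppressWarnings(build_network(filt,
                                                r_min = config$r_min,
                                                alpha = config$edge_alpha))
          mods <- if (nrow(net$edges) > 0)
            detect_modules(net, seed = config$seeds$modules) else NULL
          topo <- topology(net, modules = mods)
          roles <- if (!is.null(mods)) zipi(net, mods) else NULL
          write_edge_list(net, file.path(out_dir,
                                         sprintf("edges_%s_%s.tsv", k, tr)))
          igraph::write_graph(net$graph,
                              file.path(out_dir,
                                        sprintf("network_%s_%s.graphml",
                                                k, tr)),
                              format = "graphml")
          if (!is.null(roles)) {
            readr::write_csv(roles, file.path(out_dir,
                                              sprintf("node_roles_%s_%s.csv",
                                                      k, tr)))
          }
          per_treat[[tr]] <- list(network = net, topology = topo,
                                  roles = roles)
        }
        topo_all <- dplyr::bind_rows(
          lapply(per_treat, function(x) x$topology), .id = "treatment")
        jsonlite::write_json(topo_all,
                             file.path(out_dir,
                                       sprintf("topology_%s.json", k)),
                             digits = NA)
        per_treat
      })
      community_out[[k]] <- list(alpha = alpha, pcoa = ord,
                                 permanova = perm, networks = nets)
    }
  }

  say("stage: stats")
  stats_out <- stage("stats", {
    vars <- setdiff(names(soil)[vapply(soil, is.numeric, logical(1))],
                    ms_key_cols)
    duncan <- list()
    for (yr in unique(soil$year)) {
      sub <- soil[soil$year == yr, ]
      for (v in vars) {
        key <- paste(v, yr, sep = "_")
        duncan[[key]] <- tryCatch(
          anova_duncan(sub, !!rlang::sym(v), treatment,
                       alpha = config$stats_alpha),
          error = function(e) NULL)
      }
    }
    duncan_tbl <- dplyr::bind_rows(lapply(
      Filter(Negate(is.null), duncan), function(d) {
        tibble::add_column(generics::tidy(d), f = d$f,
                           p_value_anova = d$p_value)
      }), .id = "variable_year")
    contr <- dplyr::bind_rows(lapply(stats::setNames(vars, vars),
      function(v) {
        orthogonal_contrast(soil, !!rlang::sym(v), treatment,
                            coefficients = c(NPK = 3, CM = -1, PM = -1,
                                             SM = -1))
      }), .id = "variable")
    list(duncan = duncan_tbl, contrasts = contr)
  })
  readr::write_csv(stats_out$duncan, file.path(out_dir, "anova_duncan.csv"))
  readr::write_csv(stats_out$contrasts, file.path(out_dir, "contrasts.csv"))

  say("stage: report")
  report <- stage("report", {
    # columns already present in the soil table (e.g. published SQI/EMF
    # in a group-means fixture) take precedence over recomputed indices
    extra <- setdiff(names(indices), names(soil))
    joined <- dplyr::left_join(soil, indices[, c(ms_key_cols, extra)],
                               by = ms_key_cols)
    fold_change_report(group_summary(joined))
  })
  jsonlite::write_json(
    list(ratios = report$ratios, ranges = report$ranges),
    file.path(out_dir, "report.json"), digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("milletsoil")),
    config_hash = rlang::hash(unclass(config)),
    seeds = config$seeds,
    skip_community = skip_community,
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(soil = soil, indices = indices, summary = idx_summary,
                 community = community_out, stats = stats_out,
                 report = report, manifest = manifest))
}
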