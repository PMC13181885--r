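#' Configure a synthetic fertilization trial
#'
#' Encodes the study design the package emulates: four treatments (mineral
#' NPK control and 50% cow/pig/sheep manure replacement), two years, three
#' replicate plots, with per-(variable, treatment, year) means and standard
#' errors defaulting to the published group summaries. Replicate values are
#' drawn as Normal(mean, se * sqrt(replicates)) — the SE-to-SD conversion
#' for the printed n = 3 — truncated at zero for positive quantities.
#'
#' Grain yield uses a multiplicative model around an NPK baseline at the
#' 13% grain-moisture convention. Only the pig-manure fold over NPK is
#' published (+4.81% in 2022, +7.87% in 2023) together with the ordering
#' PM > SM > CM > NPK, so the cow- and sheep-manure multipliers default to
#' 1/3 and 2/3 of the PM gain. The unfertilized-control yield (needed for
#' agronomic efficiency) is never published and defaults to `y0_frac` of
#' the NPK baseline — an explicit, configurable assumption.
#'
#' @param treatments Treatment codes (default NPK, CM, PM, SM).
#' @param years Trial years (default 2022:2023).
#' @param replicates Replicate plots per treatment-year (default 3).
#' @param means Tibble `variable, year, treatment, mean, se`; defaults to
#'   the measured variables of [millet_table1()] (derived indices excluded).
#' @param yield_baseline NPK grain yield, kg/ha (default 4200).
#' @param pm_multiplier Named per-year PM-over-NPK yield folds.
#' @param yield_cv Coefficient of variation of plot yields (default 0.02).
#' @param y0_frac Unfertilized-control yield as a fraction of the NPK
#'   baseline (default 0.6).
#' @param n_rate N application rate, kg/ha (default 225).
#' @return A `ms_trial_config` list.
#' @export
trial_config <- function(treatments = MS_TREATMENTS,
                         years = c(2022L, 2023L),
                         replicates = 3L,
                         means = NULL,
                         yield_baseline = 4200,
                         pm_multiplier = c("2022" = 1.0481,
                                           "2023" = 1.0787),
                         yield_cv = 0.02,
                         y0_frac = 0.6,
                         n_rate = 225) {
  if (replicates < 2) abort("replicates must be >= 2",
                            class = "ms_config_error")
  if (is.null(means)) {
    means <- dplyr::filter(millet_table1(),
                           !.data$variable %in% MS_DERIVED_VARS)
  }
  means <- tibble::as_tibble(means)
  stopifnot(all(c("variable", "year", "treatment", "mean", "se") %in%
                  names(means)))
  if (any(means$se < 0)) abort("standard errors must be >= 0",
                               class = "ms_config_error")
  if (any(pm_multiplier <= 0) || yield_baseline <= 0) {
    abort("yield parameters must be positive", class = "ms_config_error")
  }
  mult <- yield_multipliers(treatments, years, pm_multiplier)
  structure(list(treatments = treatments, years = as.integer(years),
                 replicates = as.integer(replicates), means = means,
                 yield_baseline = yield_baseline,
                 yield_multipliers = mult, yield_cv = yield_cv,
                 y0_frac = y0_frac, n_rate = n_rate),
            class = "ms_trial_config")
}

# Interpolate CM/SM between 1.0 (NPK) and the PM fold, preserving the
# published ordering PM > SM > CM > NPK.
yield_multipliers <- function(treatments, years, pm_multiplier) {
  out <- tidyr::crossing(treatment = treatments, year = as.integer(years))
  pm <- pm_multiplier[as.character(out$year)]
  frac <- c(NPK = 0, CM = 1 / 3, SM = 2 / 3, PM = 1)[out$treatment]
  out$multiplier <- 1 + frac * (pm - 1)
  out
}

#' Simulate a replicate-level soil dataset
#'
#' One row per (treatment, year, replicate); each variable drawn
#' independently as Normal(mean, se * sqrt(replicates)), truncated at zero
#' (pH additionally kept inside (0, 14)). Deterministic under `seed`.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return A validated soil tibble.
#' @export
simulate_soil <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "ms_trial_config"))
  set.seed(seed)
  sd_mult <- sqrt(config$replicates)
  grid <- tidyr::crossing(
    dplyr::distinct(config$means[, c("variable", "year", "treatment")]),
    replicate = seq_len(config$replicates))
  grid <- dplyr::left_join(grid, config$means,
                           by = c("variable", "year", "treatment"))
  # order draws deterministically
  grid <- dplyr::arrange(grid, .data$variable, .data$year, .data$treatment,
                         .data$replicate)
  grid$value <- truncated_normal(grid$mean, grid$se * sd_mult,
                                 lower = ifelse(grid$variable == "pH",
                                                .Machine$double.eps, 0),
                                 upper = ifelse(grid$variable == "pH",
                                                14, Inf))
  wide <- tidyr::pivot_wider(grid[, c("treatment", "year", "replicate",
                                      "variable", "value")],
                             names_from = "variable",
                             values_from = "value")
  validate_soil_table(wide)
}

# Draw Normal(mean, sd) and redraw outside [lower, upper]; with sd = 0 the
# mean is returned exactly.
truncated_normal <- function(mean, sd, lower = 0, upper = Inf) {
  x <- stats::rnorm(length(mean), mean, sd)
  bad <- which(x <= lower | x >= upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lower[bad] | x[bad] >= upper[bad]]
    tries <- tries + 1L
  }
  if (length(bad) > 0) x[bad] <- pmax(lower[bad] + 1e-9, mean[bad])
  x
}

#' Simulate per-plot grain yields and the unfertilized control
#'
#' Group means follow `baseline * multiplier(treatment, year)`; plot noise
#' is Normal with coefficient of variation `yield_cv` (exact means in the
#' zero-noise limit). Yields follow the 13% grain-moisture convention.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed.
#' @return List with `yields` (treatment, year, replicate, yield) and
#'   `y0` (year, y0) tibbles.
#' @export
simulate_yields <- function(config = trial_config(), seed = 1L) {
  stopifnot(inherits(config, "ms_trial_config"))
  set.seed(seed + 1L)
  grid <- tidyr::crossing(config$yield_multipliers,
                          replicate = seq_len(config$replicates))
  mu <- config$yield_baseline * grid$multiplier
  grid$yield <- truncated_normal(mu, config$yield_cv * mu,
                                 lower = rep(0, length(mu)),
                                 upper = rep(Inf, length(mu)))
  y0 <- tibble::tibble(year = as.integer(config$years),
                       y0 = config$y0_frac * config$yield_baseline)
  list(yields = dplyr::arrange(grid[, c("treatment", "year", "replicate",
                                        "yield")],
                               .data$year, .data$treatment, .data$replicate),
       y0 = y0)
}

#' Configure synthetic microbial communities
#'
#' Per-kingdom phylum concentration profiles encode the qualitative
#' treatment shifts reported for the trial: Proteobacteria (and
#' Gemmatimonadetes, Crenarchaeota) elevated under cow manure;
#' Bacteroidetes and Ascomycota elevated under pig manure; Acidobacteria,
#' Chloroflexi, Basidiomycota and Thaumarchaeota highest under the mineral
#' control; Chytridiomycota, Microsporidia, Euryarchaeota and
#' Candidatus_Bathyarchaeota elevated under all organic treatments.
#' Species are nested within phyla with geometrically decaying weights;
#' per-sample compositions are Dirichlet(profile / overdispersion) and
#' counts multinomial at `depth`.
#'
#' @param n_taxa Named integer vector of species counts per kingdom.
#' @param depth Sequencing depth per sample (default 1e5).
#' @param overdispersion Dirichlet overdispersion; compositions converge
#'   to the profile means as it approaches 0 (default 2e-3).
#' @param phylum_sigma SD (log scale) of a per-sample, per-phylum
#'   lognormal activity factor shared by all species of a phylum; this is
#'   what makes species of one phylum co-occur across samples, so
#'   networks have within-phylum correlation blocks. 0 disables the
#'   effect, giving (compositionally) near-independent taxa (default 0.7).
#' @param replicates Samples per treatment-year used when communities are
#'   generated without a soil table; networks need more than the 3 field
#'   replicates for estimable correlations (default 10).
#' @param profiles Optional list overriding the per-kingdom phylum
#'   base concentrations and treatment multipliers.
#' @return A `ms_community_config` list.
#' @export
community_config <- function(n_taxa = c(bacteria = 120L, fungi = 60L,
                                        archaea = 40L),
                             depth = 1e5, overdispersion = 2e-3,
                             phylum_sigma = 0.7,
                             replicates = 10L, profiles = NULL) {
  if (depth < 1) abort("depth must be >= 1", class = "ms_config_error")
  if (overdispersion <= 0) abort("overdispersion must be > 0",
                                 class = "ms_config_error")
  if (phylum_sigma < 0) abort("phylum_sigma must be >= 0",
                              class = "ms_config_error")
  structure(list(n_taxa = n_taxa, depth = depth,
                 overdispersion = overdispersion,
                 phylum_sigma = phylum_sigma,
                 replicates = as.integer(replicates),
                 profiles = profiles %||% default_phylum_profiles()),
            class = "ms_community_config")
}

# Base phylum concentrations (relative weights) and treatment multipliers.
default_phylum_profiles <- function() {
  bact <- tibble::tribble(
    ~phylum,                  ~base, ~NPK, ~CM,  ~PM,  ~SM,
    "Proteobacteria",           30,  1.0,  1.5,  1.15, 1.1,
    "Acidobacteria",            16,  1.3,  0.7,  0.85, 0.9,
    "Actinobacteria",           15,  1.0,  1.0,  1.0,  1.0,
    "Bacteroidetes",             8,  0.8,  1.1,  1.6,  1.3,
    "Gemmatimonadetes",          6,  0.8,  1.4,  1.15, 1.1,
    "Chloroflexi",               8,  1.3,  0.75, 0.85, 0.9,
    "Verrucomicrobia",           4,  1.0,  1.0,  1.0,  1.0,
    "Candidatus_Rokubacteria",   3,  1.2,  0.8,  0.85, 0.9,
    "Nitrospirae",               3,  1.2,  0.8,  0.85, 0.9,
    "Planctomycetes",            3,  1.0,  1.0,  1.0,  1.0)
  fung <- tibble::tribble(
    ~phylum,              ~base, ~NPK, ~CM,  ~PM,  ~SM,
    "Ascomycota",           40,  0.9,  1.05, 1.3,  1.0,
    "Mucoromycota",         20,  1.0,  1.0,  1.0,  1.0,
    "Basidiomycota",        15,  1.4,  0.75, 0.7,  0.8,
    "Chytridiomycota",      10,  0.7,  1.3,  1.4,  1.3,
    "Zoopagomycota",         6,  1.0,  1.0,  1.0,  1.0,
    "Microsporidia",         5,  0.75, 1.25, 1.3,  1.2,
    "Blastocladiomycota",    4,  1.0,  1.0,  1.0,  1.0)
  arch <- tibble::tribble(
    ~phylum,                      ~base, ~NPK, ~CM,  ~PM,  ~SM,
    "Thaumarchaeota",               50,  1.3,  0.7,  0.8,  0.85,
    "Crenarchaeota",                25,  0.75, 1.6,  1.3,  1.2,
    "Euryarchaeota",                15,  0.8,  1.25, 1.3,  1.2,
    "Candidatus_Bathyarchaeota",    10,  0.8,  1.2,  1.3,  1.25)
  list(bacteria = bact, fungi = fung, archaea = arch)
}

# Species-level Dirichlet concentrations for one kingdom under one
# treatment: phylum concentration spread over species with geometric
# weights (ratio 0.75), so every phylum keeps a few dominant species.
species_profile <- function(profile, treatment, n_species) {
  conc <- profile$base * profile[[treatment]]
  n_phy <- nrow(profile)
  per <- rep(n_species %/% n_phy, n_phy)
  if (n_species %% n_phy > 0) {
    per[seq_len(n_species %% n_phy)] <- per[seq_len(n_species %% n_phy)] + 1
  }
  out <- lapply(seq_len(n_phy), function(i) {
    w <- 0.75^(seq_len(per[i]) - 1)
    tibble::tibble(
      taxon = sprintf("%s|sp%02d", profile$phylum[i], seq_len(per[i])),
      alpha = conc[i] * w / sum(w))
  })
  dplyr::bind_rows(out)
}

#' Simulate taxa-by-sample community tables for each kingdom
#'
#' @param config A [community_config()].
#' @param samples Optional tibble with `treatment`, `year`, `replicate`
#'   naming the samples (e.g. a soil table); by default a
#'   `config$replicates`-per-group grid over the four treatments and two
#'   years.
#' @param seed Integer seed.
#' @param kingdoms Which kingdoms to generate.
#' @return Named list of relative-abundance tibbles (attribute `kingdom`
#'   set; column names `treatment_year_replicate`), with raw counts in
#'   attribute `counts`.
#' @export
simulate_communities <- function(config = community_config(),
                                 samples = NULL, seed = 1L,
                                 kingdoms = c("bacteria", "fungi",
                                              "archaea")) {
  stopifnot(inherits(config, "ms_community_config"))
  if (is.null(samples)) {
    samples <- tidyr::crossing(treatment = MS_TREATMENTS,
                               year = c(2022L, 2023L),
                               replicate = seq_len(config$replicates))
  }
  samples <- dplyr::arrange(tibble::as_tibble(samples), .data$year,
                            .data$treatment, .data$replicate)
  ids <- sprintf("%s_%d_%d", samples$treatment, samples$year,
                 samples$replicate)
  set.seed(seed + 2L)
  out <- list()
  for (k in kingdoms) {
    n_sp <- config$n_taxa[[k]]
    if (config$depth < n_sp) {
      warn(sprintf("depth %g below taxon count %d for %s; sparse columns
expected", config$depth, n_sp, k))
    }
    profs <- lapply(MS_TREATMENTS, species_profile,
                    profile = config$profiles[[k]], n_species = n_sp)
    names(profs) <- MS_TREATMENTS
    phyla <- taxon_phylum(profs[[1]]$taxon)
    phy_levels <- unique(phyla)
    counts <- matrix(0L, nrow = n_sp, ncol = length(ids),
                     dimnames = list(profs[[1]]$taxon, ids))
    for (j in seq_along(ids)) {
      pr <- profs[[samples$treatment[j]]]
      alpha <- pr$alpha
      if (config$phylum_sigma > 0) {
        fac <- stats::rlnorm(length(phy_levels), 0, config$phylum_sigma)
        alpha <- alpha * fac[match(phyla, phy_levels)]
      }
      alpha <- (alpha / sum(alpha)) / config$overdispersion
      g <- stats::rgamma(n_sp, shape = alpha, rate = 1)
      if (sum(g) == 0) g <- alpha
      comp <- g / sum(g)
      counts[, j] <- stats::rmultinom(1, size = config$depth, prob = comp)
    }
    tbl <- tibble::as_tibble(counts, .name_repair = "minimal")
    tbl <- tibble::add_column(tbl, taxon = rownames(counts),
                              .before = 1)
    tbl <- tibble::add_column(tbl, phylum = taxon_phylum(tbl$taxon),
                              .after = "taxon")
    rel <- relative_abundance(tbl)
    attr(rel, "kingdom") <- k
    attr(rel, "counts") <- counts
    out[[k]] <- rel
  }
  out
}

#' Simulate a full trial (soil, yields, communities)
#'
#' @param config A [trial_config()].
#' @param community A [community_config()].
#' @param seed Integer seed driving every stage.
#' @return List with `soil`, `yields`, `y0`, and `communities`.
#' @export
simulate_trial <- function(config = trial_config(),
                           community = community_config(), seed = 1L) {
  soil <- simulate_soil(config, seed = seed)
  yl <- simulate_yields(config, seed = seed)
  comms <- simulate_communities(community, samples = NULL, seed = seed)
  list(soil = soil, yields = yl$yields, y0 = yl$y0, communities = comms)
}
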