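#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr across all_of any_of
NULL

# Canonical treatment codes and Table-1-style variable sets. The four
# treatments are a pure mineral NPK control and three 50% organic
# replacements (cow / pig / sheep manure) at equal total N-P2O5-K2O rates.
MS_TREATMENTS <- c("NPK", "CM", "PM", "SM")

# The ten physicochemical indicators entering the soil quality index,
# in their conventional order.
MS_SQI_INDICATORS <- c("pH", "SP", "TC", "TN", "TP", "TK",
                       "NH4", "NO3", "AP", "AK")

# The six enzyme activities entering ecological multifunctionality.
MS_EMF_FUNCTIONS <- c("CAT", "INV", "NAG", "URE", "ALP", "GLS")

# Derived indices that may legitimately be non-positive and are therefore
# exempt from the strict-positivity check on measured soil variables.
MS_DERIVED_VARS <- c("SQI", "EMF")

ms_key_cols <- c("treatment", "year", "replicate")

#' Validate a replicate-level soil sample table
#'
#' Checks the contract shared by all downstream stages: key columns
#' `treatment`, `year`, `replicate` present; no duplicated keys; all
#' variable columns numeric with no missing values; pH within (0, 14);
#' every other measured variable strictly positive (derived indices such
#' as `SQI`/`EMF` may be negative).
#'
#' @param soil A data frame with one row per (treatment, year, replicate).
#' @return The validated table as a tibble, invisibly classed.
#' @export
validate_soil_table <- function(soil) {
  soil <- tibble::as_tibble(soil)
  missing_keys <- setdiff(ms_key_cols, names(soil))
  if (length(missing_keys) > 0) {
    abort(paste0("soil table is missing required column(s): ",
                 paste(missing_keys, collapse = ", ")),
          class = "ms_schema_error")
  }
  vars <- setdiff(names(soil), ms_key_cols)
  if (length(vars) == 0) {
    abort("soil table has no variable columns", class = "ms_schema_error")
  }
  for (v in vars) {
    if (!is.numeric(soil[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(soil[[v]])))))
      abort(sprintf("column '%s' is not numeric (first bad row: %d)",
                    v, if (length(bad)) bad[1] else NA_integer_),
            class = "ms_parse_error")
    }
    if (anyNA(soil[[v]])) {
      abort(sprintf("column '%s' contains missing values (row %d); the
trial design is complete-case", v, which(is.na(soil[[v]]))[1]),
            class = "ms_validation_error")
    }
  }
  keys <- paste(soil$treatment, soil$year, soil$replicate, sep = "/")
  if (anyDuplicated(keys)) {
    abort(paste0("duplicated (treatment, year, replicate) key: ",
                 keys[anyDuplicated(keys)]),
          class = "ms_validation_error")
  }
  if ("pH" %in% vars && any(soil$pH <= 0 | soil$pH >= 14)) {
    abort("pH values must lie strictly inside (0, 14)",
          class = "ms_validation_error")
  }
  for (v in setdiff(vars, c("pH", MS_DERIVED_VARS))) {
    if (any(soil[[v]] <= 0)) {
      abort(sprintf("variable '%s' must be strictly positive (row %d)",
                    v, which(soil[[v]] <= 0)[1]),
            class = "ms_validation_error")
    }
  }
  soil
}

#' Read a replicate-level soil table from CSV
#'
#' Expects one header row, '.' decimal separator, UTF-8, and the Table-1
#' variable abbreviations as column names (units live in documentation,
#' not headers).
#'
#' @param path Path to a CSV file.
#' @param required Optional character vector of variable columns that must
#'   be present (e.g. an indicator set).
#' @return A validated tibble with key columns and numeric variables.
#' @export
read_soil_table <- function(path, required = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ms_io_error")
  }
  soil <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("could not parse CSV: ",
                                     conditionMessage(e)),
                              class = "ms_parse_error"))
  if (nrow(soil) == 0 || ncol(soil) == 0) {
    abort("empty soil table", class = "ms_schema_error")
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(soil))
    if (length(miss) > 0) {
      abort(paste0("soil table is missing required column(s): ",
                   paste(miss, collapse = ", ")),
            class = "ms_schema_error")
    }
  }
  validate_soil_table(soil)
}

#' Write a soil table to CSV
#'
#' @param soil A validated soil table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_soil_table <- function(soil, path) {
  readr::write_csv(validate_soil_table(soil), path)
  invisible(path)
}

#' Convert an abundance table to relative abundances
#'
#' Columns (samples) are renormalized to sum to one; the operation is
#' idempotent. Taxon labels stay in the first column.
#'
#' @param abund A tibble whose first column is `taxon` and remaining
#'   columns are per-sample non-negative abundances or counts.
#' @return A tibble of the same shape with columns summing to 1.
#' @export
relative_abundance <- function(abund) {
  abund <- validate_abundance_table(abund)
  samples <- setdiff(names(abund), c("taxon", "phylum"))
  for (s in samples) {
    tot <- sum(abund[[s]])
    abund[[s]] <- abund[[s]] / tot
  }
  abund
}

#' Validate an abundance table
#'
#' @param abund Tibble with a `taxon` first column, optional `phylum`
#'   column, and numeric sample columns.
#' @return The validated tibble.
#' @export
validate_abundance_table <- function(abund) {
  abund <- tibble::as_tibble(abund)
  if (names(abund)[1] != "taxon") {
    abort("first column of an abundance table must be 'taxon'",
          class = "ms_schema_error")
  }
  samples <- setdiff(names(abund), c("taxon", "phylum"))
  if (length(samples) == 0) {
    abort("abundance table has no sample columns", class = "ms_schema_error")
  }
  if (anyDuplicated(abund$taxon)) {
    abort("duplicated taxon labels", class = "ms_validation_error")
  }
  for (s in samples) {
    if (!is.numeric(abund[[s]]) || anyNA(abund[[s]])) {
      abort(sprintf("sample column '%s' must be numeric with no missing
values", s), class = "ms_validation_error")
    }
    if (any(abund[[s]] < 0)) {
      abort(sprintf("negative abundance in sample '%s'", s),
            class = "ms_validation_error")
    }
    if (sum(abund[[s]]) == 0) {
      abort(sprintf("sample '%s' has zero total abundance", s),
            class = "ms_validation_error")
    }
  }
  abund
}

#' Read a taxa-by-samples abundance table from TSV
#'
#' First column holds taxon labels (convention: `Phylum|species`, so
#' phylum membership survives round trips); remaining columns are samples.
#' Counts are converted to relative abundances unless `relative = FALSE`.
#'
#' @param path Path to a TSV file.
#' @param kingdom One of `"bacteria"`, `"fungi"`, `"archaea"`; recorded as
#'   an attribute and used for default network filtering thresholds.
#' @param relative Convert columns to relative abundances (default TRUE).
#' @return A tibble with `taxon`, `phylum` and sample columns; attribute
#'   `kingdom` set.
#' @export
read_abundance_table <- function(path, kingdom = c("bacteria", "fungi",
                                                   "archaea"),
                                 relative = TRUE) {
  kingdom <- match.arg(kingdom)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ms_io_error")
  }
  abund <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(abund)[1] <- "taxon"
  abund <- validate_abundance_table(abund)
  abund <- tibble::add_column(abund, phylum = taxon_phylum(abund$taxon),
                              .after = "taxon")
  if (relative) abund <- relative_abundance(abund)
  attr(abund, "kingdom") <- kingdom
  abund
}

#' Write an abundance table to TSV
#'
#' The `phylum` helper column is dropped on write; phylum membership is
#' carried inside the taxon label.
#'
#' @param abund Abundance tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(abund, path) {
  abund <- validate_abundance_table(abund)
  abund$phylum <- NULL
  readr::write_tsv(abund, path)
  invisible(path)
}

#' Extract phylum from `Phylum|species` taxon labels
#'
#' @param taxon Character vector of taxon labels.
#' @return Character vector of phylum names (`NA` where no separator).
#' @export
taxon_phylum <- function(taxon) {
  out <- ifelse(grepl("|", taxon, fixed = TRUE),
                sub("\\|.*$", "", taxon), NA_character_)
  out
}

#' Abundance tibble to taxa-by-samples matrix
#'
#' @param abund Abundance tibble.
#' @return Numeric matrix, rownames = taxon labels, colnames = samples.
#' @export
abund_matrix <- function(abund) {
  abund <- validate_abundance_table(abund)
  samples <- setdiff(names(abund), c("taxon", "phylum"))
  m <- as.matrix(abund[, samples])
  rownames(m) <- abund$taxon
  m
}

#' Published per-group soil summary (means and standard errors)
#'
#' Treatment-by-year means and standard errors (n = 3) for the sixteen
#' measured soil variables plus the published SQI and EMF indices, as
#' packaged with the trial fixture. These feed the synthetic generator
#' defaults and the fold-change report.
#'
#' @return Tibble with columns `variable`, `year`, `treatment`, `mean`, `se`.
#' @export
millet_table1 <- function() {
  path <- system.file("extdata", "table1_summary.csv",
                      package = "milletsoil", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Group means as a pseudo-replicate soil table
#'
#' Expands the per-group summary into a replicate-level table with
#' `replicates` identical pseudo-replicates per (treatment, year) at the
#' group mean. Useful where only published means are available: group
#' means then act as the scoring pool.
#'
#' @param summary Output of [millet_table1()] or same shape.
#' @param replicates Pseudo-replicates per group (default 3).
#' @return Validated soil tibble.
#' @export
summary_to_samples <- function(summary = millet_table1(), replicates = 3) {
  wide <- tidyr::pivot_wider(summary[, c("variable", "year", "treatment",
                                         "mean")],
                             names_from = "variable", values_from = "mean")
  out <- tidyr::crossing(wide, replicate = seq_len(replicates))
  out <- dplyr::relocate(out, "treatment", "year", "replicate")
  validate_soil_table(out)
}
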