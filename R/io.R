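.TRAIT_COLUMNS <- c("species", "family", "order", "voc", "uv_reflectance",
                    "blue_reflectance", "green_reflectance", "red_reflectance",
                    "lambda_max", "peak_brightness", "area_to_weight",
                    "n_fruits")

#' Load and validate a species trait table
#'
#' Reads a CSV with one row per species and the column layout of the
#' packaged community table: taxonomy (`species`, `family`, `order`; `"UK"`
#' marks unknown placements), the surface-area-scaled VOC sum (`voc`), the
#' four visible-scale band percentages, peak hue (`lambda_max`) and peak
#' brightness, the surface-area:weight ratio and the number of fruits
#' sampled.
#'
#' @param path Path to the CSV file, or a data frame to validate in place.
#' @return A validated data frame.
#' @export
load_trait_table <- function(path) {
  d <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.TRAIT_COLUMNS, names(d))
  if (length(missing)) {
    stop(sprintf("trait table is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(d$species)) {
    stop(sprintf("duplicate species rows: %s",
                 paste(unique(d$species[duplicated(d$species)]), collapse = ", ")),
         call. = FALSE)
  }
  num_cols <- setdiff(.TRAIT_COLUMNS, c("species", "family", "order"))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric value in column '%s' at row %d",
                   col, which(is.na(v))[1]), call. = FALSE)
    }
    d[[col]] <- v
  }
  bad <- which(d$voc <= 0 | d$area_to_weight <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive VOC or SA:W at row %d (species %s)",
                 bad[1], d$species[bad[1]]), call. = FALSE)
  }
  bands <- c("uv_reflectance", "blue_reflectance", "green_reflectance",
             "red_reflectance")
  if (any(as.matrix(d[bands]) < 0)) {
    stop("band percentages must be nonnegative", call. = FALSE)
  }
  d[.TRAIT_COLUMNS]
}

#' The packaged Malagasy fruit community trait table
#'
#' Returns the published trait table for the 56 endemic wild fruit species
#' of a Malagasy tropical dry forest (19 known families, 10 known orders),
#' transcribed verbatim: surface-area-scaled VOC sums, visible-scale band
#' reflectance percentages, peak hue and brightness, surface-area:weight
#' ratios and fruit sample sizes. Printed spellings are preserved exactly,
#' including two species pairs that share identical reflectance rows.
#'
#' @return A 56-row data frame (see [load_trait_table()] for columns).
#' @export
madagascar_fruit_traits <- function() {
  load_trait_table(system.file("extdata", "table1_traits.csv",
                               package = "fruitsignals", mustWork = TRUE))
}

#' Write a trait table
#' @param records Trait table data frame.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(records, path) {
  write.csv(records[.TRAIT_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from long-format CSV
#'
#' Expects columns `species`, `wavelength_nm`, `reflectance`.
#'
#' @param path CSV path.
#' @return Named list of [reflectance_spectrum()] objects.
#' @export
read_spectra <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "wavelength_nm", "reflectance")
  if (!all(need %in% names(d))) {
    stop("spectra CSV needs columns species, wavelength_nm, reflectance",
         call. = FALSE)
  }
  out <- lapply(split(d, factor(d$species, levels = unique(d$species))),
                function(g) {
    g <- g[order(g$wavelength_nm), ]
    reflectance_spectrum(g$wavelength_nm, g$reflectance)
  })
  out
}

#' Write spectra to long-format CSV
#' @param spectra Named list of [reflectance_spectrum()] objects.
#' @param path Output CSV path.
#' @export
write_spectra <- function(spectra, path) {
  d <- do.call(rbind, lapply(names(spectra), function(sp) {
    data.frame(species = sp, wavelength_nm = spectra[[sp]]$wavelength,
               reflectance = spectra[[sp]]$reflectance,
               stringsAsFactors = FALSE)
  }))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every input and tuning choice for [run_pipeline()] so a run is
#' fully determined by its config.
#'
#' @param traits Trait table: a path or a data frame.
#' @param spectra Optional spectra: a path to a long-format CSV or a named
#'   list of [reflectance_spectrum()]; when absent the spectral regression
#'   stage is skipped (band summaries alone cannot feed it).
#' @param tree Optional tree: a newick path or an `ape::phylo`; by default a
#'   framework tree is built from the table's taxonomy.
#' @param knots,referent,boundary Spline settings; see [build_basis()].
#' @param band_denominator Band scale for the correlation screen; see
#'   [correlation_matrix()].
#' @param n_perm Randomizations for the Blomberg's K test.
#' @param seed Integer seed recorded in the report and used for every
#'   stochastic step.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(traits, spectra = NULL, tree = NULL,
                            knots = c(350, 410, 470, 530, 590),
                            referent = 650, boundary = c(300, 700),
                            band_denominator = "total",
                            n_perm = 1000, seed = 1L) {
  structure(
    list(traits = traits, spectra = spectra, tree = tree, knots = knots,
         referent = referent, boundary = boundary,
         band_denominator = band_denominator,
         n_perm = n_perm, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Composes the package's stages in order: load and validate the trait
#' table, Pearson correlation screen, spectral spline regression with band
#' effects (when spectra are supplied), and the phylogenetic-signal battery
#' on the species-level tree. Deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `"analysis_report"` with elements `traits`,
#'   `correlations`, `spline` (or `NULL`), `signal` and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- load_trait_table(config$traits)

  corr <- correlation_matrix(records,
                             band_denominator = config$band_denominator)

  spline_out <- NULL
  if (!is.null(config$spectra)) {
    spectra <- if (is.character(config$spectra)) read_spectra(config$spectra)
               else config$spectra
    spectra <- spectra[.tip_label(names(spectra)) %in% .tip_label(records$species) |
                         names(spectra) %in% records$species]
    if (length(spectra) != nrow(records)) {
      stop("spectra do not cover every species in the trait table",
           call. = FALSE)
    }
    spectra <- spectra[match(records$species, names(spectra))]
    grid <- spectra[[1]]$wavelength
    basis <- build_basis(knots = config$knots, referent = config$referent,
                         boundary = config$boundary, grid = grid)
    fit <- fit_spectral_model(spectra, voc = records$voc,
                              area_to_weight = records$area_to_weight,
                              basis = basis)
    spline_out <- list(fit = fit, band_effects = band_effects(fit))
  }

  tree <- if (is.null(config$tree)) {
    tree_from_taxonomy(records)
  } else if (is.character(config$tree)) {
    ape::read.tree(config$tree)
  } else {
    config$tree
  }
  signal <- phylo_signal_table(records, tree = tree, n_perm = config$n_perm,
                               seed = config$seed)

  structure(
    list(traits = records, correlations = corr, spline = spline_out,
         signal = signal, tree = tree,
         provenance = list(
           package = "fruitsignals",
           version = as.character(utils::packageVersion("fruitsignals")),
           seed = config$seed, n_perm = config$n_perm,
           knots = config$knots, referent = config$referent,
           boundary = config$boundary,
           band_denominator = config$band_denominator)),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d species (seed %d)\n",
              nrow(x$traits), x$provenance$seed))
  print(x$correlations)
  if (!is.null(x$spline)) {
    print(x$spline$fit)
    print(x$spline$band_effects)
  }
  cat("Phylogenetic signal:\n")
  print(x$signal, digits = 3)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the trait table, the correlation table (4-significant-digit CSV
#' with significance stars), the signal table, the spline fit summary (when
#' present) and a full-precision JSON sidecar carrying every number plus the
#' provenance block. Output bytes are a pure function of the report, so
#' identical configs give identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traits = file.path(dir, "trait_table.csv"),
             correlations = file.path(dir, "correlations.csv"),
             signal = file.path(dir, "phylo_signal.csv"),
             sidecar = file.path(dir, "report.json"))
  write_trait_table(report$traits, paths[["traits"]])
  write.csv(correlation_table(report$correlations, digits = 4),
            paths[["correlations"]], row.names = FALSE)
  sig <- report$signal
  sig[-1] <- lapply(sig[-1], signif, digits = 4)
  write.csv(sig, paths[["signal"]], row.names = FALSE)

  payload <- list(
    provenance = report$provenance,
    correlations = list(r = report$correlations$r, p = report$correlations$p),
    signal = report$signal
  )
  if (!is.null(report$spline)) {
    f <- report$spline$fit
    payload$spline <- list(
      coefficients = as.list(f$coefficients), covariance = f$covariance,
      r_squared = f$r_squared, f_stat = f$f_stat, f_df = f$f_df, f_p = f$f_p,
      n_obs = f$n_obs, band_effects = report$spline$band_effects)
    paths <- c(paths, spline = file.path(dir, "spline_fit.csv"))
    write.csv(report$spline$band_effects, paths[["spline"]],
              row.names = FALSE)
  }
  jsonlite::write_json(payload, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
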