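#' Configuration for a synthetic fruit community
#'
#' Bundles and validates the generating parameters for
#' [generate_community()]. The defaults describe the study conditions the
#' rest of the package is calibrated against: a 56-species community measured
#' on a 300-700 nm grid in 20 nm steps (21 points per spectrum, ~1176 pooled
#' reflectance values), a negative blue-reflectance effect and a positive
#' surface-area:weight effect on the log10 VOC index, and traits that carry
#' no phylogenetic structure.
#'
#' @param n_species Number of species (>= 3).
#' @param wavelength_grid Strictly increasing wavelengths in nm within
#'   300-700.
#' @param blue_voc_effect Change in log10 VOC index per unit blue reflectance
#'   percentage (visible-scale band index).
#' @param saw_voc_effect Change in log10 VOC index per unit log10
#'   surface-area:weight ratio.
#' @param voc_intercept Intercept of the generating VOC model (log10 scale).
#' @param voc_noise_sd Standard deviation of the log10-scale VOC noise (>= 0).
#' @param spectral_smoothness Width (nm) of the Gaussian reflectance bump.
#' @param tree_model `"taxonomy_polytomy"` (framework tree of nested
#'   polytomies with unit branch lengths) or `"birth_death"` (random
#'   bifurcating tree).
#' @param trait_model `"white_noise"` (clade-free traits), `"brownian"`, or
#'   `"lambda"` (Brownian with off-diagonal covariance scaled by `lambda`).
#' @param lambda Pagel's lambda in `[0, 1]`; required when
#'   `trait_model = "lambda"`.
#' @param seed Integer seed; the community is fully reproducible given the
#'   config.
#' @return A validated list of class `"community_config"`.
#' @export
community_config <- function(n_species = 56,
                             wavelength_grid = seq(300, 700, by = 20),
                             blue_voc_effect = -0.04,
                             saw_voc_effect = 0.5,
                             voc_intercept = -0.1,
                             voc_noise_sd = 0.35,
                             spectral_smoothness = 50,
                             tree_model = c("taxonomy_polytomy", "birth_death"),
                             trait_model = c("white_noise", "brownian", "lambda"),
                             lambda = NULL,
                             seed = 1L) {
  tree_model <- match.arg(tree_model)
  trait_model <- match.arg(trait_model)
  if (n_species < 3) stop("n_species must be at least 3", call. = FALSE)
  if (length(wavelength_grid) == 0 || any(diff(wavelength_grid) <= 0) ||
      min(wavelength_grid) < 300 || max(wavelength_grid) > 700) {
    stop("wavelength_grid must be strictly increasing within [300, 700]",
         call. = FALSE)
  }
  if (voc_noise_sd < 0) stop("voc_noise_sd must be nonnegative", call. = FALSE)
  if (trait_model == "lambda") {
    if (is.null(lambda) || lambda < 0 || lambda > 1) {
      stop("trait_model = 'lambda' requires lambda in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(n_species = as.integer(n_species), wavelength_grid = wavelength_grid,
         blue_voc_effect = blue_voc_effect, saw_voc_effect = saw_voc_effect,
         voc_intercept = voc_intercept, voc_noise_sd = voc_noise_sd,
         spectral_smoothness = spectral_smoothness, tree_model = tree_model,
         trait_model = trait_model, lambda = lambda, seed = as.integer(seed)),
    class = "community_config"
  )
}

#' Generate one synthetic reflectance spectrum
#'
#' Spectra are mixtures of Gaussian bumps: a main bump of width `smoothness`
#' at `mean_hue`, a broad shoulder of width `5 * smoothness` at the same hue
#' carrying 30% of the main weight, and optionally further bumps
#' (`extra_bumps`) that add secondary reflectance structure elsewhere in the
#' spectrum. The mixture is rescaled so its maximum equals `brightness`.
#' This produces the smooth, nonnegative curves portable spectrometers
#' record from ripe fruit skins. As `smoothness` shrinks the spectrum
#' concentrates at the grid point nearest `mean_hue`; as it grows the
#' spectrum flattens towards uniform.
#'
#' @param mean_hue Peak wavelength in nm, within 300-700.
#' @param brightness Peak reflectance, in (0, 1].
#' @param smoothness Gaussian bump width in nm (> 0).
#' @param grid Wavelength grid to evaluate on.
#' @param extra_bumps Optional data frame with columns `hue`, `width`,
#'   `weight` adding secondary Gaussian components (weights relative to the
#'   main bump's weight of 0.7).
#' @return A [reflectance_spectrum()] (not brightness-normalized).
#' @export
generate_spectrum <- function(mean_hue, brightness, smoothness,
                              grid = seq(300, 700, by = 20),
                              extra_bumps = NULL) {
  if (length(grid) == 0) stop("wavelength grid must be non-empty", call. = FALSE)
  if (mean_hue < 300 || mean_hue > 700) {
    stop("mean_hue must lie in [300, 700] nm", call. = FALSE)
  }
  if (brightness <= 0 || brightness > 1) {
    stop("brightness must lie in (0, 1]", call. = FALSE)
  }
  if (smoothness <= 0) stop("smoothness must be positive", call. = FALSE)
  bump <- function(mu, s) exp(-(grid - mu)^2 / (2 * s^2))
  r <- 0.7 * bump(mean_hue, smoothness) + 0.3 * bump(mean_hue, 5 * smoothness)
  if (!is.null(extra_bumps)) {
    for (i in seq_len(nrow(extra_bumps))) {
      r <- r + extra_bumps$weight[i] * bump(extra_bumps$hue[i],
                                            extra_bumps$width[i])
    }
  }
  if (max(r) <= 0) {
    stop("spectrum underflowed to zero; increase smoothness", call. = FALSE)
  }
  reflectance_spectrum(grid, brightness * r / max(r))
}

## Draw one standard multivariate-normal vector with covariance V via the
## Cholesky root, consuming exactly length(z) = n variates so that draws are
## comparable across models under a common seed.
.mvn_draw <- function(V, z) {
  as.vector(t(chol(V)) %*% z)
}

#' Simulate a continuous trait on a tree
#'
#' Draws one trait vector over the tips of `tree` under one of three
#' covariance models: `"white_noise"` (independent `N(0, sigma2)` draws,
#' ignoring the tree), `"brownian"` (multivariate normal with covariance
#' `sigma2 * C` where `C[i, j]` is the shared root-to-tip path length), or
#' `"lambda"` (Brownian covariance with off-diagonal entries multiplied by
#' `lambda`). `lambda = 1` reproduces the Brownian draw exactly and
#' `lambda = 0` reduces to independent draws with the Brownian tip variances.
#'
#' All three models consume the same `n` standard-normal variates in the same
#' order, so draws under different models with the same seed are coupled.
#'
#' @param tree An `ape::phylo` tree; branch lengths must be positive for the
#'   Brownian and lambda models.
#' @param model One of `"white_noise"`, `"brownian"`, `"lambda"`.
#' @param sigma2 Brownian rate (variance per unit branch length), or the
#'   variance of each draw under white noise.
#' @param lambda Pagel's lambda in `[0, 1]` (lambda model only).
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_trait_on_tree <- function(tree,
                                   model = c("white_noise", "brownian", "lambda"),
                                   sigma2 = 1, lambda = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  z <- rnorm(n)
  if (model == "white_noise") {
    x <- sqrt(sigma2) * z
  } else {
    if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
      stop("tree must have positive branch lengths for this model", call. = FALSE)
    }
    V <- ape::vcv(tree)
    if (model == "lambda") {
      if (is.null(lambda) || lambda < 0 || lambda > 1) {
        stop("lambda must lie in [0, 1]", call. = FALSE)
      }
      d <- diag(V)
      V <- lambda * V
      diag(V) <- d
    }
    x <- .mvn_draw(sigma2 * V, z)
  }
  setNames(x, tree$tip.label)
}

#' Generate a synthetic fruit community
#'
#' Produces a full community with the statistical structure the downstream
#' analyses assume: smooth reflectance spectra, ellipsoidal fruit geometry
#' whose surface-area:weight (SA:W) ratio spans roughly the observed
#' 66-1965 mm^2/g, a taxonomy (orders / families / genera) with a matching
#' framework tree, and a log10-scale VOC index generated as
#'
#' `voc_index = intercept + blue_voc_effect * blue% + saw_voc_effect * log10(SA:W) + noise`
#'
#' where `blue%` is the visible-scale blue band index computed from the
#' species' own generated spectrum. Raw surface-area-scaled VOC sums are
#' obtained by exponentiation. Under `trait_model = "white_noise"` the hue,
#' brightness and size drivers are independent across species (no clade
#' structure); under `"brownian"`/`"lambda"` they inherit the corresponding
#' covariance from the tree.
#'
#' @param config A [community_config()].
#' @return A list of class `"synthetic_community"` with elements `records`
#'   (trait table in the packaged-fixture column layout), `spectra` (named
#'   list of [reflectance_spectrum()]), `tree` (`ape::phylo`), `true_effects`
#'   (named vector of the injected generating coefficients) and `config`.
#' @export
generate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n <- config$n_species

  ## taxonomy scaled to echo 56 species / 19 families / 10 orders
  n_ord <- max(2L, round(n / 5.6))
  n_fam <- max(n_ord, round(n / 2.95))
  n_gen <- max(n_fam, round(n / 1.4))
  fam_of_gen <- c(seq_len(n_fam), sample(n_fam, max(0, n_gen - n_fam), TRUE))[1:n_gen]
  ord_of_fam <- c(seq_len(n_ord), sample(n_ord, max(0, n_fam - n_ord), TRUE))[1:n_fam]
  gen_of_sp <- sort(c(seq_len(n_gen), sample(n_gen, max(0, n - n_gen), TRUE))[1:n])
  genus <- sprintf("Genus%02d", gen_of_sp)
  species <- sprintf("%s sp%03d", genus, seq_len(n))
  family <- sprintf("Family%02d", fam_of_gen[gen_of_sp])
  order <- sprintf("Order%02d", ord_of_fam[fam_of_gen[gen_of_sp]])

  records0 <- data.frame(species = species, family = family, order = order,
                         stringsAsFactors = FALSE)
  tree <- if (config$tree_model == "taxonomy_polytomy") {
    tree_from_taxonomy(records0)
  } else {
    t <- ape::rphylo(n, birth = 1, death = 0)
    t$tip.label <- .tip_label(species)
    t
  }

  ## latent drivers of hue, brightness and size
  draw_driver <- function() {
    z <- simulate_trait_on_tree(tree, model = config$trait_model,
                                sigma2 = 1, lambda = config$lambda)
    if (config$trait_model != "white_noise") {
      z <- z / sqrt(diag(ape::vcv(tree)))  # unit marginal variance per tip
    }
    z[.tip_label(species)]
  }
  z_hue <- draw_driver(); z_bri <- draw_driver(); z_size <- draw_driver()

  mean_hue <- 480 + 220 * stats::pnorm(z_hue)
  brightness <- 0.06 + 0.78 * stats::pnorm(z_bri)
  diam <- 10^(log10(14) + 0.3 * z_size)          # mm, lognormal around 14

  axes <- cbind(diam * runif(n, 0.75, 1.3),
                diam * runif(n, 0.75, 1.3),
                diam * runif(n, 0.75, 1.3))
  area <- ellipsoid_surface_area(axes, dims_are = "full_axes")   # mm^2
  volume <- (4 / 3) * pi * apply(axes / 2, 1, prod)              # mm^3
  weight <- volume * 0.001 * runif(n, 0.9, 1.15)                 # g
  saw <- area / weight

  ## per-species spectral shape: width jitter plus a secondary bump at an
  ## independent hue, so spectra vary in shape as well as peak location
  width_mult <- runif(n, 0.6, 1.6)
  extra_hue <- runif(n, 300, 700)
  extra_weight <- runif(n, 0, 0.45)
  extra_width <- config$spectral_smoothness * runif(n, 0.8, 2.0)
  spectra <- lapply(seq_len(n), function(i) {
    generate_spectrum(mean_hue[i], brightness[i],
                      config$spectral_smoothness * width_mult[i],
                      grid = config$wavelength_grid,
                      extra_bumps = data.frame(hue = extra_hue[i],
                                               width = extra_width[i],
                                               weight = extra_weight[i]))
  })
  names(spectra) <- species
  bands <- lapply(seq_len(n), function(i) {
    band_proportions(normalize_brightness(spectra[[i]]), species = species[i])
  })
  blue <- vapply(bands, `[[`, numeric(1), "blue")

  vi <- config$voc_intercept + config$blue_voc_effect * blue +
    config$saw_voc_effect * log10(saw) + rnorm(n, 0, config$voc_noise_sd)

  records <- data.frame(
    species = species, family = family, order = order,
    voc = 10^vi,
    uv_reflectance = vapply(bands, `[[`, numeric(1), "uv"),
    blue_reflectance = blue,
    green_reflectance = vapply(bands, `[[`, numeric(1), "green"),
    red_reflectance = vapply(bands, `[[`, numeric(1), "red"),
    lambda_max = vapply(bands, `[[`, numeric(1), "lambda_max"),
    peak_brightness = vapply(bands, `[[`, numeric(1), "peak_brightness"),
    area_to_weight = saw,
    n_fruits = sample(c(5L, 6L, 8L, 10L), n, TRUE, prob = c(.6, .1, .05, .25)),
    stringsAsFactors = FALSE
  )

  structure(
    list(records = records, spectra = spectra, tree = tree,
         true_effects = c(intercept = config$voc_intercept,
                          blue = config$blue_voc_effect,
                          saw = config$saw_voc_effect),
         config = config),
    class = "synthetic_community"
  )
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d species, %d-point spectra, tree: %s\n",
              nrow(x$records), length(x$config$wavelength_grid),
              x$config$tree_model))
  cat(sprintf("  injected effects: blue %.4g, log10(SA:W) %.4g\n",
              x$true_effects[["blue"]], x$true_effects[["saw"]]))
  invisible(x)
}

#' Write a synthetic community to disk
#'
#' Writes the trait table (same column layout as the packaged fixture), the
#' spectra in long format (`species, wavelength_nm, reflectance`) and the
#' tree in newick format.
#'
#' @param community A [generate_community()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "synthetic_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.csv"),
             spectra = file.path(dir, "spectra.csv"),
             tree = file.path(dir, "tree.nwk"))
  write_trait_table(community$records, paths[["traits"]])
  write_spectra(community$spectra, paths[["spectra"]])
  ape::write.tree(community$tree, paths[["tree"]])
  invisible(paths)
}
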