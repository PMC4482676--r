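test_that("generated spectra hit the delta, flat and peak-location limits", {
  g <- balanced_grid()
  # near-delta: all reflectance collapses onto the grid point nearest the hue
  s <- generate_spectrum(545, 1, smoothness = 0.5, grid = g)
  b <- band_proportions(normalize_brightness(s))
  expect_equal(c(b$uv, b$blue, b$green, b$red), c(0, 0, 100, 0),
               tolerance = 1e-9)
  expect_equal(b$lambda_max, 545)
  # near-flat: raw band masses approach the uniform split
  f <- generate_spectrum(500, 0.5, smoothness = 1e6, grid = g)
  raw <- reflectance_spectrum(f$wavelength, f$reflectance, normalized = TRUE)
  bf <- band_proportions(raw)
  expect_equal(c(bf$blue, bf$green, bf$red), rep(100 / 3, 3), tolerance = 1e-4)
  # default smoothness: spectrum peaks within one grid step of the hue
  grid20 <- seq(300, 700, by = 20)
  s450 <- generate_spectrum(450, 0.8, smoothness = 50, grid = grid20)
  expect_lte(abs(grid20[which.max(s450$reflectance)] - 450), 20)
  expect_true(all(s450$reflectance >= 0 & s450$reflectance <= 1))
  expect_error(generate_spectrum(450, 0.8, 50, grid = numeric(0)), "non-empty")
  expect_error(generate_spectrum(450, 1.2, 50), "brightness")
  expect_error(generate_spectrum(250, 0.5, 50), "mean_hue")
})

test_that("community generation is deterministic and internally consistent", {
  cfg <- community_config(n_species = 30, seed = 99)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$spectra, c2$spectra)
  expect_identical(ape::write.tree(c1$tree), ape::write.tree(c2$tree))
  # one spectrum and one tip per record; unique species labels
  expect_false(anyDuplicated(c1$records$species) > 0)
  expect_setequal(names(c1$spectra), c1$records$species)
  expect_setequal(c1$tree$tip.label, gsub(" ", "_", c1$records$species))
  # visible band proportions are compositional for every synthetic species
  sums <- with(c1$records,
               blue_reflectance + green_reflectance + red_reflectance)
  expect_equal(sums, rep(100, 30), tolerance = 1e-9)
  expect_identical(unname(c1$true_effects["blue"]), -0.04)
})

test_that("injected VOC structure follows the generating equation", {
  # no noise, no blue effect: VOC index is an exact affine function of
  # log10(SA:W), so r(blue, voc) equals r(blue, log10 SA:W) exactly
  cfg <- community_config(n_species = 80, blue_voc_effect = 0,
                          voc_noise_sd = 0, seed = 4)
  cm <- generate_community(cfg)
  vi <- log10(cm$records$voc)
  expect_equal(cor(cm$records$blue_reflectance, vi),
               cor(cm$records$blue_reflectance,
                   log10(cm$records$area_to_weight)),
               tolerance = 1e-12)
  # with all effects and noise off, the VOC index is flat
  cfg0 <- community_config(n_species = 20, blue_voc_effect = 0,
                           saw_voc_effect = 0, voc_noise_sd = 0, seed = 4)
  c0 <- generate_community(cfg0)
  expect_equal(log10(c0$records$voc), rep(cfg0$voc_intercept, 20),
               tolerance = 1e-12)
  # exact reconstruction of the generating equation with effects on
  cfg2 <- community_config(n_species = 40, voc_noise_sd = 0, seed = 5)
  c2 <- generate_community(cfg2)
  pred <- cfg2$voc_intercept +
    cfg2$blue_voc_effect * c2$records$blue_reflectance +
    cfg2$saw_voc_effect * log10(c2$records$area_to_weight)
  expect_equal(log10(c2$records$voc), pred, tolerance = 1e-12)
  # geometry spans a realistic SA:W range
  big <- generate_community(community_config(n_species = 300, seed = 6))
  expect_lt(min(big$records$area_to_weight), 250)
  expect_gt(max(big$records$area_to_weight), 900)
})

test_that("trait simulation models nest as their parameters say", {
  tr <- ape::rphylo(25, 1, 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tru <- tr; tru$edge.length <- tru$edge.length / depth  # unit-depth tree
  # lambda = 1 is exactly the Brownian draw
  expect_identical(simulate_trait_on_tree(tru, "lambda", lambda = 1, seed = 11),
                   simulate_trait_on_tree(tru, "brownian", seed = 11))
  # lambda = 0 on a unit-depth ultrametric tree is the white-noise draw
  expect_equal(simulate_trait_on_tree(tru, "lambda", lambda = 0, seed = 12),
               simulate_trait_on_tree(tru, "white_noise", seed = 12),
               tolerance = 1e-12)
  expect_error(simulate_trait_on_tree(tru, "lambda", lambda = 1.5), "lambda")
  nolen <- tru; nolen$edge.length <- NULL
  expect_error(simulate_trait_on_tree(nolen, "brownian"), "branch lengths")
})

test_that("Brownian tip-difference variance scales with shared path length", {
  t2 <- tree2(t = 0.7)
  set.seed(21)
  diffs <- replicate(1e4, {
    x <- simulate_trait_on_tree(t2, "brownian", sigma2 = 1.3)
    x[["a"]] - x[["b"]]
  })
  expect_equal(var(diffs), 2 * 1.3 * 0.7, tolerance = 0.05)
})

test_that("a community round-trips through its on-disk formats", {
  cm <- generate_community(community_config(n_species = 12, seed = 31))
  dir <- withr::local_tempdir()
  paths <- write_community(cm, dir)
  back <- load_trait_table(paths[["traits"]])
  expect_equal(back$voc, cm$records$voc)
  expect_equal(back$species, cm$records$species)
  spec <- read_spectra(paths[["spectra"]])
  expect_equal(spec[[cm$records$species[3]]]$reflectance,
               cm$spectra[[3]]$reflectance)
  tre <- ape::read.tree(paths[["tree"]])
  expect_setequal(tre$tip.label, cm$tree$tip.label)
})
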