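#' Natural-cubic-spline basis over wavelength with a fixed referent
#'
#' Builds the five-column spectral basis used by [fit_spectral_model()]. The
#' coefficient function over wavelength is modelled as a natural cubic spline
#' on the knot vector formed by `knots` together with `referent` (which acts
#' as the terminal knot), giving exactly `length(knots)` basis functions that
#' exclude the constant. Each column is then re-centred by subtracting its
#' value at the referent wavelength, so every basis function -- and hence any
#' fitted coefficient curve -- is zero at the referent. Because summed
#' visible-range reflectance is the same for every species after
#' normalization, pinning the curve at one wavelength in this way removes the
#' compositional near-collinearity from the design.
#'
#' Beyond the outermost knots the basis is linear (the natural condition:
#' second derivative zero), which defines its values on grid points outside
#' the knot span, e.g. 300-340 nm and 660-700 nm under the defaults.
#'
#' @param knots Strictly increasing interior knot wavelengths (nm); the
#'   default places them at 350, 410, 470, 530 and 590 nm.
#' @param referent Referent wavelength (nm) at which the basis is pinned to
#'   zero; default 650. Must lie inside `boundary`, above `max(knots)`, and
#'   not coincide with a knot.
#' @param boundary Analysis range (nm); knots, referent and grid must lie
#'   inside it. Default `c(300, 700)`, the measured range.
#' @param grid Wavelengths (nm) at which the basis is evaluated; must match
#'   the spectra the basis will be applied to.
#' @return An object of class `"spline_basis"`: list with `knots`,
#'   `referent`, `boundary`, `grid` and the centred `matrix`
#'   (`length(grid)` x 5, full column rank).
#' @export
build_basis <- function(knots = c(350, 410, 470, 530, 590), referent = 650,
                        boundary = c(300, 700),
                        grid = seq(300, 700, by = 20)) {
  if (length(boundary) != 2 || boundary[1] >= boundary[2]) {
    stop("boundary must be an increasing pair of wavelengths", call. = FALSE)
  }
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  if (any(knots <= boundary[1] | knots >= boundary[2])) {
    stop("knots must lie strictly inside the boundary", call. = FALSE)
  }
  if (referent <= boundary[1] || referent >= boundary[2]) {
    stop("referent must lie strictly inside the boundary", call. = FALSE)
  }
  if (referent %in% knots) {
    stop("referent must be distinct from the knots", call. = FALSE)
  }
  if (referent <= max(knots)) {
    stop("referent must lie above the last knot (it acts as the terminal knot)",
         call. = FALSE)
  }
  if (length(grid) == 0 || any(diff(grid) <= 0) ||
      min(grid) < boundary[1] || max(grid) > boundary[2]) {
    stop("grid must be strictly increasing within the boundary", call. = FALSE)
  }

  allk <- sort(c(knots, referent))
  m <- .ns_eval(grid, allk)
  if (ncol(m) != 5L) {
    stop(sprintf(paste0("basis has %d columns, expected 5; choose knots and ",
                        "referent yielding five spectral terms"), ncol(m)),
         call. = FALSE)
  }
  ref_row <- .ns_eval(referent, allk)
  centred <- sweep(m, 2, as.vector(ref_row))
  if (qr(centred)$rank < 5L) {
    stop("centred basis is rank-deficient on this grid; use a finer grid",
         call. = FALSE)
  }
  colnames(centred) <- paste0("s", seq_len(ncol(centred)))
  structure(
    list(knots = knots, referent = referent, boundary = boundary,
         grid = grid, matrix = centred, all_knots = allk),
    class = "spline_basis"
  )
}

## Natural cubic spline design on the full knot vector (first and last act
## as boundary knots). Linear extrapolation outside the knot span.
.ns_eval <- function(x, all_knots) {
  k <- length(all_knots)
  unclass(splines::ns(x, knots = all_knots[2:(k - 1)],
                      Boundary.knots = all_knots[c(1, k)]))
}

#' Evaluate a spline basis at new wavelengths
#'
#' Returns the referent-centred basis rows for arbitrary wavelengths (linear
#' extrapolation beyond the outermost knots).
#'
#' @param basis A [build_basis()] result.
#' @param wavelength Numeric vector of wavelengths (nm).
#' @return A `length(wavelength)` x 5 matrix.
#' @export
evaluate_basis <- function(basis, wavelength) {
  stopifnot(inherits(basis, "spline_basis"))
  m <- .ns_eval(wavelength, basis$all_knots)
  ref <- .ns_eval(basis$referent, basis$all_knots)
  out <- sweep(m, 2, as.vector(ref))
  colnames(out) <- colnames(basis$matrix)
  out
}

#' Normalized per-wavelength reflectance (percent of visible)
#'
#' Brightness-normalizes a spectrum and expresses each reflectance value as a
#' percentage of the summed visible-range (400-700 nm) reflectance. This is
#' the per-wavelength analogue of the band indices: summing the returned
#' values over a colour band gives that band's index.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @param species Optional label for error messages.
#' @return A [reflectance_spectrum()] whose reflectance holds the percent
#'   values (`normalized = TRUE`).
#' @export
visible_percent <- function(spectrum, species = NULL) {
  s <- if (spectrum$normalized) spectrum else normalize_brightness(spectrum)
  reflectance_spectrum(s$wavelength,
                       .percent_reflectance(s, "visible", species = species),
                       normalized = TRUE)
}

#' Collapse a spectrum to the five spline predictors
#'
#' Computes the weighted sums `p_j = sum_w B[w, j] * reflectance[w]` of the
#' spectrum values against the centred basis columns. The operation is linear
#' in the spectrum: predictors of a sum of spectra equal the sum of their
#' predictors, a zero spectrum maps to zero, and a spectrum concentrated at
#' the referent wavelength maps to zero. The spectrum is used exactly as
#' given; apply [visible_percent()] first to put it on the analysis scale.
#'
#' @param spectrum A normalized [reflectance_spectrum()] whose wavelengths
#'   equal the basis grid exactly (no silent interpolation).
#' @param basis A [build_basis()] result.
#' @return Named numeric vector of five predictor values.
#' @export
spectrum_predictors <- function(spectrum, basis) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"),
            inherits(basis, "spline_basis"))
  if (!isTRUE(all.equal(spectrum$wavelength, basis$grid))) {
    stop("spectrum wavelengths do not align with the basis grid", call. = FALSE)
  }
  colSums(basis$matrix * spectrum$reflectance)
}

#' Fit the spectral spline regression of odour on reflectance
#'
#' Ordinary least squares of the VOC index (log10 surface-area-scaled VOC
#' sum) on the five spline-transformed spectral predictors plus the log10
#' surface-area:weight ratio. Each species contributes one spectrum, which is
#' brightness-normalized, expressed as percent of visible reflectance, and
#' collapsed through the basis with [spectrum_predictors()]. The overall
#' spectral effect is tested with the 5-degree-of-freedom F test comparing
#' the full model against the SA:W-only model.
#'
#' @param x A `"synthetic_community"`, or a named list of
#'   [reflectance_spectrum()] objects.
#' @param ... Passed to methods.
#' @return An object of class `"spectral_fit"`.
#' @export
fit_spectral_model <- function(x, ...) UseMethod("fit_spectral_model")

#' @rdname fit_spectral_model
#' @param basis A [build_basis()] whose grid matches the spectra.
#' @export
fit_spectral_model.synthetic_community <- function(x, basis = NULL, ...) {
  if (is.null(basis)) basis <- build_basis(grid = x$config$wavelength_grid)
  fit_spectral_model(x$spectra, voc = x$records$voc,
                     area_to_weight = x$records$area_to_weight,
                     basis = basis, ...)
}

#' @rdname fit_spectral_model
#' @param voc Raw surface-area-scaled VOC sums (one per spectrum); the model
#'   response is `log10(voc)`.
#' @param area_to_weight Surface-area:weight ratios (mm^2/g), entered as
#'   log10.
#' @export
fit_spectral_model.default <- function(x, voc, area_to_weight, basis, ...) {
  stopifnot(inherits(basis, "spline_basis"))
  n <- length(x)
  if (length(voc) != n || length(area_to_weight) != n) {
    stop("voc and area_to_weight must match the number of spectra", call. = FALSE)
  }
  if (n < 8) {
    stop("need at least 8 species to fit 7 parameters", call. = FALSE)
  }
  species <- names(x)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n))

  preds <- t(vapply(seq_len(n), function(i) {
    spectrum_predictors(visible_percent(x[[i]], species = species[i]), basis)
  }, numeric(5)))
  dat <- data.frame(voc_index = voc_index(voc), preds,
                    log_saw = log10(area_to_weight))

  full <- lm(voc_index ~ s1 + s2 + s3 + s4 + s5 + log_saw, data = dat)
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  reduced <- lm(voc_index ~ log_saw, data = dat)
  an <- anova(reduced, full)

  structure(
    list(coefficients = coef(full), covariance = vcov(full),
         r_squared = summary(full)$r.squared,
         f_stat = an$F[2], f_df = c(an$Df[2], full$df.residual),
         f_p = an$`Pr(>F)`[2],
         n_obs = n, df_residual = full$df.residual,
         basis = basis, lm_fit = full, data = dat),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> n = %d, R^2 = %.3f\n", x$n_obs, x$r_squared))
  cat(sprintf("  spectral effect: F(%d, %d) = %.2f, p = %.4g\n",
              x$f_df[1], x$f_df[2], x$f_stat, x$f_p))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Cumulative per-band effect via the delta method
#'
#' Back-calculates the effect of reflectance in one 100 nm colour band from
#' the fitted spline coefficients. The contrast vector `c` is the mean (or
#' sum) of the centred basis rows over the grid wavelengths in the band; the
#' cumulative coefficient is `c' beta` and its variance the delta-method form
#' `c' Sigma c`, with a two-tailed p-value from the t reference on the
#' model's residual degrees of freedom. With the default `aggregate = "mean"`
#' the coefficient reads as the change in log10 VOC per unit reflectance
#' percentage placed in that band.
#'
#' @param fit A [fit_spectral_model()] result.
#' @param band One of `"uv"`, `"blue"`, `"green"`, `"red"`.
#' @param aggregate `"mean"` (default) or `"sum"` of the basis rows over the
#'   band.
#' @return A one-row data frame of class `"band_effect"` with columns `band`,
#'   `cumulative_coefficient`, `std_error`, `t_stat`, `df`, `p_two_tailed`.
#' @export
band_effect <- function(fit, band = c("uv", "blue", "green", "red"),
                        aggregate = c("mean", "sum")) {
  stopifnot(inherits(fit, "spectral_fit"))
  band <- match.arg(band)
  aggregate <- match.arg(aggregate)
  rng <- .BANDS[[band]]
  w <- fit$basis$grid
  rows <- w >= rng[1] & (w < rng[2] | (band == "red" & w == 700))
  if (!any(rows)) {
    stop(sprintf("no grid wavelengths fall in the %s band", band), call. = FALSE)
  }
  contrast_b <- if (aggregate == "mean") {
    colMeans(fit$basis$matrix[rows, , drop = FALSE])
  } else {
    colSums(fit$basis$matrix[rows, , drop = FALSE])
  }
  cvec <- setNames(numeric(length(fit$coefficients)), names(fit$coefficients))
  cvec[names(contrast_b)] <- contrast_b

  est <- sum(cvec * fit$coefficients)
  v <- as.numeric(cvec %*% fit$covariance %*% cvec)
  se <- sqrt(max(v, 0))
  tt <- if (se > 0) est / se else NA_real_
  p <- if (se > 0) 2 * pt(-abs(tt), df = fit$df_residual) else NA_real_
  out <- data.frame(band = band, cumulative_coefficient = est, std_error = se,
                    t_stat = tt, df = fit$df_residual, p_two_tailed = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("band_effect", class(out))
  out
}

#' All four band effects
#'
#' @param fit A [fit_spectral_model()] result.
#' @param aggregate Passed to [band_effect()].
#' @return A four-row data frame.
#' @export
band_effects <- function(fit, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  do.call(rbind, lapply(names(.BANDS), function(b) {
    band_effect(fit, b, aggregate = aggregate)
  }))
}
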