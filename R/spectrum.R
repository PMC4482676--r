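#' Construct a reflectance spectrum
#'
#' A spectrum is a set of wavelength/reflectance pairs for one fruit, as read
#' off a field spectrometer against a white standard. Wavelengths must be
#' strictly increasing and lie within the instrument range 250-720 nm;
#' reflectance values are nonnegative fractions of the standard.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance Numeric vector of reflectance values, same length.
#' @param normalized Logical; whether brightness normalization (see
#'   [normalize_brightness()]) has already been applied.
#' @return An object of class `"reflectance_spectrum"`.
#' @seealso [normalize_brightness()], [band_proportions()]
#' @export
#' @examples
#' s <- reflectance_spectrum(seq(300, 700, 20), runif(21, 0, 0.5))
reflectance_spectrum <- function(wavelength, reflectance, normalized = FALSE) {
  wavelength <- as.numeric(wavelength)
  reflectance <- as.numeric(reflectance)
  if (length(wavelength) == 0L) {
    stop("spectrum needs at least one wavelength", call. = FALSE)
  }
  if (length(wavelength) != length(reflectance)) {
    stop("wavelength and reflectance must have the same length", call. = FALSE)
  }
  if (any(!is.finite(wavelength)) || any(!is.finite(reflectance))) {
    stop("spectrum values must be finite", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(wavelength < 250 | wavelength > 720)) {
    stop("wavelengths must lie within the spectrometer range 250-720 nm",
         call. = FALSE)
  }
  if (any(reflectance < 0)) {
    stop("reflectance must be nonnegative", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, reflectance = reflectance,
         normalized = isTRUE(normalized)),
    class = "reflectance_spectrum"
  )
}

#' @export
print.reflectance_spectrum <- function(x, ...) {
  cat(sprintf("<reflectance_spectrum> %d points, %g-%g nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (x$normalized) ", brightness-normalized" else ""))
  invisible(x)
}

#' Brightness-normalize a spectrum
#'
#' Subtracts the minimum reflectance over the visible range (400-700 nm) from
#' every value of the spectrum, so that the lowest visible value becomes zero.
#' This corrects additive spectrometer drift between measurements. Values
#' outside 400-700 nm that become negative after the subtraction are clipped
#' to zero. The operation is idempotent.
#'
#' @param spectrum A [reflectance_spectrum()].
#' @return The normalized spectrum, with `normalized = TRUE`.
#' @export
normalize_brightness <- function(spectrum) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  vis <- .in_visible(spectrum$wavelength)
  if (sum(vis) < 2L) {
    stop("spectrum must cover at least 2 points in 400-700 nm", call. = FALSE)
  }
  shift <- min(spectrum$reflectance[vis])
  r <- pmax(spectrum$reflectance - shift, 0)
  reflectance_spectrum(spectrum$wavelength, r, normalized = TRUE)
}

## Per-wavelength reflectance as a percentage of a band-sum denominator.
## denominator = "visible": sum over 400-700 nm (the convention used when the
## trait table is built); "total": sum over 300-700 nm.
.percent_reflectance <- function(spectrum, denominator = c("visible", "total"),
                                 species = NULL) {
  denominator <- match.arg(denominator)
  w <- spectrum$wavelength
  keep <- if (denominator == "visible") .in_visible(w) else (w >= 300 & w <= 700)
  tot <- sum(spectrum$reflectance[keep])
  if (tot <= 0) {
    stop(sprintf("zero reflectance in the %s range%s", denominator,
                 if (is.null(species)) "" else paste0(" for species ", species)),
         call. = FALSE)
  }
  100 * spectrum$reflectance / tot
}

#' Band reflectance proportions, peak hue and peak brightness
#'
#' Collapses a brightness-normalized spectrum into the four colour-band
#' indices: ultraviolet (300-400 nm), blue/violet (400-500 nm), green/yellow
#' (500-600 nm) and orange/red (600-700 nm). Each index is the summed
#' reflectance in the band expressed as a percentage of the summed reflectance
#' over the visible range 400-700 nm, so blue + green + red = 100 while UV is
#' unbounded by the others. Also reports the wavelength of peak visible
#' reflectance (lambda_max, peak hue) and the reflectance value there
#' (peak brightness).
#'
#' Band boundaries are half-open `[low, high)` with 700 nm assigned to red, so
#' every wavelength contributes to exactly one band.
#'
#' @param spectrum A brightness-normalized [reflectance_spectrum()].
#' @param species Optional species label used in error messages.
#' @return A list of class `"reflectance_bands"` with elements `uv`, `blue`,
#'   `green`, `red` (percentages), `lambda_max` (nm) and `peak_brightness`.
#' @export
band_proportions <- function(spectrum, species = NULL) {
  stopifnot(inherits(spectrum, "reflectance_spectrum"))
  if (!spectrum$normalized) {
    stop("spectrum must be brightness-normalized first; see normalize_brightness()",
         call. = FALSE)
  }
  w <- spectrum$wavelength
  pct <- .percent_reflectance(spectrum, "visible", species = species)
  band <- .band_of(w)
  sums <- vapply(names(.BANDS),
                 function(b) sum(pct[!is.na(band) & band == b]), numeric(1))
  vis <- .in_visible(w)
  i <- which(vis)[which.max(spectrum$reflectance[vis])]
  structure(
    list(uv = sums[["uv"]], blue = sums[["blue"]], green = sums[["green"]],
         red = sums[["red"]], lambda_max = w[i],
         peak_brightness = spectrum$reflectance[i]),
    class = "reflectance_bands"
  )
}

#' @export
print.reflectance_bands <- function(x, ...) {
  cat(sprintf(
    "<reflectance_bands> UV %.2f | blue %.2f | green %.2f | red %.2f (%% of visible)\n",
    x$uv, x$blue, x$green, x$red))
  cat(sprintf("  lambda_max %g nm, peak brightness %.3f\n",
              x$lambda_max, x$peak_brightness))
  invisible(x)
}

#' Re-express band percentages over the full 300-700 nm total
#'
#' The trait table stores band indices as percentages of the visible-range
#' (400-700 nm) reflectance sum, so UV floats free of the other three. For
#' correlation analyses across all four bands it is preferable to place the
#' bands on a single compositional scale: percentages of the total 300-700 nm
#' reflectance. Because `uv + blue + green + red = 100 + uv` on the visible
#' scale, the conversion needs only the printed values:
#' `x_total = x_visible / (1 + uv_visible / 100)`.
#'
#' @param uv,blue,green,red Numeric vectors of visible-scale band percentages.
#' @return A data frame with the four bands on the common total scale
#'   (each row sums to 100).
#' @export
bands_to_total_scale <- function(uv, blue, green, red) {
  den <- 1 + uv / 100
  data.frame(uv = uv / den, blue = blue / den,
             green = green / den, red = red / den)
}
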