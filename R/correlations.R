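#' Pearson correlation with t test
#'
#' Sample Pearson correlation between two trait vectors with the exact
#' two-tailed t test on n - 2 degrees of freedom,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @param pair Optional character vector of two labels for the pair.
#' @return A one-row data frame of class `"correlation_result"` with columns
#'   `var1`, `var2`, `r`, `t_stat`, `df`, `p_two_tailed`, `n`.
#' @export
pearson_test <- function(x, y, pair = c("x", "y")) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop(sprintf("constant input for pair (%s, %s): correlation undefined",
                 pair[1], pair[2]), call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  out <- data.frame(var1 = pair[1], var2 = pair[2],
                    r = unname(ct$estimate), t_stat = unname(ct$statistic),
                    df = unname(ct$parameter), p_two_tailed = ct$p.value,
                    n = length(x), stringsAsFactors = FALSE)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Trait correlation matrix
#'
#' Pearson correlation screening of the six community traits: VOC index
#' (log10 surface-area-scaled VOC sum), the four reflectance band indices,
#' and the surface-area:weight ratio (log10-transformed by default, matching
#' the scale used in the regression analysis).
#'
#' By default the four band indices are first re-expressed on a common
#' compositional scale -- percentages of the total 300-700 nm reflectance --
#' rather than the visible-range (400-700 nm) scale they are tabulated on
#' (see [bands_to_total_scale()]). On the common scale the four proportions
#' sum to 100 for every species, which is the scale on which the published
#' correlation screen is reproduced exactly. Set
#' `band_denominator = "visible"` to correlate the tabulated values directly.
#'
#' @param records A trait table as returned by [load_trait_table()].
#' @param band_denominator `"total"` (default) or `"visible"`.
#' @param saw_transform `"log10"` (default) or `"identity"`.
#' @return An object of class `"trait_correlations"`: list with the `r`, `p`
#'   and significance-star matrices over
#'   `voc, uv, blue, green, red, saw`, plus the long table of
#'   [pearson_test()] results and the sample size `n`. Stars mark p < 0.05
#'   (`*`) and p < 0.01 (`**`).
#' @export
correlation_matrix <- function(records,
                               band_denominator = c("total", "visible"),
                               saw_transform = c("log10", "identity")) {
  band_denominator <- match.arg(band_denominator)
  saw_transform <- match.arg(saw_transform)
  if (nrow(records) < 3) stop("need at least 3 records", call. = FALSE)

  bands <- if (band_denominator == "total") {
    bands_to_total_scale(records$uv_reflectance, records$blue_reflectance,
                         records$green_reflectance, records$red_reflectance)
  } else {
    data.frame(uv = records$uv_reflectance, blue = records$blue_reflectance,
               green = records$green_reflectance, red = records$red_reflectance)
  }
  vars <- data.frame(
    voc = voc_index(records$voc),
    uv = bands$uv, blue = bands$blue, green = bands$green, red = bands$red,
    saw = if (saw_transform == "log10") log10(records$area_to_weight)
          else records$area_to_weight
  )

  nm <- names(vars)
  k <- length(nm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  tests <- list()
  for (i in 2:k) {
    for (j in 1:(i - 1)) {
      res <- tryCatch(
        pearson_test(vars[[i]], vars[[j]], pair = c(nm[i], nm[j])),
        error = function(e) {
          stop(sprintf("pair (%s, %s): %s", nm[i], nm[j], conditionMessage(e)),
               call. = FALSE)
        })
      r[i, j] <- r[j, i] <- res$r
      p[i, j] <- p[j, i] <- res$p_two_tailed
      tests[[length(tests) + 1L]] <- res
    }
  }
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  diag(stars) <- ""

  structure(
    list(r = r, p = p, stars = stars,
         tests = do.call(rbind, tests), n = nrow(records),
         band_denominator = band_denominator, saw_transform = saw_transform),
    class = "trait_correlations"
  )
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (N = %d; bands on %s denominator; SA:W %s)\n",
              x$n, x$band_denominator, x$saw_transform))
  k <- nrow(x$r)
  disp <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in 2:k) for (j in 1:(i - 1)) {
    disp[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"),
                         x$stars[i, j])
  }
  print(as.data.frame(disp[, -k, drop = FALSE]))
  cat("*  p < 0.05, ** p < 0.01\n")
  invisible(x)
}

#' Export a correlation matrix as a data frame
#'
#' Lower-triangular layout with significance stars, suitable for writing to
#' CSV.
#'
#' @param x A [correlation_matrix()] result.
#' @param digits Rounding for the displayed coefficients.
#' @return A data frame.
#' @export
correlation_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "trait_correlations"))
  k <- nrow(x$r)
  out <- matrix("", k, k - 1, dimnames = list(rownames(x$r),
                                              colnames(x$r)[-k]))
  for (i in 2:k) for (j in 1:(i - 1)) {
    out[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"),
                        x$stars[i, j])
  }
  data.frame(trait = rownames(out), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
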