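## Magnitude-frequency spectrum of coupling values and its power-law fit.

#' Fit a power law to the coupling-magnitude spectrum
#'
#' Histograms the off-diagonal coupling values into linear bins and fits
#' the occurrence frequency as \eqn{y = a x^{-b}} by least squares on
#' \eqn{\log_{10}} frequency versus \eqn{\log_{10}} bin center, over the
#' nonempty bins inside `fit_range`.
#'
#' @param coupling A `coupling_matrix`, or a numeric vector of coupling
#'   values.
#' @param bin_width Linear bin width (default 0.1).
#' @param fit_range Optional numeric length-2 interval of bin centers to
#'   fit over; default all nonempty bins.
#' @return Object of class `spectrum_fit`: list with `a` (prefactor), `b`
#'   (positive exponent), `r_squared`, `bin_centers`, `frequencies`,
#'   `bin_edges`, `fit_range` and `n_bins_fit`.
#' @export
fit_powerlaw_spectrum <- function(coupling, bin_width = 0.1,
                                  fit_range = NULL) {
  v <- if (inherits(coupling, "coupling_matrix"))
    coupling_values(coupling) else as.numeric(coupling)
  v <- v[is.finite(v)]
  if (length(v) < 3L) stop("fit error: need at least 3 values")
  lo <- min(v)
  edges <- seq(lo, max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  centers <- h$mids
  freq <- h$counts
  use <- freq > 0 & centers > 0
  if (!is.null(fit_range))
    use <- use & centers >= fit_range[1] & centers <= fit_range[2]
  if (sum(use) < 3L)
    stop("fit error: fewer than 3 usable bins in fit range")
  fit <- stats::lm(log10(freq[use]) ~ log10(centers[use]))
  co <- stats::coef(fit)
  structure(list(a = unname(10^co[1]), b = unname(-co[2]),
                 r_squared = summary(fit)$r.squared,
                 bin_centers = centers, frequencies = freq,
                 bin_edges = edges,
                 fit_range = fit_range %||% range(centers[use]),
                 n_bins_fit = sum(use)),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "<spectrum_fit> y = a x^-b with a = %.3g, b = %.3f (R^2 = %.3f) over %d bins\n",
    x$a, x$b, x$r_squared, x$n_bins_fit))
  invisible(x)
}
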