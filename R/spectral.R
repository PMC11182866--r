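#' Per-depth reflectance spectra of a scanned core face
#'
#' @param depth numeric depths (cm), one per scan row.
#' @param wavelength strictly increasing wavelength grid (nm); must cover the
#'   continuum endpoints and the 655-680 nm trough window to compute the
#'   chloropigment index.
#' @param reflectance matrix of reflectance in (0, 1], rows = depths,
#'   columns = wavelengths.
#' @return An object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(depth, wavelength, reflectance) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(depth) ||
      ncol(reflectance) != length(wavelength))
    stop("reflectance must be length(depth) x length(wavelength)", call. = FALSE)
  check_increasing(wavelength, "wavelength")
  if (any(reflectance < 0, na.rm = TRUE))
    stop("negative reflectance", call. = FALSE)
  structure(list(depth = as.numeric(depth),
                 wavelength = as.numeric(wavelength),
                 reflectance = unname(reflectance)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("Spectral cube: %d depths (%.2f-%.2f cm), %d bands (%g-%g nm)\n",
              length(x$depth), min(x$depth), max(x$depth),
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Relative absorption band depth (RABD) chloropigment index
#'
#' Computes the continuum-normalized depth of the chlorophyll absorption
#' trough: the trough minimum R(l_min) is located on the native wavelength
#' grid within `trough`, the continuum at l_min is the band-count-weighted
#' mean of the endpoint reflectances, `(X * R_left + Y * R_right) / (X + Y)`
#' with X the number of bands between l_min and the right endpoint and Y the
#' number between the left endpoint and l_min (equal, on a uniform grid, to
#' linear interpolation of the endpoints at l_min), and the index is
#' continuum / R(l_min). A flat spectrum gives exactly 1; deeper troughs give
#' larger values.
#'
#' @param wavelength wavelength grid (nm), strictly increasing.
#' @param reflectance reflectance at each wavelength (> 0 at the trough).
#' @param left_nm,right_nm continuum endpoints (nm); must be on the grid span.
#' @param trough two-element window (nm) searched for the reflectance minimum.
#' @return The RABD index (unitless, >= 0).
#' @examples
#' wl <- 590:730
#' r <- rep(0.5, length(wl)); r[wl == 670] <- 0.4
#' rabd_index(wl, r)  # 1.25
#' @export
rabd_index <- function(wavelength, reflectance,
                       left_nm = 590, right_nm = 730,
                       trough = c(655, 680)) {
  check_increasing(wavelength, "wavelength")
  if (left_nm < wavelength[1] || right_nm > wavelength[length(wavelength)])
    stop("continuum endpoints outside the wavelength grid", call. = FALSE)
  i_left <- which.min(abs(wavelength - left_nm))
  i_right <- which.min(abs(wavelength - right_nm))
  in_trough <- which(wavelength >= trough[1] & wavelength <= trough[2])
  if (!length(in_trough))
    stop("wavelength grid does not cover the trough window", call. = FALSE)
  i_min <- in_trough[which.min(reflectance[in_trough])]
  r_min <- reflectance[i_min]
  if (!is.finite(r_min) || r_min <= 0)
    stop("non-positive reflectance at the trough minimum", call. = FALSE)
  x <- i_right - i_min   # bands between minimum and right endpoint
  y <- i_min - i_left    # bands between left endpoint and minimum
  continuum <- (x * reflectance[i_left] + y * reflectance[i_right]) / (x + y)
  continuum / r_min
}

#' RABD index for every depth of a spectral cube
#'
#' @param cube a [spectral_cube()].
#' @param smooth_k optional odd window for a [moving_average()] of the index
#'   series (`NULL` for none).
#' @inheritParams rabd_index
#' @return Data frame `depth_cm`, `rabd`, and (when smoothing) `rabd_smoothed`.
#' @export
rabd_series <- function(cube, left_nm = 590, right_nm = 730,
                        trough = c(655, 680), smooth_k = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  idx <- apply(cube$reflectance, 1, function(r)
    rabd_index(cube$wavelength, r, left_nm, right_nm, trough))
  out <- data.frame(depth_cm = cube$depth, rabd = idx)
  if (!is.null(smooth_k))
    out$rabd_smoothed <- moving_average(idx, k = smooth_k)
  out
}

#' Centred moving average with truncated edge windows
#'
#' A k-point centred window mean; at the series ends the window is truncated
#' to the available samples, so a k = 13 smoother of the chloropigment
#' profile stays defined to the core top and bottom.
#'
#' @param x numeric series.
#' @param k odd window length, `1 <= k <= length(x)`.
#' @return Smoothed series of the same length.
#' @examples
#' moving_average(c(1, 2, 3), k = 3)  # 1.5 2.0 2.5
#' @export
moving_average <- function(x, k = 13L) {
  n <- length(x)
  if (k %% 2 == 0) stop("`k` must be odd", call. = FALSE)
  if (k < 1 || k > n) stop("`k` must be between 1 and length(x)", call. = FALSE)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Bin a depth series into fixed-width depth intervals
#'
#' Values whose mid-depth falls in the half-open bin `[i*bin, (i+1)*bin)` are
#' averaged; empty bins are returned with `NA` and flagged.
#'
#' @param depth sample mid-depths (cm).
#' @param value values to bin.
#' @param bin_cm bin width (cm), > 0.
#' @return Data frame `bin_top_cm`, `bin_bottom_cm`, `depth_cm` (bin centre),
#'   `value`, `n`, `empty`.
#' @export
bin_by_depth <- function(depth, value, bin_cm) {
  if (bin_cm <= 0) stop("`bin_cm` must be > 0", call. = FALSE)
  idx <- floor(depth / bin_cm)
  bins <- seq(min(idx), max(idx))
  means <- vapply(bins, function(b) {
    v <- value[idx == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  counts <- vapply(bins, function(b) sum(idx == b), integer(1))
  data.frame(bin_top_cm = bins * bin_cm,
             bin_bottom_cm = (bins + 1) * bin_cm,
             depth_cm = (bins + 0.5) * bin_cm,
             value = means, n = counts, empty = counts == 0L)
}
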