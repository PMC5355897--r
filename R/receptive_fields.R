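#' @keywords internal
#' Centered pixel coordinates for an H x W grid.
#' x increases to the right, y increases upward; for even dimensions the
#' coordinates are half-integers so no pixel sits exactly on the center axes.
rf_coords <- function(H, W) {
  x <- matrix(rep(seq_len(W) - (W + 1) / 2, each = H), nrow = H)
  y <- matrix(rep((H + 1) / 2 - seq_len(H), times = W), nrow = H)
  list(x = x, y = y)
}

new_rf_kernel <- function(kind, grid, params) {
  stopifnot(all(is.finite(grid)))
  structure(c(list(kind = kind, grid = grid), params),
            class = "lif_rf_kernel")
}

#' Rectangular edge-detecting receptive field
#'
#' Two adjacent rectangular ON and OFF regions of equal size: weights are +1
#' on the ON half-plane and -1 on the OFF half-plane of the axis rotated by
#' `orientation` about the grid center. At `orientation = 0` the ON region is
#' the top half of the grid. For even grid dimensions the two areas are
#' exactly equal; for odd dimensions they differ by at most one pixel row.
#'
#' @param H,W Grid height and width in pixels, both `>= 2`.
#' @param orientation Rotation of the ON/OFF boundary normal (radian).
#' @return An object of class `lif_rf_kernel` with `kind = "edge"`.
#' @export
#' @examples
#' k <- make_edge_kernel(4, 4)
#' sum(k$grid)  # 0: equal ON and OFF areas
make_edge_kernel <- function(H, W, orientation = 0) {
  if (H < 2 || W < 2) stop("degenerate kernel size: need H, W >= 2")
  cc <- rf_coords(H, W)
  d <- cc$y * cos(orientation) + cc$x * sin(orientation)
  grid <- ifelse(d >= 0, 1, -1)
  new_rf_kernel("edge", grid, list(orientation = orientation))
}

#' Center-surround (difference-of-Gaussians) receptive field
#'
#' The kernel is the difference of two isotropic Gaussians centered on the
#' grid, `G(sigma_center) - G(sigma_surround)`, each normalized to unit
#' discrete sum so that the kernel weights sum to zero (balanced
#' center-surround). This is the receptive field type found in the retina
#' and lateral geniculate nucleus. For an OFF-center field the kernel is
#' negated elementwise.
#'
#' @param H,W Grid size (pixels).
#' @param sigma_center,sigma_surround Gaussian widths (pixels), with
#'   `sigma_center < sigma_surround`.
#' @param on_center Logical; `FALSE` gives the OFF-center (negated) field.
#' @return An object of class `lif_rf_kernel` with `kind = "dog"`.
#' @export
make_dog_kernel <- function(H, W, sigma_center = 1, sigma_surround = 2,
                            on_center = TRUE) {
  if (!(sigma_center < sigma_surround)) {
    stop("'sigma_center' must be smaller than 'sigma_surround'")
  }
  cc <- rf_coords(H, W)
  r2 <- cc$x^2 + cc$y^2
  gc <- exp(-r2 / (2 * sigma_center^2))
  gs <- exp(-r2 / (2 * sigma_surround^2))
  grid <- gc / sum(gc) - gs / sum(gs)
  if (!on_center) grid <- -grid
  new_rf_kernel("dog", grid,
                list(sigma_center = sigma_center,
                     sigma_surround = sigma_surround, on_center = on_center))
}

#' Orientation-selective (Gabor) receptive field
#'
#' An oriented Gaussian envelope multiplied by a cosine carrier:
#' `exp(-x'^2 / (2 sigma_x^2) - y'^2 / (2 sigma_y^2)) *
#'  cos(2 pi x' / wavelength + phase)`,
#' where `(x', y')` are the pixel coordinates rotated by `orientation` about
#' the grid center. This is the classic model of simple-cell receptive fields
#' in primary visual cortex.
#'
#' @param H,W Grid size (pixels).
#' @param orientation Preferred orientation (radian).
#' @param sigma_x,sigma_y Envelope widths along and across the carrier
#'   (pixels).
#' @param wavelength Carrier wavelength (pixels), `> 0`.
#' @param phase Carrier phase (radian).
#' @return An object of class `lif_rf_kernel` with `kind = "gabor"`.
#' @export
make_gabor_kernel <- function(H, W, orientation = 0, sigma_x = W / 8,
                              sigma_y = H / 8, wavelength = W / 8, phase = 0) {
  if (wavelength <= 0) stop("'wavelength' must be > 0")
  cc <- rf_coords(H, W)
  xr <- cc$x * cos(orientation) + cc$y * sin(orientation)
  yr <- -cc$x * sin(orientation) + cc$y * cos(orientation)
  grid <- exp(-xr^2 / (2 * sigma_x^2) - yr^2 / (2 * sigma_y^2)) *
    cos(2 * pi * xr / wavelength + phase)
  new_rf_kernel("gabor", grid,
                list(orientation = orientation, sigma_x = sigma_x,
                     sigma_y = sigma_y, wavelength = wavelength,
                     phase = phase))
}

#' Validate a grayscale stimulus
#'
#' @param image Numeric matrix of intensities in `[0, 1]`.
#' @return The matrix, with class `lif_stimulus` attached.
#' @export
visual_stimulus <- function(image) {
  image <- as.matrix(image)
  if (!is.numeric(image) || any(!is.finite(image))) {
    stop("stimulus must be a finite numeric matrix")
  }
  if (any(image < 0) || any(image > 1)) {
    stop("stimulus intensities must lie in [0, 1]")
  }
  class(image) <- c("lif_stimulus", class(image))
  image
}

#' Sinusoidal grating stimulus
#'
#' Convenience generator of a full-contrast grating,
#' `0.5 + 0.5 * cos(2 pi x' / wavelength + phase)` with `x'` the coordinate
#' rotated by `orientation`, for probing receptive-field tuning.
#'
#' @param H,W Grid size (pixels).
#' @param orientation Grating orientation (radian).
#' @param wavelength Grating wavelength (pixels).
#' @param phase Phase (radian).
#' @return A stimulus matrix with intensities in `[0, 1]`.
#' @export
make_grating <- function(H, W, orientation = 0, wavelength = W / 8, phase = 0) {
  cc <- rf_coords(H, W)
  xr <- cc$x * cos(orientation) + cc$y * sin(orientation)
  visual_stimulus(0.5 + 0.5 * cos(2 * pi * xr / wavelength + phase))
}

#' Instantaneous receptive-field response
#'
#' The response is the weight-intensity inner product divided by the pixel
#' count, so that gains transfer across grid sizes. It depends only on the
#' current frame: there is no temporal kernel.
#'
#' @param kernel A `lif_rf_kernel`.
#' @param stim A stimulus matrix with the same dimensions as the kernel grid.
#' @return A dimensionless scalar response.
#' @export
field_response <- function(kernel, stim) {
  stim <- unclass(stim)
  if (!identical(dim(kernel$grid), dim(stim))) {
    stop("stimulus dimensions ", paste(dim(stim), collapse = "x"),
         " do not match kernel grid ",
         paste(dim(kernel$grid), collapse = "x"))
  }
  sum(kernel$grid * stim) / length(stim)
}

#' Read a grayscale stimulus from a PNG file
#'
#' RGB images are converted to luminance (Rec. 709 weights); an alpha
#' channel, if present, is ignored.
#'
#' @param path Path to a PNG file.
#' @return A stimulus matrix with intensities in `[0, 1]`.
#' @export
read_stimulus_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("reading PNG stimuli requires the 'png' package")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  visual_stimulus(img)
}

#' Convert a response to a spike (one step)
#'
#' Half-wave rectified Bernoulli conversion: the probability of a spike this
#' step is `min(1, max(0, response) * gain * dt)`, mirroring the per-step
#' construction of the Poisson generator. Nonpositive responses never fire.
#'
#' @param response Dimensionless response from [field_response()].
#' @param gain Firing-rate gain (Hz per unit response), `>= 0`.
#' @param dt Time step (second).
#' @return Logical; consumes one uniform draw from the R random stream.
#' @export
encode_response <- function(response, gain, dt) {
  stopifnot(gain >= 0, dt > 0)
  p <- min(1, max(0, response) * gain * dt)
  stats::runif(1) < p
}
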