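# FPM image formation: angled plane-wave illumination from an LED array,
# spectrum shift, pupil filtering, and intensity capture on a low-resolution
# sensor grid. Units: lengths in micrometers unless a field is suffixed _mm;
# spatial frequencies in cycles/um (no 2*pi; the 2*pi enters only inside the
# modulation exponent).

#' Programmable LED illumination array
#'
#' Describes the geometry of the LED matrix used as the microscope light
#' source. Odd `rows`/`cols` place one LED on the optical axis; that LED
#' provides normal incidence (zero illumination wave vector).
#'
#' @param rows,cols number of LEDs per side.
#' @param pitch_mm center-to-center LED spacing in millimeters.
#' @param distance_mm distance from the array plane to the sample, mm.
#' @param center_offset_mm lateral offset `(x, y)` of the array center from
#'   the optical axis, mm.
#' @param wavelengths_um named numeric vector of illumination wavelengths in
#'   micrometers, one per color channel.
#' @returns an object of class `led_array`.
#' @export
#' @examples
#' led_array(13, 13)
led_array <- function(rows = 13L, cols = 13L, pitch_mm = 4, distance_mm = 80,
                      center_offset_mm = c(0, 0),
                      wavelengths_um = c(red = 0.632, green = 0.532, blue = 0.470)) {
  stopifnot(rows >= 1, cols >= 1, distance_mm > 0, pitch_mm > 0,
            all(wavelengths_um > 0), length(center_offset_mm) == 2)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_mm = pitch_mm, distance_mm = distance_mm,
                 center_offset_mm = center_offset_mm,
                 wavelengths_um = wavelengths_um),
            class = "led_array")
}

#' @export
print.led_array <- function(x, ...) {
  cat(sprintf("<led_array> %dx%d LEDs, pitch %.3g mm, distance %.3g mm\n",
              x$rows, x$cols, x$pitch_mm, x$distance_mm))
  invisible(x)
}

#' Illumination wave vector for one LED
#'
#' The LED at `(led_row, led_col)` illuminates the sample with a plane wave
#' whose transverse spatial frequency is `sin(angle) / lambda` per axis,
#' with `sin(angle) = offset / sqrt(offset^2 + distance^2)` from exact
#' trigonometry. The on-axis LED of an odd-sized centered array yields
#' `(0, 0)`.
#'
#' @param array an [led_array()].
#' @param led_row,led_col 1-based LED indices.
#' @param channel color channel name matching `array$wavelengths_um`.
#' @returns object of class `wave_vector` with fields `kx`, `ky`
#'   (cycles/um), `led_row`, `led_col`, `channel`, `wavelength_um`.
#' @export
compute_wave_vector <- function(array, led_row, led_col, channel = "green") {
  if (led_row < 1 || led_row > array$rows || led_col < 1 || led_col > array$cols)
    stop("LED index out of range: (", led_row, ", ", led_col, ")")
  lambda <- array$wavelengths_um[[channel]]
  if (is.null(lambda)) stop("unknown channel: ", channel)
  # mm cancel in offset / hypotenuse
  off_x <- (led_col - (array$cols + 1) / 2) * array$pitch_mm + array$center_offset_mm[1]
  off_y <- (led_row - (array$rows + 1) / 2) * array$pitch_mm + array$center_offset_mm[2]
  d <- array$distance_mm
  sin_ax <- off_x / sqrt(off_x^2 + d^2)
  sin_ay <- off_y / sqrt(off_y^2 + d^2)
  structure(list(kx = sin_ax / lambda, ky = sin_ay / lambda,
                 led_row = as.integer(led_row), led_col = as.integer(led_col),
                 channel = channel, wavelength_um = lambda),
            class = "wave_vector")
}

#' Complex optical field on a square grid
#'
#' @param values square complex (or real) matrix of even side; the complex
#'   amplitude transmittance/field o(r).
#' @param pixel_pitch_um physical sampling pitch in micrometers.
#' @param channel optional color channel tag.
#' @returns object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_pitch_um, channel = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("field grid must be square")
  if (nrow(values) %% 2 != 0) stop("field side must be even")
  if (pixel_pitch_um <= 0) stop("pixel pitch must be positive")
  structure(list(values = values + 0i, pixel_pitch_um = pixel_pitch_um,
                 channel = channel),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %dx%d, pitch %.3g um%s\n", nrow(x$values),
              ncol(x$values), x$pixel_pitch_um,
              if (is.null(x$channel)) "" else paste0(", channel ", x$channel)))
  invisible(x)
}

#' Coherent transfer function (pupil) of the objective
#'
#' An ideal binary circular pupil: pass-band is the disk of spatial-frequency
#' radius `na / wavelength` (cycles/um) centered at zero frequency.
#'
#' @param na numerical aperture, 0 < na < 1.
#' @param wavelength_um illumination wavelength, um.
#' @param grid_side side of the frequency grid the CTF is evaluated on.
#' @param pixel_pitch_um pitch of the *spatial* grid the spectrum came from.
#' @returns object of class `fpm_ctf` with the defining parameters and a
#'   `radius_bins` entry (pupil radius in frequency bins).
#' @export
make_ctf <- function(na, wavelength_um, grid_side, pixel_pitch_um) {
  stopifnot(na > 0, na < 1, wavelength_um > 0, grid_side >= 2, pixel_pitch_um > 0)
  dk <- 1 / (grid_side * pixel_pitch_um)            # bin spacing, cycles/um
  structure(list(na = na, wavelength_um = wavelength_um,
                 grid_side = as.integer(grid_side),
                 pixel_pitch_um = pixel_pitch_um,
                 cutoff = na / wavelength_um,
                 radius_bins = (na / wavelength_um) / dk),
            class = "fpm_ctf")
}

# Binary pupil mask on an arbitrary grid side sharing the CTF's bin spacing.
ctf_mask <- function(ctf, side = ctf$grid_side) {
  disk_mask(side, ctf$radius_bins)
}

#' Modulate a sample field by angled plane-wave illumination
#'
#' Multiplies the sample transmittance o(r) by the unit-amplitude tilted
#' plane wave `exp(j 2 pi (kx x + ky y))`, producing the emergent field
#' e(r). Magnitudes are unchanged pointwise; the spectrum shifts by the
#' illumination wave vector.
#'
#' @param sample a [complex_field()].
#' @param k a [compute_wave_vector()] result (or list with `kx`, `ky`).
#' @returns the modulated [complex_field()].
#' @export
modulate_sample <- function(sample, k) {
  n <- nrow(sample$values)
  coord <- (seq_len(n) - 1) * sample$pixel_pitch_um
  ramp_x <- exp(2i * pi * k$kx * coord)   # along columns (x)
  ramp_y <- exp(2i * pi * k$ky * coord)   # along rows (y)
  out <- sample
  out$values <- sample$values * (ramp_y %o% ramp_x)
  out
}

#' Apply the coherent transfer function to a spectrum
#'
#' Binary pupil: frequency components outside the pass disk are zeroed,
#' components inside are unchanged.
#'
#' @param shifted_spectrum centered complex spectrum matrix.
#' @param ctf an [make_ctf()] pupil; its grid side must match.
#' @returns filtered spectrum matrix.
#' @export
apply_ctf <- function(shifted_spectrum, ctf) {
  if (nrow(shifted_spectrum) != ctf$grid_side ||
      ncol(shifted_spectrum) != ctf$grid_side)
    stop("spectrum grid does not match CTF grid")
  shifted_spectrum * ctf_mask(ctf)
}

#' Sensor capture: band-limited downsampling and intensity detection
#'
#' Models the low-resolution sensor by cropping the central
#' `(side/ratio)^2` block of the (already pupil-filtered) centered
#' spectrum, inverse transforming on the small grid, and taking the squared
#' magnitude. Spectral cropping (not spatial decimation) is the correct
#' model for diffraction-limited imaging onto a coarser sensor.
#'
#' @param filtered_spectrum centered complex spectrum on the high-res grid.
#' @param ratio integer downsampling ratio; must divide the grid side.
#' @returns nonnegative real intensity matrix of side `side/ratio`.
#' @export
capture_intensity <- function(filtered_spectrum, ratio = 1L) {
  n <- nrow(filtered_spectrum)
  if (n %% ratio != 0) stop("ratio must divide the high-res grid side")
  m <- n %/% ratio
  c_hi <- n / 2 + 1
  idx <- (c_hi - m / 2):(c_hi + m / 2 - 1)
  g <- stats::fft(ifftshift2(filtered_spectrum[idx, idx]), inverse = TRUE) / n^2
  Mod(g)^2
}

# Integer-bin offset of an illumination wave vector on a grid with bin
# spacing 1/(side * pitch). Nearest-bin rounding; the sub-bin residue is
# ignored (standard discrete-FPM practice).
k_to_bins <- function(k, side, pixel_pitch_um) {
  dk <- 1 / (side * pixel_pitch_um)
  c(sx = round(k$kx / dk), sy = round(k$ky / dk))
}

# One forward frame from a centered high-res spectrum. The emergent
# spectrum O(k - kn) restricted to the pupil equals, on the sensor band,
# the window of O centered at -kn bins.
forward_frame <- function(spec_hi, s_bins, pupil_lowres, ratio) {
  n <- nrow(spec_hi)
  m <- n %/% ratio
  c_hi <- n / 2 + 1
  iy <- (c_hi - s_bins[["sy"]] - m / 2):(c_hi - s_bins[["sy"]] + m / 2 - 1)
  ix <- (c_hi - s_bins[["sx"]] - m / 2):(c_hi - s_bins[["sx"]] + m / 2 - 1)
  if (min(iy) < 1 || max(iy) > n || min(ix) < 1 || max(ix) > n)
    stop("illumination wave vector shifts the pupil outside the sampled spectrum")
  g_low <- spec_hi[iy, ix] * pupil_lowres
  g <- stats::fft(ifftshift2(g_low), inverse = TRUE) / n^2
  Mod(g)^2
}

#' Simulate a full FPM acquisition stack
#'
#' Runs the forward model for every LED and channel: tilt-induced spectrum
#' shift, pupil filtering, band-limited sensor capture, and optional noise.
#' Frames are ordered channel-major, then row-major over LEDs (top-left
#' first); the on-axis LED of an odd array is the center element.
#'
#' @param sample_per_channel named list of [complex_field()]s, one per
#'   channel to simulate.
#' @param array an [led_array()].
#' @param na objective numerical aperture (a per-channel CTF is derived
#'   from this and each channel's wavelength). Alternatively pass
#'   `ctf_per_channel`, a named list of [make_ctf()] objects.
#' @param ratio integer high-res/low-res side ratio.
#' @param noise optional list with elements `gaussian_sd` (additive read
#'   noise on intensity) and/or `poisson_photons` (mean photon count at
#'   unit intensity for shot noise). `NULL` (default) = noiseless.
#' @param seed integer seed used only when `noise` is active.
#' @param ctf_per_channel optional explicit per-channel pupils.
#' @returns object of class `fpm_stack`: list with `frames` (each frame a
#'   list `intensity`, `led_row`, `led_col`, `led_index`, `channel`,
#'   `wavelength_um`, `kx`, `ky`), `lowres_side`, `ratio`, `highres_side`,
#'   `pixel_pitch_um`, `na`, `array`.
#' @export
#' @examples
#' o <- complex_field(matrix(1, 64, 64), 0.4)
#' st <- simulate_stack(list(green = o), led_array(3, 3), na = 0.1, ratio = 2)
#' length(st$frames)  # 9
simulate_stack <- function(sample_per_channel, array, na = 0.1, ratio = 4L,
                           noise = NULL, seed = NULL, ctf_per_channel = NULL) {
  channels <- names(sample_per_channel)
  if (is.null(channels) || any(channels == ""))
    stop("sample_per_channel must be a named list of complex_field objects")
  n <- nrow(sample_per_channel[[1]]$values)
  pitch <- sample_per_channel[[1]]$pixel_pitch_um
  if (n %% ratio != 0) stop("ratio must divide the high-res grid side")
  m <- n %/% ratio
  if (!is.null(noise) && !is.null(seed)) set.seed(seed)

  frames <- vector("list", length(channels) * array$rows * array$cols)
  fi <- 0L
  for (ch in channels) {
    fld <- sample_per_channel[[ch]]
    if (is.null(fld)) stop("missing sample field for channel ", ch)
    if (nrow(fld$values) != n || fld$pixel_pitch_um != pitch)
      stop("all channel fields must share grid and pitch")
    ctf <- if (!is.null(ctf_per_channel)) {
      if (is.null(ctf_per_channel[[ch]])) stop("missing CTF for channel ", ch)
      ctf_per_channel[[ch]]
    } else make_ctf(na, array$wavelengths_um[[ch]], n, pitch)
    pupil_low <- ctf_mask(ctf, m)
    spec <- fft2c(fld$values)
    for (r in seq_len(array$rows)) for (cc in seq_len(array$cols)) {
      k <- compute_wave_vector(array, r, cc, ch)
      s <- k_to_bins(k, n, pitch)
      int <- forward_frame(spec, s, pupil_low, ratio)
      if (!is.null(noise)) {
        if (!is.null(noise$poisson_photons)) {
          ph <- noise$poisson_photons
          int <- matrix(stats::rpois(length(int), int * ph) / ph, m, m)
        }
        if (!is.null(noise$gaussian_sd))
          int <- int + matrix(stats::rnorm(length(int), 0, noise$gaussian_sd), m, m)
        int[int < 0] <- 0
      }
      fi <- fi + 1L
      frames[[fi]] <- list(intensity = int, led_row = r, led_col = cc,
                           led_index = (r - 1L) * array$cols + cc,
                           channel = ch, wavelength_um = k$wavelength_um,
                           kx = k$kx, ky = k$ky)
    }
  }
  structure(list(frames = frames, lowres_side = m, ratio = as.integer(ratio),
                 highres_side = n, pixel_pitch_um = pitch,
                 na = if (is.null(ctf_per_channel)) na else NA_real_,
                 ctf_per_channel = ctf_per_channel,
                 array = array, channels = channels),
            class = "fpm_stack")
}

#' @export
print.fpm_stack <- function(x, ...) {
  cat(sprintf("<fpm_stack> %d frames (%s), low-res %d^2, ratio %d\n",
              length(x$frames), paste(x$channels, collapse = "/"),
              x$lowres_side, x$ratio))
  invisible(x)
}

# Frames of one channel, ordered by |k| ascending (brightfield first).
stack_channel_frames <- function(stack, channel, order_by_k = TRUE) {
  fr <- Filter(function(f) f$channel == channel, stack$frames)
  if (length(fr) == 0) stop("stack has no frames for channel ", channel)
  if (order_by_k) fr[order(vapply(fr, function(f) f$kx^2 + f$ky^2, 0))] else fr
}
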