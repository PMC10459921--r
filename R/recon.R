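# Iterative FPM reconstruction: alternating-projection amplitude
# replacement with frequency-domain sub-aperture stitching, per channel,
# followed by RGB synthesis.

#' Initialize the high-resolution spectrum estimate
#'
#' The starting guess is the Fourier-upsampled on-axis amplitude
#' `sqrt(I_1)` (zero phase): its centered low-res spectrum is embedded in
#' the center of the high-res frequency grid with the scale factor that
#' preserves field amplitude.
#'
#' @param stack an [simulate_stack()] acquisition stack.
#' @param channel channel to initialize.
#' @returns object of class `spectrum_estimate` with `spectrum` (centered,
#'   high-res), `channel`, `iteration`.
#' @export
initialize_spectrum <- function(stack, channel) {
  fr <- Filter(function(f) f$channel == channel, stack$frames)
  if (length(fr) == 0) stop("stack has no frames for channel ", channel)
  kk <- vapply(fr, function(f) f$kx^2 + f$ky^2, 0)
  on_axis <- fr[[which.min(kk)]]
  if (min(kk) > 1e-12)
    stop("stack has no on-axis frame for channel ", channel)
  m <- stack$lowres_side; n <- stack$highres_side
  s_low <- fft2c(sqrt(on_axis$intensity)) * (n^2 / m^2)
  spec <- matrix(0i, n, n)
  c_hi <- n / 2 + 1
  idx <- (c_hi - m / 2):(c_hi + m / 2 - 1)
  spec[idx, idx] <- s_low
  structure(list(spectrum = spec, channel = channel, iteration = 0L),
            class = "spectrum_estimate")
}

#' One sub-aperture amplitude-replacement update
#'
#' Extracts the pupil-supported sub-spectrum at the frame's illumination
#' offset, inverse-transforms to the sensor grid, replaces the magnitude
#' with `sqrt(I_n)` while keeping the phase, transforms back, and writes
#' the result into the pupil region of the spectrum. The spectrum outside
#' the shifted pupil disk is untouched.
#'
#' @param estimate a `spectrum_estimate`.
#' @param frame one element of `stack$frames` for the same channel.
#' @param stack the stack the frame came from (provides geometry).
#' @param ctf pupil as [make_ctf()] on the high-res grid; defaults to the
#'   stack's recorded NA and the frame wavelength.
#' @returns updated `spectrum_estimate`.
#' @export
update_subaperture <- function(estimate, frame, stack, ctf = NULL) {
  n <- stack$highres_side; m <- stack$lowres_side
  if (is.null(ctf)) ctf <- stack_ctf(stack, frame$channel)
  pupil <- ctf_mask(ctf, m)
  s <- k_to_bins(frame, n, stack$pixel_pitch_um)
  c_hi <- n / 2 + 1
  iy <- (c_hi - s[["sy"]] - m / 2):(c_hi - s[["sy"]] + m / 2 - 1)
  ix <- (c_hi - s[["sx"]] - m / 2):(c_hi - s[["sx"]] + m / 2 - 1)
  if (min(iy) < 1 || max(iy) > n || min(ix) < 1 || max(ix) > n)
    stop("frame wave vector falls outside the reconstruction grid")
  sub <- estimate$spectrum[iy, ix] * pupil
  g <- stats::fft(ifftshift2(sub), inverse = TRUE) / n^2
  mag <- Mod(g)
  phase_factor <- ifelse(mag > 0, g / mag, 1 + 0i)
  g_new <- sqrt(frame$intensity) * phase_factor
  sub_new <- fft2c(g_new) * (n^2 / m^2)
  out <- estimate
  region <- estimate$spectrum[iy, ix]
  region[pupil] <- sub_new[pupil]
  out$spectrum[iy, ix] <- region
  out
}

# Data-consistency error: sum over frames of ||sqrt(I_sim) - sqrt(I_meas)||^2
# normalized by sum ||sqrt(I_meas)||^2.
data_consistency_error <- function(spectrum, frames, stack, pupil_low) {
  n <- stack$highres_side
  num <- 0; den <- 0
  for (f in frames) {
    s <- k_to_bins(f, n, stack$pixel_pitch_um)
    sim <- forward_frame(spectrum, s, pupil_low, stack$ratio)
    num <- num + sum((sqrt(sim) - sqrt(f$intensity))^2)
    den <- den + sum(f$intensity)
  }
  num / den
}

#' Reconstruct one channel by alternating projections
#'
#' Sweeps all frames of the channel in low-to-high |k| order (brightfield
#' first) once per iteration, applying [update_subaperture()], and records
#' a per-iteration data-consistency error. Deterministic and seed-free.
#'
#' @param stack acquisition stack.
#' @param channel channel name.
#' @param n_iters maximum number of sweeps (default 15).
#' @param tol early stop when the relative improvement of the
#'   data-consistency error falls below this (default 1e-4).
#' @param overlap_warn warn if the spectral overlap of adjacent
#'   sub-apertures is below this fraction (default 0.35).
#' @returns object of class `recon_result`: `field` ([complex_field()]),
#'   `convergence_trace` (one error per completed iteration), `channel`.
#' @export
reconstruct_channel <- function(stack, channel, n_iters = 15L, tol = 1e-4,
                                overlap_warn = 0.35) {
  stopifnot(n_iters >= 1)
  fr <- stack_channel_frames(stack, channel)
  n <- stack$highres_side; m <- stack$lowres_side
  ctf <- stack_ctf(stack, channel)
  ov <- subaperture_overlap(stack, channel)
  if (!is.na(ov) && ov < overlap_warn)
    warning(sprintf("adjacent sub-aperture overlap %.0f%% < %.0f%%; recovery may fail",
                    100 * ov, 100 * overlap_warn))
  pupil_low <- ctf_mask(ctf, m)
  est <- initialize_spectrum(stack, channel)
  trace <- numeric(0)
  for (it in seq_len(n_iters)) {
    for (f in fr) est <- update_subaperture(est, f, stack, ctf)
    est$iteration <- it
    trace <- c(trace, data_consistency_error(est$spectrum, fr, stack, pupil_low))
    if (it >= 2) {
      rel <- (trace[it - 1] - trace[it]) / max(trace[it - 1], .Machine$double.eps)
      if (rel < tol) break
    }
  }
  field <- complex_field(ifft2c(est$spectrum), stack$pixel_pitch_um, channel)
  structure(list(field = field, convergence_trace = trace, channel = channel),
            class = "recon_result")
}

# Pupil for a channel: the stack's explicit per-channel CTF when it was
# simulated with one, else derived from the recorded objective NA.
stack_ctf <- function(stack, channel) {
  if (!is.null(stack$ctf_per_channel[[channel]]))
    return(stack$ctf_per_channel[[channel]])
  lam <- Filter(function(f) f$channel == channel, stack$frames)[[1]]$wavelength_um
  make_ctf(stack$na, lam, stack$highres_side, stack$pixel_pitch_um)
}

# Area-overlap fraction of two adjacent LEDs' pupil disks in the frequency
# plane (NA if the array has a single LED).
subaperture_overlap <- function(stack, channel) {
  a <- stack$array
  if (a$rows * a$cols < 2) return(NA_real_)
  r <- stack_ctf(stack, channel)$cutoff            # pupil radius, cycles/um
  mid_r <- (a$rows + 1) %/% 2; mid_c <- (a$cols + 1) %/% 2
  k0 <- compute_wave_vector(a, mid_r, mid_c, channel)
  k1 <- if (a$cols >= 2) compute_wave_vector(a, mid_r, mid_c + 1, channel)
        else compute_wave_vector(a, mid_r + 1, mid_c, channel)
  d <- sqrt((k1$kx - k0$kx)^2 + (k1$ky - k0$ky)^2)
  if (d >= 2 * r) return(0)
  area <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  area / (pi * r^2)
}

#' Reconstruct and synthesize an RGB image
#'
#' Reconstructs each of the three color channels independently, takes the
#' magnitudes, normalizes each channel to `[0, 1]` by its maximum, and
#' stacks them as an H x W x 3 array (R, G, B).
#'
#' @param stack acquisition stack holding `red`, `green`, `blue` frames.
#' @param n_iters sweeps per channel.
#' @param channels channel names mapped to R, G, B planes.
#' @returns list with `rgb` (H x W x 3 array in `[0, 1]`) and
#'   `per_channel` (named list of `recon_result`).
#' @export
reconstruct_rgb <- function(stack, n_iters = 15L,
                            channels = c("red", "green", "blue")) {
  missing <- setdiff(channels, unique(vapply(stack$frames, `[[`, "", "channel")))
  if (length(missing) > 0)
    stop("stack is missing channels: ", paste(missing, collapse = ", "))
  res <- lapply(channels, function(ch) reconstruct_channel(stack, ch, n_iters))
  names(res) <- channels
  n <- stack$highres_side
  img <- array(0, dim = c(n, n, 3))
  for (i in 1:3) {
    a <- Mod(res[[i]]$field$values)
    img[, , i] <- a / max(a, .Machine$double.eps)
  }
  list(rgb = img, per_channel = res)
}
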