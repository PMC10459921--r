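# Alternating-projection reconstruction: init, sub-aperture updates,
# convergence, round-trip fidelity, RGB synthesis.

make_small_stack <- function(seed = 3, side = 128, leds = 5, channel = "green") {
  sc <- generate_scene(detection_phantom_config(n_rbc = c(15, 25)), seed)
  o <- render_highres(sc, side, channel)
  st <- simulate_stack(stats::setNames(list(o), channel),
                       led_array(leds, leds), na = 0.1, ratio = 4)
  list(scene = sc, field = o, stack = st)
}

test_that("initialization is the upsampled on-axis amplitude", {
  s <- make_small_stack()
  est <- initialize_spectrum(s$stack, "green")
  expect_equal(est$iteration, 0L)
  expect_identical(dim(est$spectrum), c(128L, 128L))
  # determinism
  est2 <- initialize_spectrum(s$stack, "green")
  expect_identical(est$spectrum, est2$spectrum)
  # Fourier upsampling by zero padding is a trigonometric interpolant:
  # it reproduces the original samples exactly at their grid positions
  field <- fpmdetect:::ifft2c(est$spectrum)
  on_axis <- Filter(function(f) abs(f$kx) < 1e-12 && abs(f$ky) < 1e-12,
                    s$stack$frames)[[1]]
  a_low <- sqrt(on_axis$intensity)
  sampled <- Mod(field)[seq(1, 128, by = 4), seq(1, 128, by = 4)]
  expect_equal(sampled, a_low, tolerance = 1e-8)
  expect_error(initialize_spectrum(s$stack, "red"), "no frames")
})

test_that("constant sample yields a single central spectral peak", {
  o <- complex_field(matrix(0.8, 64, 64), 0.4)
  st <- simulate_stack(list(green = o), led_array(3, 3), na = 0.1, ratio = 2)
  est <- initialize_spectrum(st, "green")
  s <- Mod(est$spectrum)
  peak <- which(s == max(s), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(33, 33))
  expect_lt(sum(s) - max(s), 1e-6 * max(s))
})

test_that("sub-aperture update: fixed point, data consistency, locality", {
  s <- make_small_stack()
  st <- s$stack
  # converge first, then check the fixed-point property
  rr <- reconstruct_channel(st, "green", n_iters = 12)
  est <- fpmdetect:::fft2c(rr$field$values)
  est <- structure(list(spectrum = est, channel = "green", iteration = 12L),
                   class = "spectrum_estimate")
  fr <- st$frames[[7]]
  upd <- update_subaperture(est, fr, st)
  expect_equal(upd$spectrum, est$spectrum,
               tolerance = 1e-6 * max(Mod(est$spectrum)))
  # amplitude-replacement property: re-simulating the updated estimate
  # reproduces the measured frame up to the out-of-pupil residue of the
  # replaced field (exact only for band-limited fields, so compare on
  # the converged estimate where that residue is small)
  ctf <- make_ctf(st$na, fr$wavelength_um, st$highres_side, st$pixel_pitch_um)
  pupil_low <- fpmdetect:::ctf_mask(ctf, st$lowres_side)
  upd2 <- update_subaperture(est, fr, st)
  sim <- fpmdetect:::forward_frame(
    upd2$spectrum, fpmdetect:::k_to_bins(fr, st$highres_side,
                                         st$pixel_pitch_um),
    pupil_low, st$ratio)
  expect_equal(sim, fr$intensity, tolerance = 1e-3)
  raw <- initialize_spectrum(st, "green")
  upd2 <- update_subaperture(raw, fr, st)
  # locality: spectrum outside the shifted pupil disk is bit-identical
  sb <- fpmdetect:::k_to_bins(fr, st$highres_side, st$pixel_pitch_um)
  n <- st$highres_side; m <- st$lowres_side; c_hi <- n / 2 + 1
  mask <- matrix(FALSE, n, n)
  iy <- (c_hi - sb[["sy"]] - m / 2):(c_hi - sb[["sy"]] + m / 2 - 1)
  ix <- (c_hi - sb[["sx"]] - m / 2):(c_hi - sb[["sx"]] + m / 2 - 1)
  mask[iy, ix] <- fpmdetect:::ctf_mask(ctf, m)
  expect_identical(upd2$spectrum[!mask], raw$spectrum[!mask])
})

test_that("noiseless round trip recovers the amplitude", {
  s <- make_small_stack(seed = 3, leds = 7)
  expect_gt(fpmdetect:::subaperture_overlap(s$stack, "green"), 0.6)
  rr <- reconstruct_channel(s$stack, "green", n_iters = 10)
  a <- Mod(rr$field$values); g <- Mod(s$field$values)
  expect_gt(stats::cor(c(a), c(g)), 0.95)
  expect_lt(sqrt(mean((a - g)^2)) / sqrt(mean(g^2)), 0.1)
  # trace is non-increasing (1% slack) and one entry per iteration
  tr <- rr$convergence_trace
  expect_lte(length(tr), 10)
  if (length(tr) >= 2)
    expect_true(all(diff(tr) <= 0.01 * tr[-length(tr)]))
  # data consistency of the final estimate
  est <- fpmdetect:::fft2c(rr$field$values)
  fr <- fpmdetect:::stack_channel_frames(s$stack, "green")
  ctf <- make_ctf(0.1, 0.532, 128, s$field$pixel_pitch_um)
  pupil_low <- fpmdetect:::ctf_mask(ctf, 32)
  rel <- vapply(fr, function(f) {
    sim <- fpmdetect:::forward_frame(
      est, fpmdetect:::k_to_bins(f, 128, s$field$pixel_pitch_um),
      pupil_low, 4L)
    mean(abs(sqrt(sim) - sqrt(f$intensity))) / mean(sqrt(f$intensity))
  }, 0)
  expect_lt(mean(rel), 0.05)
})

test_that("reconstruction is deterministic and seed-free", {
  s <- make_small_stack(seed = 9, leds = 5)
  set.seed(1); r1 <- reconstruct_channel(s$stack, "green", n_iters = 3)
  set.seed(999); r2 <- reconstruct_channel(s$stack, "green", n_iters = 3)
  expect_identical(r1$field$values, r2$field$values)
})

test_that("single-frame stack with all-pass pupil returns the amplitude", {
  set.seed(5)
  o <- complex_field(matrix(runif(64^2, 0.3, 1), 64, 64), 2)
  ctf_all <- make_ctf(0.9, 0.2, 64, 2)  # radius beyond Nyquist
  st <- simulate_stack(list(green = o), led_array(1, 1), ratio = 1,
                       ctf_per_channel = list(green = ctf_all))
  rr <- reconstruct_channel(st, "green", n_iters = 1)
  expect_equal(Mod(rr$field$values), Mod(o$values), tolerance = 1e-8)
})

test_that("low-overlap geometry triggers the overlap warning", {
  o <- complex_field(matrix(runif(64^2, 0.5, 1), 64, 64), 0.4)
  # large LED pitch: sub-apertures overlap ~25%, below the 35% warning
  arr <- led_array(3, 3, pitch_mm = 10, distance_mm = 80)
  st <- simulate_stack(list(green = o), arr, na = 0.1, ratio = 2)
  expect_warning(reconstruct_channel(st, "green", n_iters = 1), "overlap")
})

test_that("rgb reconstruction stacks normalized channels", {
  sc <- generate_scene(detection_phantom_config(n_rbc = c(10, 15)), 4)
  fields <- lapply(stats::setNames(nm = c("red", "green", "blue")),
                   function(ch) render_highres(sc, 96, ch))
  st <- simulate_stack(fields, led_array(3, 3), na = 0.1, ratio = 4)
  out <- reconstruct_rgb(st, n_iters = 3)
  expect_equal(dim(out$rgb), c(96, 96, 3))
  expect_gte(min(out$rgb), 0); expect_lte(max(out$rgb), 1)
  # grayscale phantom identical in all channels: R = G = B
  og <- render_highres(sc, 96, NULL)
  stg <- simulate_stack(list(red = og, green = og, blue = og),
                        led_array(3, 3,
                                  wavelengths_um = c(red = 0.532,
                                                     green = 0.532,
                                                     blue = 0.532)),
                        na = 0.1, ratio = 4)
  outg <- reconstruct_rgb(stg, n_iters = 3)
  expect_equal(outg$rgb[, , 1], outg$rgb[, , 2], tolerance = 1e-9)
  expect_equal(outg$rgb[, , 2], outg$rgb[, , 3], tolerance = 1e-9)
  # missing channel errors
  expect_error(reconstruct_rgb(st2 <- simulate_stack(list(green = og),
                                                     led_array(3, 3),
                                                     ratio = 4)),
               "missing")
})
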