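# Forward model: wave vectors, modulation, pupil, capture, stacks.

test_that("wave vectors follow exact trigonometry and symmetry", {
  arr <- led_array(13, 13, pitch_mm = 4, distance_mm = 80)
  k0 <- compute_wave_vector(arr, 7, 7, "green")
  expect_equal(c(k0$kx, k0$ky), c(0, 0))
  # mirror-symmetric LEDs: equal magnitude, opposite sign
  ka <- compute_wave_vector(arr, 7, 10, "green")
  kb <- compute_wave_vector(arr, 7, 4, "green")
  expect_equal(ka$kx, -kb$kx)
  expect_equal(ka$ky, kb$ky)
  # hand trigonometry: offset 50 mm, distance 86.602 mm, lambda 0.5 um
  arr2 <- led_array(3, 3, pitch_mm = 50, distance_mm = 86.602,
                    wavelengths_um = c(green = 0.5))
  k <- compute_wave_vector(arr2, 2, 3, "green")
  expect_equal(k$kx, (50 / sqrt(50^2 + 86.602^2)) / 0.5, tolerance = 1e-5)
  expect_equal(k$kx, 1.0, tolerance = 1e-5)
  # magnitude bounded by 1/lambda
  kc <- compute_wave_vector(arr, 1, 1, "blue")
  expect_lt(sqrt(kc$kx^2 + kc$ky^2), 1 / 0.47)
  expect_error(compute_wave_vector(arr, 0, 1), "out of range")
  expect_error(compute_wave_vector(arr, 14, 1), "out of range")
})

test_that("modulation preserves magnitude and shifts the spectrum", {
  set.seed(11)
  n <- 32
  o <- complex_field(matrix(runif(n^2), n, n) *
                       exp(1i * matrix(runif(n^2, 0, 1), n, n)), 0.5)
  # identity illumination
  k0 <- list(kx = 0, ky = 0)
  expect_equal(modulate_sample(o, k0)$values, o$values)
  # unit-modulus factor
  dk <- 1 / (n * 0.5)
  k <- list(kx = 3 * dk, ky = -2 * dk)
  e <- modulate_sample(o, k)
  expect_equal(Mod(e$values), Mod(o$values), tolerance = 1e-12)
  # FFT shift theorem: spectrum circularly shifted by (3, -2) bins
  S_o <- fpmdetect:::fft2c(o$values)
  S_e <- fpmdetect:::fft2c(e$values)
  shifted <- S_o[(seq_len(n) - 1 - (-2)) %% n + 1, (seq_len(n) - 1 - 3) %% n + 1]
  # centered rep: shifting by +s bins moves content to higher index
  expect_equal(S_e, shifted, tolerance = 1e-8 * max(Mod(S_o)))
})

test_that("pupil filtering is an exact binary mask", {
  n <- 64
  ctf <- make_ctf(0.1, 0.532, n, 0.4)
  spec <- matrix(1 + 0i, n, n)
  out <- apply_ctf(spec, ctf)
  mask <- fpmdetect:::ctf_mask(ctf)
  expect_equal(out[mask], spec[mask])
  expect_true(all(out[!mask] == 0))
  # all-pass pupil: radius beyond Nyquist leaves spectrum unchanged
  ctf_all <- make_ctf(0.99, 0.2, n, 2)   # radius_bins > n/2
  expect_gt(ctf_all$radius_bins, n / 2)
  expect_equal(apply_ctf(spec, ctf_all), spec)
  # delta outside the disk is removed
  spec2 <- matrix(0i, n, n); spec2[1, 1] <- 1
  expect_true(all(apply_ctf(spec2, ctf) == 0))
  # pass-band energy of a flat spectrum = lattice points inside the disk
  expect_equal(sum(Mod(apply_ctf(spec, ctf))^2), sum(mask))
  expect_error(apply_ctf(matrix(0i, 32, 32), ctf), "does not match")
})

test_that("capture_intensity crops spectrally and stays nonnegative", {
  n <- 64
  # uniform unit field through an all-pass pupil at ratio 1
  o <- matrix(1 + 0i, n, n)
  I <- capture_intensity(fpmdetect:::fft2c(o), 1L)
  expect_equal(I, matrix(1, n, n), tolerance = 1e-12)
  # ratio r shrinks the grid and keeps intensity nonnegative and finite
  set.seed(12)
  f <- matrix(stats::rnorm(n^2) + 1i * stats::rnorm(n^2), n, n)
  I4 <- capture_intensity(fpmdetect:::fft2c(f), 4L)
  expect_equal(dim(I4), c(16, 16))
  expect_gte(min(I4), 0)
  expect_true(all(is.finite(I4)))
  expect_error(capture_intensity(fpmdetect:::fft2c(f), 5L), "divide")
})

test_that("simulate_stack honors frame count, ordering and determinism", {
  set.seed(13)
  o <- complex_field(matrix(runif(64^2, 0.5, 1), 64, 64), 0.4)
  arr <- led_array(3, 3)
  st <- simulate_stack(list(green = o, red = o, blue = o), arr,
                       na = 0.1, ratio = 2)
  expect_equal(length(st$frames), 3 * 3 * 3)
  # channel-major then row-major ordering
  expect_equal(vapply(st$frames[1:9], `[[`, "", "channel"), rep("green", 9))
  expect_equal(vapply(st$frames[1:3], `[[`, 0L, "led_row"), rep(1L, 3))
  expect_equal(vapply(st$frames[1:3], `[[`, 0L, "led_col"), 1:3)
  # all intensities nonnegative
  expect_true(all(vapply(st$frames, function(f) min(f$intensity) >= 0, TRUE)))
  # 1x1 array, all-pass pupil, ratio 1, no noise: frame == |o|^2
  arr1 <- led_array(1, 1)
  ctf_all <- make_ctf(0.9, 0.532, 64, 5)
  st1 <- simulate_stack(list(green = o), arr1, ratio = 1,
                        ctf_per_channel = list(green = ctf_all))
  expect_equal(st1$frames[[1]]$intensity, Mod(o$values)^2, tolerance = 1e-10)
  # determinism with noise and a seed
  noise <- list(gaussian_sd = 1e-3, poisson_photons = 1e4)
  sa <- simulate_stack(list(green = o), arr, ratio = 2, noise = noise, seed = 5)
  sb <- simulate_stack(list(green = o), arr, ratio = 2, noise = noise, seed = 5)
  expect_identical(sa, sb)
  expect_error(simulate_stack(list(o), arr), "named")
})

test_that("shift-then-filter equals modulate-then-transform-then-filter", {
  set.seed(14)
  n <- 64
  o <- complex_field(matrix(runif(n^2, 0.3, 1), n, n) *
                       exp(0.3i * matrix(rnorm(n^2), n, n)), 0.4)
  ctf <- make_ctf(0.1, 0.532, n, 0.4)
  pupil_low <- fpmdetect:::ctf_mask(ctf, n %/% 4)
  dk <- 1 / (n * 0.4)
  for (s in list(c(3, 2), c(-5, 0), c(0, 7))) {
    k <- list(kx = s[1] * dk, ky = s[2] * dk)
    # route 1: window extraction from the unmodulated spectrum
    I1 <- fpmdetect:::forward_frame(fpmdetect:::fft2c(o$values),
                                    c(sx = s[1], sy = s[2]), pupil_low, 4L)
    # route 2: modulate in space, transform, central pupil, capture
    e <- modulate_sample(o, k)
    spec_e <- fpmdetect:::fft2c(e$values)
    c_hi <- n / 2 + 1; m <- n %/% 4
    idx <- (c_hi - m / 2):(c_hi + m / 2 - 1)
    g <- stats::fft(fpmdetect:::ifftshift2(spec_e[idx, idx] * pupil_low),
                    inverse = TRUE) / n^2
    I2 <- Mod(g)^2
    expect_equal(I1, I2, tolerance = 1e-8 * max(I1))
  }
})

test_that("brightfield frames are brighter than darkfield frames", {
  set.seed(15)
  sc <- generate_scene(detection_phantom_config(n_rbc = 25, n_wbc = 1), 2)
  o <- render_highres(sc, 128, "green")
  st <- simulate_stack(list(green = o), led_array(5, 5), na = 0.1, ratio = 4)
  cutoff <- 0.1 / 0.532
  means <- vapply(st$frames, function(f) mean(f$intensity), 0)
  bright <- vapply(st$frames, function(f) sqrt(f$kx^2 + f$ky^2) <= cutoff, TRUE)
  expect_true(any(bright) && any(!bright))
  expect_gt(min(means[bright]), max(means[!bright]))
})

test_that("stack write/read round-trips through PGM + manifest", {
  set.seed(16)
  o <- complex_field(matrix(runif(32^2, 0.4, 1), 32, 32), 0.4)
  st <- simulate_stack(list(green = o), led_array(3, 3), na = 0.1, ratio = 2)
  dir <- withr::local_tempdir()
  write_stack(st, dir)
  st2 <- read_stack(dir)
  expect_equal(length(st2$frames), length(st$frames))
  expect_equal(st2$lowres_side, st$lowres_side)
  expect_equal(st2$array$rows, st$array$rows)
  for (i in c(1, 5, 9)) {
    expect_equal(st2$frames[[i]]$kx, st$frames[[i]]$kx, tolerance = 1e-12)
    # 16-bit quantization tolerance
    expect_equal(st2$frames[[i]]$intensity, st$frames[[i]]$intensity,
                 tolerance = 1e-3)
  }
})
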