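# Centered-spectrum FFT helpers. All spectra in this package are stored
# "centered": the zero-frequency bin sits at (N/2 + 1, N/2 + 1) for even N.

fftshift2 <- function(x) {
  n <- dim(x)
  stopifnot(length(n) == 2L)
  x[c((n[1] / 2 + 1):n[1], 1:(n[1] / 2)), c((n[2] / 2 + 1):n[2], 1:(n[2] / 2))]
}

# For even side lengths ifftshift == fftshift.
ifftshift2 <- fftshift2

# Forward transform to a centered spectrum (unnormalized, as stats::fft).
fft2c <- function(x) fftshift2(stats::fft(x))

# Inverse of fft2c with 1/N^2 normalization on the *stated* grid.
ifft2c <- function(s) stats::fft(ifftshift2(s), inverse = TRUE) / length(s)

#' Centered frequency-bin coordinates of an FFT grid
#'
#' @param n grid side (even).
#' @returns integer vector of bin offsets from the zero-frequency bin,
#'   `-n/2` to `n/2 - 1`, ordered to match a centered spectrum's rows/cols.
#' @keywords internal
freq_bins <- function(n) seq.int(-n / 2, n / 2 - 1)

# Circular disk mask on an n x n centered frequency grid.
# radius_bins is in frequency-bin units.
disk_mask <- function(n, radius_bins) {
  b <- freq_bins(n)
  outer(b, b, function(y, x) sqrt(x^2 + y^2)) <= radius_bins
}
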