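# Independent numerical oracles used to cross-check package routines.
# These deliberately avoid the code paths they verify.

# Power-series Bessel J_n(x), valid for |x| up to ~50 with 60 terms.
bessel_series <- function(order, x, nterms = 60) {
  out <- 0
  for (m in 0:(nterms - 1)) {
    out <- out + (-1)^m / (factorial(m) * factorial(m + order)) *
      (x / 2)^(2 * m + order)
  }
  out
}

# Brute-force evaluation of the sized Fourier sum: O(N^2 M^2).
direct_ft_2d <- function(field, input_step, output_step, out_size, k) {
  n <- nrow(field)
  s <- (seq_len(n) - 1 - (n - 1) / 2) * input_step
  x <- (seq_len(out_size) - 1 - (out_size - 1) / 2) * output_step
  out <- matrix(0 + 0i, out_size, out_size)
  for (m1 in seq_len(out_size)) for (m2 in seq_len(out_size)) {
    ph <- exp(1i * k * outer(s * x[m1], s * x[m2], `+`))
    out[m1, m2] <- sum(field * ph)
  }
  out
}

# Relative L2 distance between two complex arrays.
rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# Small default fixtures shared across tests.
fx_setup_low <- function() optical_setup(na = 0.5, wavelength = 632)
fx_setup_high <- function() optical_setup(na = 1.3, wavelength = 632,
                                          n_sample = 1.5)
fx_grid_small <- function(z = 0)
  sampling_grid(pupil_size = 65, out_size = 41, pixel_size = 120, z_planes = z)
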