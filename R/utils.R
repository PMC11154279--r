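# small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_equal = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (allow_equal) x >= lower && x <= upper else x > lower && x < upper
  if (!ok) {
    abort(sprintf("`%s` must lie in [%s, %s] (got %g).", name,
                  format(lower), format(upper), x))
  }
  invisible(x)
}

# log-log linear interpolation used for all attenuation tables; energies
# outside the tabulated range are an error (range contract of the tables)
loglog_interp <- function(energy_kev, table_e, table_v) {
  if (any(energy_kev < min(table_e) | energy_kev > max(table_e))) {
    abort(sprintf(
      "energy %g keV outside the tabulated range [%g, %g] keV",
      energy_kev[which(energy_kev < min(table_e) | energy_kev > max(table_e))][1],
      min(table_e), max(table_e)))
  }
  exp(approx(log(table_e), log(table_v), xout = log(energy_kev),
             ties = "ordered")$y)
}

# linear-convolution of a signal with a short symmetric kernel via FFT with
# zero padding; kernel given as numeric weights on the same pitch, assumed
# centred (odd length)
conv_same <- function(x, k) {
  nk <- length(k)
  stopifnot(nk %% 2L == 1L)
  n <- length(x) + nk - 1L
  nfft <- stats::nextn(n, 2)
  fx <- fft(c(x, numeric(nfft - length(x))))
  fk <- fft(c(k, numeric(nfft - nk)))
  full <- Re(fft(fx * fk, inverse = TRUE)) / nfft
  half <- (nk - 1L) %/% 2L
  full[(half + 1L):(half + length(x))]
}

# running mean with reflecting edges, for depth-curve smoothing
running_mean <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[(length(x) - half + 1L):length(x)]))
  as.numeric(stats::filter(xp, rep(1 / (2 * half + 1), 2 * half + 1),
                           sides = 2))[(half + 1L):(half + length(x))]
}
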