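#' Build a power-of-two frequency grid
#'
#' Constructs the tone set \eqn{f_i = f_0 / 2^i}, \eqn{0 \le i < n_f}, together
#' with the clock and record geometry implied by coherent sampling: the ADC
#' clock is \eqn{f_{clk} = 4 f_0} (so a quarter period of every tone is an
#' integer number of clock ticks) and one acquisition record spans exactly one
#' period of the lowest tone, \eqn{2^{n_f-1}/f_0}, i.e. \eqn{2^{n_f+1}}
#' samples.
#'
#' The logarithmic spacing gives a fixed resolution of
#' \eqn{\log_2(10) \approx 3.32} points per decade, enough for the smooth,
#' resonance-free dispersions typical of biological tissue.
#'
#' @param f0 Highest tone frequency in Hz. Must be positive.
#' @param nf Number of tones (positive integer).
#'
#' @return An object of class `"bis_grid"`: a list with elements `f0`, `nf`,
#'   `frequencies` (descending, Hz), `fclk` (Hz), `record_length` (samples),
#'   `global_period` (seconds) and `points_per_decade`.
#'
#' @examples
#' g <- build_grid(250e3, 8)
#' g$frequencies      # 250 kHz down to 1953.125 Hz
#' g$fclk             # 1 MHz
#' g$record_length    # 512 samples
#' @export
build_grid <- function(f0, nf) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("'f0' must be a single positive frequency in Hz")
  if (!is.numeric(nf) || length(nf) != 1L || nf < 1 || nf != round(nf))
    stop("'nf' must be a positive integer")
  nf <- as.integer(nf)
  structure(list(
    f0 = f0,
    nf = nf,
    frequencies = f0 / 2^(0:(nf - 1L)),
    fclk = 4 * f0,
    record_length = as.integer(2^(nf + 1L)),
    global_period = 2^(nf - 1L) / f0,
    points_per_decade = log2(10)
  ), class = "bis_grid")
}

#' @export
print.bis_grid <- function(x, ...) {
  cat(sprintf("Multitone frequency grid: nf = %d tones, f0 = %g Hz\n", x$nf, x$f0))
  cat(sprintf("  tones        : %s Hz\n", paste(format(x$frequencies, trim = TRUE), collapse = ", ")))
  cat(sprintf("  ADC clock    : %g Hz (4*f0)\n", x$fclk))
  cat(sprintf("  record       : %d samples = one period of the lowest tone (%g s)\n",
              x$record_length, x$global_period))
  cat(sprintf("  resolution   : %.3f points per decade\n", x$points_per_decade))
  invisible(x)
}
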