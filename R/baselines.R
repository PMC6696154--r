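# Reference estimators and the cost/acquisition-time model the multitone
# coherent-sampling method is compared against. On a noiseless linear
# time-invariant load all three estimators return the same spectrum; they
# differ in acquisition time and arithmetic, not in the ideal answer.

#' Single-tone coherent-sampling reference estimator
#'
#' The classical frequency sweep: each tone is excited alone with a unit
#' cosine, the response is sampled at that tone's own rate (in-phase, and
#' quarter-period delayed for quadrature) for one period of the lowest grid
#' tone, and averaged. No aliasing occurs, so no correction is needed —
#' at the price of an acquisition \eqn{n_f} times longer than the multitone
#' run (\eqn{n_f 2^{n_f-1}/f_0} in total).
#'
#' @param model Impedance model (or complex `Zi` vector).
#' @param grid A [build_grid()] object.
#' @return A `bis_spectrum`; the total simulated acquisition time (seconds)
#'   is attached as attribute `"acquisition_time_s"`.
#' @export
single_tone_coherent <- function(model, grid) {
  stopifnot(inherits(grid, "bis_grid"))
  Zi <- if (inherits(model, "bis_model")) evaluate_on_grid(model, grid) else as.complex(model)
  nf <- grid$nf
  re <- numeric(nf); im <- numeric(nf)
  for (i in seq_len(nf)) {
    fi <- grid$frequencies[i]
    ni <- 2^(nf - i)                  # samples of tone i in 2^(nf-1)/f0 seconds
    k <- 0:(ni - 1)
    tone <- function(t) Mod(Zi[i]) * cos(2 * pi * fi * t + Arg(Zi[i]))
    S <- mean(tone(k / fi))
    Q <- mean(tone((k + 0.25) / fi))  # quarter-period delay
    re[i] <- S
    im[i] <- -Q
  }
  sp <- new_spectrum(complex(real = re, imaginary = im), grid)
  attr(sp, "acquisition_time_s") <- nf * 2^(nf - 1) / grid$f0
  sp
}

#' Single-bin Fourier correlation reference estimator
#'
#' Multitone excitation analyzed the conventional way: the record is
#' correlated against cosine and sine at each grid tone and averaged
#' (exact-bin discrete Fourier estimate over whole coherent periods — no
#' window is needed since every tone completes an integer number of cycles in
#' the record). Amplitude-normalized so that under the default excitation the
#' estimate at tone \eqn{i} is \eqn{Z_i} directly. Costs
#' \eqn{n_f 2^{n_f+1}} multiplications where the decimation-accumulation
#' demodulator needs none.
#'
#' @param stream A `bis_stream` covering whole global periods.
#' @param grid A [build_grid()] object (defaults to the stream's own grid).
#' @return A `bis_spectrum`.
#' @export
fourier_reference <- function(stream, grid = stream$grid) {
  stopifnot(inherits(stream, "bis_stream"), inherits(grid, "bis_grid"))
  v <- stream$values
  if (length(v) %% grid$record_length != 0L)
    stop("stream must cover whole global periods")
  t <- (0:(length(v) - 1)) / grid$fclk
  nf <- grid$nf
  re <- numeric(nf); im <- numeric(nf)
  for (i in seq_len(nf)) {
    w <- 2 * pi * grid$frequencies[i] * t
    re[i] <- 2 * mean(v * cos(w))
    im[i] <- -2 * mean(v * sin(w))
  }
  new_spectrum(complex(real = re, imaginary = im), grid)
}

#' Cost and acquisition-time model of the three estimation methods
#'
#' Closed-form operation counts and minimum acquisition times:
#' \describe{
#'   \item{`single_coherent`}{frequency sweep with coherent sampling:
#'     \eqn{n_f 2^{n_f-1}/f_0} seconds, \eqn{2(2^{n_f}-1)} additions, 0
#'     multiplications.}
#'   \item{`multi_dct`}{multitone excitation with transform-based analysis at
#'     the Shannon rate \eqn{2 f_0}: \eqn{2^{n_f-1}/f_0} seconds,
#'     \eqn{n_f 2^{n_f+1}} additions and as many multiplications.}
#'   \item{`multi_coherent`}{multitone excitation with decimation-accumulation
#'     demodulation (this package's method): \eqn{2^{n_f-1}/f_0} seconds,
#'     \eqn{2(2^{n_f}-1)} additions, 0 multiplications — the sweep's
#'     arithmetic at the multitone acquisition speed.}
#' }
#' The `multi_dct` addition count is the conventional Shannon-rate figure,
#' reported as such (the simulator itself records at \eqn{4 f_0}).
#'
#' @param method One of `"single_coherent"`, `"multi_dct"`, `"multi_coherent"`.
#' @param nf Number of tones.
#' @param f0 Highest tone frequency, Hz.
#' @return Class `"bis_cost"`: `method`, `acquisition_time_s`,
#'   `acquisition_time_periods` (units of \eqn{1/f_0}), `additions`,
#'   `multiplications`.
#' @export
cost_model <- function(method = c("single_coherent", "multi_dct", "multi_coherent"),
                       nf, f0) {
  method <- match.arg(method)
  stopifnot(nf >= 1, nf == round(nf), f0 > 0)
  periods <- switch(method,
    single_coherent = nf * 2^(nf - 1),
    multi_dct = 2^(nf - 1),
    multi_coherent = 2^(nf - 1)
  )
  additions <- switch(method,
    single_coherent = 2 * (2^nf - 1),
    multi_dct = nf * 2^(nf + 1),
    multi_coherent = 2 * (2^nf - 1)
  )
  multiplications <- switch(method,
    single_coherent = 0,
    multi_dct = nf * 2^(nf + 1),
    multi_coherent = 0
  )
  structure(list(method = method,
                 acquisition_time_s = periods / f0,
                 acquisition_time_periods = periods,
                 additions = additions,
                 multiplications = multiplications),
            class = "bis_cost")
}

#' @export
print.bis_cost <- function(x, ...) {
  cat(sprintf("Method %-16s: acquisition %g/f0 s (= %g s), %g additions, %g multiplications\n",
              x$method, x$acquisition_time_periods, x$acquisition_time_s,
              x$additions, x$multiplications))
  invisible(x)
}
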