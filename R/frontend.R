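# Multitone synthesis and the clocked ADC model.

#' Multitone excitation specification
#'
#' Per-tone complex amplitudes of the excitation current. The current is real,
#' so hermitian pairing is implicit: a complex amplitude \eqn{I_i} contributes
#' \eqn{2|I_i| \cos(2\pi f_i t + \arg I_i)}. The default, \eqn{I_i = 1/2} for
#' every tone, gives unit-amplitude zero-phase cosines, the normalization under
#' which the demodulator reads impedance directly; any other excitation is
#' folded back to this case by resistor calibration (see [calibrate()]).
#'
#' @param grid A [build_grid()] object.
#' @param amplitudes Optional complex vector of length `grid$nf`. Default `1/2`
#'   for every tone.
#' @return Class `"bis_excitation"`.
#' @export
excitation_spec <- function(grid, amplitudes = NULL) {
  stopifnot(inherits(grid, "bis_grid"))
  if (is.null(amplitudes)) amplitudes <- rep(complex(real = 0.5), grid$nf)
  amplitudes <- as.complex(amplitudes)
  if (length(amplitudes) != grid$nf)
    stop("'amplitudes' must have one entry per tone (", grid$nf, ")")
  structure(list(amplitudes = amplitudes, nf = grid$nf), class = "bis_excitation")
}

#' Synthesize the multitone excitation current
#'
#' \eqn{i(t) = \sum_i 2\Re\{I_i e^{2i\pi f_i t}\}}; with the default
#' excitation this is a sum of unit cosines, so `i(0) = nf`.
#'
#' @param grid A [build_grid()] object.
#' @param t Time(s) in seconds (vectorized).
#' @param exc Optional [excitation_spec()]; default excitation if `NULL`.
#' @return Current in A, same length as `t`.
#' @export
synthesize_current <- function(grid, t, exc = NULL) {
  tone_sum(grid, t, coef_of(grid, exc))
}

#' Synthesize the steady-state voltage across a known spectrum
#'
#' In sinusoidal steady state each tone is scaled by the complex impedance at
#' its own frequency: \eqn{v(t) = \sum_i 2\Re\{I_i Z_i e^{2i\pi f_i t}\}},
#' i.e. (default excitation) \eqn{\sum_i |Z_i|\cos(2\pi f_i t + \arg Z_i)}.
#' Purely algebraic per-tone scaling; no transient.
#'
#' @param Zi Complex impedance per tone (length `grid$nf`, descending f).
#' @param grid A [build_grid()] object.
#' @param t Time(s) in seconds (vectorized).
#' @param exc Optional [excitation_spec()].
#' @return Voltage in V, same length as `t`.
#' @export
synthesize_voltage <- function(Zi, grid, t, exc = NULL) {
  if (length(Zi) != grid$nf)
    stop("'Zi' must have one impedance per tone (", grid$nf, ")")
  tone_sum(grid, t, coef_of(grid, exc) * as.complex(Zi))
}

coef_of <- function(grid, exc) {
  if (is.null(exc)) exc <- excitation_spec(grid)
  stopifnot(inherits(exc, "bis_excitation"), exc$nf == grid$nf)
  exc$amplitudes
}

# real part of the analytic (positive-frequency) sum; exact for hermitian pairs
tone_sum <- function(grid, t, coef) {
  ph <- outer(t, grid$frequencies)      # t x nf cycles
  drop(cos(2 * pi * ph) %*% (2 * Re(coef)) - sin(2 * pi * ph) %*% (2 * Im(coef)))
}

#' ADC configuration
#'
#' Behavioral model of the clocked converter: additive white Gaussian noise on
#' the sample values, Gaussian jitter on the sampling instants, a DC offset
#' (amplifier offset / electrode potential), and optional midtread uniform
#' quantization over \eqn{\pm}`full_scale`.
#'
#' @param resolution_bits `"ideal"` (no quantization) or an integer \eqn{\ge 1}.
#' @param full_scale Full-scale voltage (quantizer spans \eqn{\pm}full_scale).
#' @param noise_sigma Std. dev. of additive white noise, volts.
#' @param jitter_sigma Std. dev. of sampling-instant jitter, seconds.
#' @param dc_offset Constant offset added to every sample, volts.
#' @param seed Integer seed for the noise/jitter draws (`NULL` = current RNG).
#' @return Class `"bis_adc"`.
#' @export
adc_config <- function(resolution_bits = "ideal", full_scale = 1,
                       noise_sigma = 0, jitter_sigma = 0, dc_offset = 0,
                       seed = NULL) {
  if (!identical(resolution_bits, "ideal")) {
    if (!is.numeric(resolution_bits) || resolution_bits < 1 ||
        resolution_bits != round(resolution_bits))
      stop("'resolution_bits' must be \"ideal\" or an integer >= 1")
    resolution_bits <- as.integer(resolution_bits)
  }
  stopifnot(full_scale > 0, noise_sigma >= 0, jitter_sigma >= 0)
  structure(list(resolution_bits = resolution_bits, full_scale = full_scale,
                 noise_sigma = noise_sigma, jitter_sigma = jitter_sigma,
                 dc_offset = dc_offset, seed = seed),
            class = "bis_adc")
}

# run code under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Sample the voltage with the clocked ADC
#'
#' Sample `n` holds \eqn{v(t_n) + \text{noise} + \text{offset}} with
#' \eqn{t_n = n/f_{clk} + \text{jitter}_n}, then midtread quantization when a
#' finite resolution is configured. Sample 0 is taken at \eqn{t = 0}, where
#' all tones have zero phase — the alignment under which the accumulator
#' index formulas hold. Samples exceeding full scale are clipped (with a
#' warning). With a fixed seed the stream is bit-reproducible.
#'
#' @param Zi Complex impedance per tone, or an impedance model (evaluated on
#'   `grid`).
#' @param grid A [build_grid()] object.
#' @param adc An [adc_config()]; default is the ideal noiseless converter.
#' @param periods Number of global periods to acquire (\eqn{M \ge 1}).
#' @param exc Optional [excitation_spec()].
#' @return Class `"bis_stream"`: `values` (volts), `codes` (integer codes, or
#'   `NULL` for an ideal converter), `quantum` (volts per code), `grid`, `adc`,
#'   `periods`.
#' @export
sample_adc <- function(Zi, grid, adc = adc_config(), periods = 1, exc = NULL) {
  stopifnot(inherits(grid, "bis_grid"), inherits(adc, "bis_adc"))
  if (periods < 1 || periods != round(periods)) stop("'periods' must be an integer >= 1")
  if (inherits(Zi, "bis_model")) Zi <- evaluate_on_grid(Zi, grid)
  n <- 0:(periods * grid$record_length - 1L)
  with_seed(adc$seed, {
    t <- n / grid$fclk
    if (adc$jitter_sigma > 0) t <- t + stats::rnorm(length(n), 0, adc$jitter_sigma)
    v <- synthesize_voltage(Zi, grid, t, exc)
    if (adc$noise_sigma > 0) v <- v + stats::rnorm(length(n), 0, adc$noise_sigma)
    v <- v + adc$dc_offset
    codes <- NULL
    quantum <- NULL
    if (!identical(adc$resolution_bits, "ideal")) {
      b <- adc$resolution_bits
      quantum <- 2 * adc$full_scale / 2^b
      codes <- round(v / quantum)
      lo <- -2^(b - 1L); hi <- 2^(b - 1L) - 1
      n_clip <- sum(codes < lo | codes > hi)
      if (n_clip > 0)
        warning(sprintf("%d sample(s) exceeded full scale and were clipped", n_clip))
      codes <- pmin(pmax(codes, lo), hi)
      v <- codes * quantum
    }
    new_stream(v, grid, adc, periods, codes = codes, quantum = quantum)
  })
}

new_stream <- function(values, grid, adc = NULL, periods = NULL,
                       codes = NULL, quantum = NULL) {
  if (length(values) %% grid$record_length != 0L || length(values) == 0L)
    stop("stream length must be a positive multiple of the record length (",
         grid$record_length, ")")
  if (is.null(periods)) periods <- length(values) %/% grid$record_length
  structure(list(values = as.numeric(values), codes = codes, quantum = quantum,
                 grid = grid, adc = adc, periods = as.integer(periods)),
            class = "bis_stream")
}

#' Wrap raw samples as a stream
#'
#' For user-supplied records or hand-built test vectors. Integer-valued
#' streams can be fed directly to [demodulate_fixed_point()] (the values are
#' then taken as ADC codes).
#'
#' @param values Numeric sample vector; length must be a positive multiple of
#'   `grid$record_length`.
#' @param grid A [build_grid()] object.
#' @return Class `"bis_stream"`.
#' @export
sample_stream <- function(values, grid) new_stream(values, grid)

#' @export
print.bis_stream <- function(x, ...) {
  cat(sprintf("Sample stream: %d samples (%d global period%s of %d), fclk = %g Hz\n",
              length(x$values), x$periods, if (x$periods > 1) "s" else "",
              x$grid$record_length, x$grid$fclk))
  if (!is.null(x$codes))
    cat(sprintf("  quantized: %d-bit codes, quantum %g V\n",
                x$adc$resolution_bits, x$quantum))
  invisible(x)
}

#' Write / read a sample stream as CSV
#'
#' One `sample_value` column preceded by `# key=value` metadata header lines
#' (f0, nf, fclk, seed, ADC settings). Values are rendered with 17 significant
#' digits so the round trip is lossless at double precision.
#'
#' @param stream A `bis_stream`.
#' @param path Output file.
#' @return `write_stream_csv` returns `path` invisibly; `read_stream_csv`
#'   returns a `bis_stream`.
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "bis_stream"))
  adc <- stream$adc
  meta <- c(
    sprintf("# f0=%.17g", stream$grid$f0),
    sprintf("# nf=%d", stream$grid$nf),
    sprintf("# fclk=%.17g", stream$grid$fclk),
    sprintf("# periods=%d", stream$periods),
    if (!is.null(adc)) c(
      sprintf("# resolution_bits=%s", as.character(adc$resolution_bits)),
      sprintf("# full_scale=%.17g", adc$full_scale),
      sprintf("# noise_sigma=%.17g", adc$noise_sigma),
      sprintf("# jitter_sigma=%.17g", adc$jitter_sigma),
      sprintf("# dc_offset=%.17g", adc$dc_offset),
      sprintf("# seed=%s", if (is.null(adc$seed)) "NA" else as.character(adc$seed))
    )
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("sample_value", con)
  writeLines(sprintf("%.17g", stream$values), con)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  for (k in c("f0", "nf")) if (is.na(meta[k]))
    stop("stream CSV ", path, " is missing metadata line '# ", k, "='")
  grid <- build_grid(as.numeric(meta["f0"]), as.integer(meta["nf"]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 1L || body[1L] != "sample_value")
    stop("malformed stream CSV at line ", length(meta_lines) + 1L,
         ": expected header 'sample_value'")
  vals <- suppressWarnings(as.numeric(body[-1L]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop("malformed numeric value at line ", length(meta_lines) + 1L + bad,
         " of ", path)
  }
  adc <- NULL
  if (!is.na(meta["resolution_bits"])) {
    rb <- meta[["resolution_bits"]]
    adc <- adc_config(
      resolution_bits = if (rb == "ideal") "ideal" else as.integer(rb),
      full_scale = as.numeric(meta[["full_scale"]]),
      noise_sigma = as.numeric(meta[["noise_sigma"]]),
      jitter_sigma = as.numeric(meta[["jitter_sigma"]]),
      dc_offset = as.numeric(meta[["dc_offset"]]),
      seed = if (meta[["seed"]] == "NA") NULL else as.integer(meta[["seed"]])
    )
  }
  s <- new_stream(vals, grid, adc = adc)
  if (!is.null(adc) && !identical(adc$resolution_bits, "ideal")) {
    s$quantum <- 2 * adc$full_scale / 2^adc$resolution_bits
    s$codes <- round(vals / s$quantum)
  }
  s
}
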