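# Synchronous decimation-accumulation demodulation: the multiplier-free core.
#
# Stage j re-samples the record at tone frequency fj = f0/2^j, i.e. every
# 2^(j+2) clock ticks, and averages; the quadrature channel does the same a
# quarter period of fj (2^j ticks) later. Tones above fj fold onto DC, which
# is undone later by recover_spectrum().

stage_counts <- function(nf) as.integer(2^(nf - seq_len(nf)))  # 2^(nf-j-1), j = 0..nf-1

# 1-based sample indices of stage j (0-based) within one record
s_indices <- function(nf, j) 2^(j + 2) * (0:(2^(nf - j - 1) - 1)) + 1L
q_indices <- function(nf, j) 2^j * (4 * (0:(2^(nf - j - 1) - 1)) + 1) + 1L

#' Demodulate a sample stream (floating point)
#'
#' For each stage \eqn{j}, averages the record's samples taken every
#' \eqn{2^{j+2}} clock ticks (in-phase, \eqn{S_j}) and the samples a quarter
#' period of \eqn{f_j = f_0/2^j} later, i.e. offset by \eqn{2^j} ticks
#' (quadrature, \eqn{Q_j}):
#' \deqn{S_j = \frac{1}{2^{n_f-j-1}} \sum_i v[2^{j+2} i], \qquad
#'       Q_j = \frac{1}{2^{n_f-j-1}} \sum_i v[2^j(4i+1)].}
#' Stage \eqn{j} accumulates \eqn{2^{n_f-j-1}} samples; the last stage uses a
#' single sample per channel. Streams spanning several global periods are
#' demodulated per period and the results averaged with equal weights.
#'
#' Because sub-sampling a multitone record aliases every tone at or above the
#' stage frequency onto DC, \eqn{S_j} and \eqn{Q_j} are cumulative mixtures of
#' impedance components, not per-tone values; see [recover_spectrum()] for the
#' exact unmixing.
#'
#' @param stream A `bis_stream` whose length is a whole number of records.
#' @return Class `"bis_demod"`: `S`, `Q` (length `nf`), `counts`
#'   (\eqn{2^{n_f-j-1}}), `mode = "float"`, `additions` (per global period,
#'   both channels) and `multiplications` (always 0).
#' @seealso [demodulate_fixed_point()], [remove_dc()], [count_operations()]
#' @export
demodulate <- function(stream) {
  stopifnot(inherits(stream, "bis_stream"))
  grid <- stream$grid
  nf <- grid$nf
  N <- grid$record_length
  v <- stream$values
  if (length(v) %% N != 0L) stop("stream length is not a multiple of the record length")
  P <- length(v) %/% N
  counts <- stage_counts(nf)
  S <- numeric(nf); Q <- numeric(nf)
  for (p in seq_len(P)) {
    off <- (p - 1L) * N
    for (j in 0:(nf - 1L)) {
      S[j + 1L] <- S[j + 1L] + mean(v[off + s_indices(nf, j)])
      Q[j + 1L] <- Q[j + 1L] + mean(v[off + q_indices(nf, j)])
    }
  }
  structure(list(nf = nf, S = S / P, Q = Q / P, counts = counts,
                 mode = "float", periods = P, grid = grid,
                 additions = 2L * sum(counts), multiplications = 0L),
            class = "bis_demod")
}

#' Count arithmetic operations of the demodulator
#'
#' Instrumented demodulation: one addition per accumulated sample per channel,
#' reported per global period. Equals the closed form \eqn{2(2^{n_f}-1)} for
#' the multitone coherent-sampling method (see [cost_model()]); no
#' multiplication is ever performed.
#'
#' @param stream A `bis_stream`.
#' @return List with `additions` (per global period) and `multiplications`.
#' @export
count_operations <- function(stream) {
  d <- demodulate(stream)
  list(additions = d$additions, multiplications = d$multiplications)
}

#' Fixed-point accumulator configuration
#'
#' Hardware sizing for the bit-true demodulator. Stage \eqn{j} accumulates
#' \eqn{2^{n_f-j-1}} two's-complement codes of `input_bits` bits, so its adder
#' carries exactly \eqn{n_f - j - 1} guard bits:
#' `adder_bits[j] = input_bits + nf - j - 1`, which provably cannot overflow.
#' The division by the sample count is realized by keeping only the `nb` most
#' significant bits of the accumulator (dropping
#' `max(0, adder_bits - nb)` LSBs — truncation toward \eqn{-\infty}), so every
#' \eqn{S_j, Q_j} is reported at the same `nb`-bit precision.
#'
#' @param nb Output word width in bits.
#' @param input_bits ADC code width in bits.
#' @param nf Number of tones / stages.
#' @return Class `"bis_fp"` with per-stage `guard_bits`, `adder_bits`,
#'   `dropped_lsbs`.
#' @export
fixed_point_config <- function(nb, input_bits, nf) {
  stopifnot(nb >= 1, nb == round(nb), input_bits >= 1, input_bits == round(input_bits),
            nf >= 1, nf == round(nf))
  j <- 0:(nf - 1L)
  guard <- nf - j - 1L
  adder <- as.integer(input_bits + guard)
  structure(list(nb = as.integer(nb), input_bits = as.integer(input_bits),
                 nf = as.integer(nf), guard_bits = as.integer(guard),
                 adder_bits = adder,
                 dropped_lsbs = pmax(0L, adder - as.integer(nb))),
            class = "bis_fp")
}

#' Demodulate in bit-true fixed point
#'
#' Integer accumulation with the adder widths of [fixed_point_config()],
#' followed by the MSB-truncation divide. The arithmetic uses additions,
#' negations and bit shifts only (the shift count is reported alongside the
#' addition count; the multiplication count is asserted to be zero). Results
#' are returned on the same scale as [demodulate()] — volts when the stream
#' carries a quantizer step, raw code units otherwise — so the two modes are
#' directly comparable: they agree within one output LSB by construction.
#'
#' @param stream A `bis_stream` that is already quantized: either produced by
#'   [sample_adc()] with finite resolution, or integer-valued (values taken as
#'   codes).
#' @param fp A [fixed_point_config()]; its `input_bits` and `nf` must match.
#' @param rounding `"truncate"` (default; plain MSB keep, toward \eqn{-\infty})
#'   or `"nearest"` (adds half an output LSB before the shift).
#' @return Class `"bis_demod"` with `mode = "fixed"`, plus `width_report`
#'   (per-stage adder sizing and output LSB) and shift/addition counters.
#' @export
demodulate_fixed_point <- function(stream, fp, rounding = c("truncate", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(stream, "bis_stream"), inherits(fp, "bis_fp"))
  grid <- stream$grid
  nf <- grid$nf
  if (fp$nf != nf) stop("fixed-point config is for nf = ", fp$nf,
                        " but the stream has nf = ", nf)
  if (!is.null(stream$codes)) {
    codes <- stream$codes
    quantum <- stream$quantum
  } else {
    codes <- stream$values
    if (any(codes != round(codes)))
      stop("stream is not quantized: provide integer codes or a stream from a finite-resolution ADC")
    quantum <- 1
  }
  lo <- -2^(fp$input_bits - 1L); hi <- 2^(fp$input_bits - 1L) - 1
  if (any(codes < lo) || any(codes > hi))
    stop("stream codes exceed the declared input width of ", fp$input_bits, " bits")
  N <- grid$record_length
  P <- length(codes) %/% N
  counts <- stage_counts(nf)
  S <- numeric(nf); Q <- numeric(nf)
  n_add <- 0L; n_shift <- 0L; n_mult <- 0L
  for (p in seq_len(P)) {
    off <- (p - 1L) * N
    for (j in 0:(nf - 1L)) {
      jj <- j + 1L
      d <- fp$dropped_lsbs[jj]
      g <- fp$guard_bits[jj]
      half <- 2^(fp$adder_bits[jj] - 1L)
      for (ch in c("S", "Q")) {
        idx <- if (ch == "S") s_indices(nf, j) else q_indices(nf, j)
        acc <- sum(codes[off + idx])              # integer-exact in doubles
        n_add <- n_add + length(idx)
        if (acc < -half || acc > half - 1)
          stop("internal error: accumulator overflow at stage ", j,
               " (must be impossible with the stated adder widths)")
        if (rounding == "nearest" && d > 0L) acc <- acc + 2^(d - 1L)
        kept <- floor(acc / 2^d)                  # drop d LSBs: arithmetic shift
        if (d > 0L) n_shift <- n_shift + 1L
        val <- kept * 2^d / 2^g                   # rescale to average, code units
        if (g > 0L || d > 0L) n_shift <- n_shift + 1L
        if (ch == "S") S[jj] <- S[jj] + val else Q[jj] <- Q[jj] + val
      }
    }
  }
  stopifnot(n_mult == 0L)
  width_report <- data.frame(
    stage = 0:(nf - 1L),
    count = counts,
    guard_bits = fp$guard_bits,
    adder_bits = fp$adder_bits,
    dropped_lsbs = fp$dropped_lsbs,
    output_lsb = quantum * 2^fp$dropped_lsbs / 2^fp$guard_bits
  )
  structure(list(nf = nf, S = S / P * quantum, Q = Q / P * quantum,
                 counts = counts, mode = "fixed", periods = P, grid = grid,
                 nb = fp$nb, width_report = width_report,
                 additions = as.integer(n_add / P),
                 multiplications = n_mult, shifts = n_shift),
            class = "bis_demod")
}

#' Remove a DC offset from demodulated averages
#'
#' Very-low-frequency disturbances (amplifier offset, electrode interface
#' potential) add the same constant to every \eqn{S_j} and \eqn{Q_j}. The
#' offset is estimated as the mean of all samples at the full clock rate —
#' i.e. before any decimation, where the multitone signal averages exactly to
#' zero over whole records — and subtracted from every channel in
#' post-processing.
#'
#' @param result A `bis_demod`.
#' @param stream The stream it was computed from.
#' @return A `bis_demod` with the offset subtracted; the estimated offset is
#'   stored as `dc_estimate`.
#' @export
remove_dc <- function(result, stream) {
  stopifnot(inherits(result, "bis_demod"), inherits(stream, "bis_stream"))
  m <- mean(stream$values)
  result$S <- result$S - m
  result$Q <- result$Q - m
  result$dc_estimate <- m
  result
}

#' @export
print.bis_demod <- function(x, digits = 6, ...) {
  cat(sprintf("Demodulation result (%s mode, nf = %d, %d period%s)\n",
              x$mode, x$nf, x$periods, if (x$periods > 1) "s" else ""))
  df <- data.frame(stage = 0:(x$nf - 1L), count = x$counts,
                   S = signif(x$S, digits), Q = signif(x$Q, digits))
  print(df, row.names = FALSE)
  cat(sprintf("  additions/period: %d, multiplications: %d\n",
              x$additions, x$multiplications))
  invisible(x)
}

#' Serialize a demodulation result to JSON
#'
#' @param result A `bis_demod`.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return JSON text (invisibly when written to file).
#' @export
demod_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "bis_demod"))
  obj <- list(nf = result$nf, mode = result$mode, S = result$S, Q = result$Q,
              counts = result$counts)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
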