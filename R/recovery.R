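# Analytic aliasing forward model and its exact recursive inversion.

#' Analytic aliased DC components of the demodulator
#'
#' Closed-form prediction of the in-phase/quadrature averages produced by
#' [demodulate()] on a noiseless synthesis of a spectrum \eqn{Z_0..Z_{n_f-1}}
#' (default excitation). Sub-sampling folds every tone at or above the stage
#' frequency onto DC:
#' \deqn{S_j = \sum_{i=0}^{j} \Re(Z_i),}
#' \deqn{Q_0 = -\Im(Z_0), \quad Q_1 = -\Re(Z_0) - \Im(Z_1),}
#' \deqn{Q_j = \sum_{i=0}^{j-2} \Re(Z_i) - \Re(Z_{j-1}) - \Im(Z_j), \quad j \ge 2.}
#'
#' @param Zi Complex impedance per tone, descending frequency.
#' @return List with numeric vectors `S` and `Q` of length `length(Zi)`.
#' @seealso [recover_spectrum()], the exact inverse.
#' @export
forward_alias <- function(Zi) {
  Zi <- as.complex(Zi)
  nf <- length(Zi)
  if (nf < 1L) stop("need at least one tone")
  re <- Re(Zi); im <- Im(Zi)
  S <- cumsum(re)
  Q <- numeric(nf)
  Q[1L] <- -im[1L]
  if (nf >= 2L) Q[2L] <- -re[1L] - im[2L]
  if (nf >= 3L) for (j in 3:nf) Q[j] <- sum(re[1:(j - 2L)]) - re[j - 1L] - im[j]
  list(S = S, Q = Q)
}

#' Recover the complex impedance spectrum from S/Q averages
#'
#' Exact recursive inversion of the aliasing mixture (see [forward_alias()]):
#' \deqn{\Re(Z_0) = S_0, \quad \Im(Z_0) = -Q_0,}
#' \deqn{\Re(Z_1) = S_1 - S_0, \quad \Im(Z_1) = -Q_1 - S_0,}
#' \deqn{\Re(Z_j) = S_j - S_{j-1}, \quad \Im(Z_j) = 2 S_{j-2} - S_{j-1} - Q_j,
#'       \quad j \ge 2.}
#' `recover_spectrum(forward_alias(Z))` is the identity for every
#' \eqn{n_f \ge 1}; the recovery is linear in \eqn{(S, Q)} and is deliberately
#' kept out of the demodulator (post-processing), mirroring a hardware
#' implementation that only ships accumulator words.
#'
#' @param S In-phase averages, or a `bis_demod` object (then `Q` is ignored).
#' @param Q Quadrature averages, same length as `S`.
#' @param grid Optional [build_grid()] used to attach frequencies.
#' @return Class `"bis_spectrum"`.
#' @export
recover_spectrum <- function(S, Q = NULL, grid = NULL) {
  if (inherits(S, "bis_demod")) {
    if (is.null(grid)) grid <- S$grid
    Q <- S$Q
    S <- S$S
  }
  nf <- length(S)
  if (nf < 1L || length(Q) != nf) stop("'S' and 'Q' must have equal positive length")
  re <- numeric(nf); im <- numeric(nf)
  re[1L] <- S[1L]
  im[1L] <- -Q[1L]
  if (nf >= 2L) {
    re[2L] <- S[2L] - S[1L]
    im[2L] <- -Q[2L] - S[1L]
  }
  if (nf >= 3L) for (j in 3:nf) {
    re[j] <- S[j] - S[j - 1L]
    im[j] <- 2 * S[j - 2L] - S[j - 1L] - Q[j]
  }
  new_spectrum(complex(real = re, imaginary = im), grid)
}

new_spectrum <- function(z, grid = NULL) {
  structure(list(
    frequency_hz = if (!is.null(grid)) grid$frequencies else rep(NA_real_, length(z)),
    impedance = z,
    modulus_ohm = Mod(z),
    phase_rad = atan2(Im(z), Re(z)),
    grid = grid
  ), class = "bis_spectrum")
}

#' @export
print.bis_spectrum <- function(x, digits = 7, ...) {
  cat(sprintf("Recovered impedance spectrum (%d tones)\n", length(x$impedance)))
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.bis_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency_hz,
             re_ohm = Re(x$impedance),
             im_ohm = Im(x$impedance),
             modulus_ohm = x$modulus_ohm,
             phase_rad = x$phase_rad)
}

#' @export
coef.bis_spectrum <- function(object, ...) {
  z <- object$impedance
  names(z) <- format(object$frequency_hz, trim = TRUE)
  z
}

#' @export
summary.bis_spectrum <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Impedance spectrum: %d tones", nrow(df)))
  if (!anyNA(df$frequency_hz))
    cat(sprintf(", %g Hz .. %g Hz", min(df$frequency_hz), max(df$frequency_hz)))
  cat("\n")
  cat(sprintf("  modulus: %.6g .. %.6g Ohm\n", min(df$modulus_ohm), max(df$modulus_ohm)))
  cat(sprintf("  phase  : %.6g .. %.6g rad\n", min(df$phase_rad), max(df$phase_rad)))
  invisible(df)
}

#' @export
plot.bis_spectrum <- function(x, ...) {
  if (anyNA(x$frequency_hz)) stop("spectrum has no attached frequency grid")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$frequency_hz, x$modulus_ohm, log = "xy", type = "b", pch = 19,
                 xlab = "frequency (Hz)", ylab = "|Z| (Ohm)", ...)
  graphics::plot(x$frequency_hz, x$phase_rad, log = "x", type = "b", pch = 19,
                 xlab = "frequency (Hz)", ylab = "arg Z (rad)", ...)
  invisible(x)
}

#' Per-tone resistor calibration
#'
#' The demodulator reads impedance directly only under the normalized
#' excitation (unit-amplitude, zero-phase tones). Any per-tone amplitude or
#' phase deviation \eqn{g_i} of the real excitation multiplies the recovered
#' spectrum tone-wise by \eqn{g_i}; measuring a known reference resistor
#' \eqn{R} gives \eqn{\hat Z_i^{(R)} = g_i R}, so the complex correction
#' \eqn{c_i = R / \hat Z_i^{(R)}} cancels it exactly.
#'
#' @param measured A `bis_spectrum` recovered from a run on the reference
#'   resistor, with the same grid and excitation as subsequent runs.
#' @param R Reference resistance in Ohm.
#' @return Class `"bis_calibration"`: complex `factors` per tone and `R`.
#' @export
calibrate <- function(measured, R) {
  stopifnot(inherits(measured, "bis_spectrum"), is.numeric(R), R > 0)
  z <- measured$impedance
  if (any(z == 0)) stop("calibration failure: zero recovered impedance on the reference resistor")
  structure(list(factors = R / z, R = R), class = "bis_calibration")
}

#' @rdname calibrate
#' @param table A `bis_calibration`.
#' @param raw A `bis_spectrum` to correct.
#' @return `apply_calibration` returns the corrected `bis_spectrum`.
#' @export
apply_calibration <- function(table, raw) {
  stopifnot(inherits(table, "bis_calibration"), inherits(raw, "bis_spectrum"))
  if (length(table$factors) != length(raw$impedance))
    stop("calibration table and spectrum have different numbers of tones")
  new_spectrum(raw$impedance * table$factors, raw$grid)
}

#' Write / read a recovered spectrum as CSV
#'
#' Columns `frequency_hz, re_ohm, im_ohm, modulus_ohm, phase_rad` in
#' descending frequency, rendered with 17 significant digits (lossless round
#' trip). A JSON metadata sidecar (`<path>.json`) records the grid.
#'
#' @param spectrum A `bis_spectrum`.
#' @param path Output CSV path.
#' @param sidecar Write the JSON metadata sidecar. Default `TRUE`.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns a `bis_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path, sidecar = TRUE) {
  stopifnot(inherits(spectrum, "bis_spectrum"))
  df <- as.data.frame(spectrum)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(sprintf, c(list(fmt = paste(rep("%.17g", ncol(df)), collapse = ",")),
                                unname(df))), con)
  if (sidecar) {
    meta <- list(
      nf = length(spectrum$impedance),
      f0 = if (!is.null(spectrum$grid)) spectrum$grid$f0 else NULL,
      fclk = if (!is.null(spectrum$grid)) spectrum$grid$fclk else NULL
    )
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "re_ohm", "im_ohm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  sp <- new_spectrum(complex(real = df$re_ohm, imaginary = df$im_ohm), grid = NULL)
  sp$frequency_hz <- df$frequency_hz
  sp
}

#' Estimate the impedance spectrum from a sample stream
#'
#' The package's central estimator: demodulate (float or bit-true fixed
#' point), optionally remove the DC offset, invert the aliasing recursion,
#' and optionally apply a resistor calibration. On a noiseless ideal
#' acquisition this reproduces the model spectrum at the grid tones to
#' machine precision.
#'
#' @param stream A `bis_stream`.
#' @param mode `"float"` (default) or `"fixed"`.
#' @param fp A [fixed_point_config()], required for `mode = "fixed"`.
#' @param dc_remove Estimate and subtract a DC offset ([remove_dc()]).
#' @param calibration Optional `bis_calibration` to apply.
#' @return A `bis_spectrum`; the intermediate `bis_demod` is attached as
#'   attribute `"demod"`.
#' @examples
#' grid <- build_grid(250e3, 8)
#' model <- cpe_model(q0 = 1e-5, alpha = 0.5)
#' stream <- sample_adc(model, grid)
#' est <- estimate_spectrum(stream)
#' max(Mod(coef(est) - evaluate_on_grid(model, grid)))  # ~1e-13
#' @export
estimate_spectrum <- function(stream, mode = c("float", "fixed"), fp = NULL,
                              dc_remove = FALSE, calibration = NULL) {
  mode <- match.arg(mode)
  d <- if (mode == "float") {
    demodulate(stream)
  } else {
    if (is.null(fp)) stop("mode = \"fixed\" requires a fixed_point_config()")
    demodulate_fixed_point(stream, fp)
  }
  if (dc_remove) d <- remove_dc(d, stream)
  sp <- recover_spectrum(d)
  if (!is.null(calibration)) sp <- apply_calibration(calibration, sp)
  attr(sp, "demod") <- d
  sp
}
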