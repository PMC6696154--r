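#' Constant phase element (CPE) impedance model
#'
#' A constant phase element has impedance
#' \deqn{Z(f) = \frac{1}{q_0\,(2 i \pi f)^\alpha}}
#' using the principal branch of the complex power, so the modulus falls as
#' \eqn{f^{-\alpha}} and the phase is frequency independent, exactly
#' \eqn{-\alpha\pi/2}. CPEs (together with resistors and capacitors) are the
#' standard building blocks of tissue impedance models; \eqn{\alpha = 1} is
#' the pure-capacitor limit and \eqn{\alpha = 1/2} is typical of dispersive
#' tissue.
#'
#' @param q0 Positive scale parameter (arbitrary units).
#' @param alpha Exponent, with \eqn{0 < \alpha \le 1}.
#' @return An object of class `c("bis_cpe", "bis_model")`.
#' @seealso [impedance()], [evaluate_on_grid()], [circuit helpers][resistor]
#' @examples
#' z <- impedance(cpe_model(1, 1), 1 / (2 * pi))  # -1i
#' Arg(impedance(cpe_model(2e-6, 0.5), 1e4))      # -pi/4
#' @export
cpe_model <- function(q0, alpha) {
  if (!is.numeric(q0) || length(q0) != 1L || !is.finite(q0) || q0 <= 0)
    stop("'q0' must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must satisfy 0 < alpha <= 1")
  structure(list(kind = "cpe", q0 = q0, alpha = alpha),
            class = c("bis_cpe", "bis_circuit", "bis_model"))
}

#' Circuit-network impedance models
#'
#' Tissue models are composed as finite series/parallel trees whose leaves are
#' resistors, capacitors and constant phase elements. `series_network()` sums
#' child impedances; `parallel_network()` sums child admittances and inverts.
#'
#' @param r Resistance in Ohm (positive).
#' @param c Capacitance in Farad (positive).
#' @param ... Child elements (other circuit nodes or leaves).
#' @return An object of class `c("bis_circuit", "bis_model")`.
#' @examples
#' # a classic two-plateau dispersion: R_inf in series with (R || CPE)
#' m <- series_network(resistor(100), parallel_network(resistor(200), cpe_model(1e-6, 0.5)))
#' impedance(m, 1e4)
#' @name circuit
NULL

#' @rdname circuit
#' @export
resistor <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive resistance in Ohm")
  structure(list(kind = "resistor", r = r), class = c("bis_circuit", "bis_model"))
}

#' @rdname circuit
#' @export
capacitor <- function(c) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single positive capacitance in Farad")
  structure(list(kind = "capacitor", c = c), class = c("bis_circuit", "bis_model"))
}

#' @rdname circuit
#' @export
series_network <- function(...) {
  children <- list(...)
  if (length(children) == 0L) stop("a series node needs at least one child")
  stopifnot(all(vapply(children, inherits, logical(1), "bis_circuit")))
  structure(list(kind = "series", children = children),
            class = c("bis_circuit", "bis_model"))
}

#' @rdname circuit
#' @export
parallel_network <- function(...) {
  children <- list(...)
  if (length(children) == 0L) stop("a parallel node needs at least one child")
  stopifnot(all(vapply(children, inherits, logical(1), "bis_circuit")))
  structure(list(kind = "parallel", children = children),
            class = c("bis_circuit", "bis_model"))
}

#' Tabulated impedance spectrum
#'
#' Wraps a measured (or published) modulus/phase table as an impedance model.
#' Evaluation is only defined at the tabulated frequencies; the demodulation
#' method only ever probes grid tones, so no interpolation is done by default.
#' Set `interpolate = TRUE` to allow log-log interpolation of the modulus
#' (and linear-in-log-f interpolation of the phase) at other frequencies.
#'
#' @param frequency_hz Strictly monotone frequency vector in Hz.
#' @param modulus_ohm Nonnegative modulus per frequency, Ohm.
#' @param phase_rad Phase per frequency, radians.
#' @param interpolate Allow evaluation between tabulated points. Default `FALSE`.
#' @return An object of class `c("bis_table", "bis_model")`.
#' @export
tabulated_spectrum <- function(frequency_hz, modulus_ohm, phase_rad, interpolate = FALSE) {
  n <- length(frequency_hz)
  if (n < 1L || length(modulus_ohm) != n || length(phase_rad) != n)
    stop("frequency, modulus and phase must be nonempty vectors of equal length")
  d <- diff(frequency_hz)
  if (n > 1L && !(all(d > 0) || all(d < 0)))
    stop("'frequency_hz' must be strictly increasing or strictly decreasing")
  if (any(modulus_ohm < 0)) stop("'modulus_ohm' must be nonnegative")
  structure(list(kind = "table",
                 frequency_hz = as.numeric(frequency_hz),
                 modulus_ohm = as.numeric(modulus_ohm),
                 phase_rad = as.numeric(phase_rad),
                 interpolate = isTRUE(interpolate)),
            class = c("bis_table", "bis_model"))
}

#' Read a tabulated spectrum from CSV
#'
#' Expects the header `frequency_hz,modulus_ohm,phase_rad`. The packaged
#' tuna-muscle reference spectrum can be loaded with
#' `read_spectrum_table(system.file("extdata", "tuna_muscle_reference.csv",
#' package = "bisdemod"))`.
#'
#' @param path CSV file path.
#' @param interpolate Passed on to [tabulated_spectrum()].
#' @return A `bis_table` model.
#' @export
read_spectrum_table <- function(path, interpolate = FALSE) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frequency_hz", "modulus_ohm", "phase_rad")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  tabulated_spectrum(df$frequency_hz, df$modulus_ohm, df$phase_rad, interpolate)
}

#' Evaluate a model's complex impedance
#'
#' @param model An impedance model (`bis_cpe`, circuit network or `bis_table`).
#' @param f Frequency (Hz), positive; may be a vector.
#' @param ... Unused.
#' @return Complex impedance in Ohm, same length as `f`.
#' @export
impedance <- function(model, f, ...) UseMethod("impedance")

#' @export
impedance.bis_model <- function(model, f, ...) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequencies must be positive and finite")
  vapply(f, function(fi) eval_node(model, fi), complex(1))
}

# recursive evaluation of the composition tree
eval_node <- function(node, f) {
  switch(node$kind,
    resistor  = complex(real = node$r),
    capacitor = 1 / (2i * pi * f * node$c),
    cpe = {
      # principal branch: (2 i pi f)^alpha = (2 pi f)^alpha * exp(i alpha pi / 2)
      1 / (node$q0 * (2 * pi * f)^node$alpha * exp(1i * node$alpha * pi / 2))
    },
    series = {
      z <- vapply(node$children, eval_node, complex(1), f = f)
      sum(z)
    },
    parallel = {
      y <- sum(1 / vapply(node$children, eval_node, complex(1), f = f))
      if (y == 0) stop("degenerate model: zero total admittance at a parallel node")
      1 / y
    },
    stop("unknown circuit node kind: ", node$kind)
  )
}

#' @export
impedance.bis_table <- function(model, f, ...) {
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequencies must be positive and finite")
  vapply(f, function(fi) {
    rel <- abs(model$frequency_hz - fi) / fi
    k <- which.min(rel)
    if (rel[k] < 1e-9) {
      complex(modulus = model$modulus_ohm[k], argument = model$phase_rad[k])
    } else if (model$interpolate) {
      lf <- log(model$frequency_hz)
      m <- exp(stats::approx(lf, log(model$modulus_ohm), xout = log(fi), rule = 1)$y)
      p <- stats::approx(lf, model$phase_rad, xout = log(fi), rule = 1)$y
      if (is.na(m) || is.na(p)) stop("frequency ", fi, " Hz outside the tabulated range")
      complex(modulus = m, argument = p)
    } else {
      stop("frequency ", fi, " Hz is not tabulated (set interpolate = TRUE to interpolate)")
    }
  }, complex(1))
}

#' Evaluate a model on a frequency grid
#'
#' Returns the per-tone impedances \eqn{Z_i = Z(f_i)} ordered from the highest
#' tone (\eqn{f_0}) down, matching the grid's index convention. For tabulated
#' models every grid tone must be tabulated (no silent interpolation).
#'
#' @param model An impedance model.
#' @param grid A [build_grid()] object.
#' @return Complex vector of length `grid$nf`, named by frequency.
#' @export
evaluate_on_grid <- function(model, grid) {
  stopifnot(inherits(grid, "bis_grid"))
  z <- impedance(model, grid$frequencies)
  names(z) <- format(grid$frequencies, trim = TRUE)
  z
}
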