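# Noise propagation through the estimator: closed-form per-stage constants,
# exact sample-level weight accounting, and a Monte Carlo arbiter.
#
# The closed-form constants count the samples entering each accumulator as if
# they were independent across stages. They are not: stage-j in-phase samples
# are a subset of stage-(j-1)'s, so the exact variance of the recovered
# components is the weight-accounting value sigma^2 * sum(w^2), which differs
# from the iid-count constants at the edge stages. Both are exposed; the
# Monte Carlo engine decides empirically (it sides with the weights).

#' Closed-form per-stage variance constants (iid-count model)
#'
#' Treating the \eqn{2^{n_f-j-1}} samples of each accumulator as independent
#' across stages gives noise variances
#' \eqn{\sigma^2 / 2^{n_f-j-1}} for \eqn{\Re(\hat Z_j)} and
#' \eqn{\sigma^2 / 2^{n_f-j+1}} for \eqn{\Im(\hat Z_j)}. At the last stage
#' (\eqn{j = n_f - 1}) a single sample feeds each channel and the real-part
#' variance equals \eqn{\sigma^2}. Compare with
#' [predict_variance_weights()], the exact linear-combination value.
#'
#' @param nf Number of tones.
#' @param j Stage index/indices, 0-based (vectorized).
#' @param sigma2 Noise power (variance) at the ADC, V^2.
#' @return List with vectors `var_re` and `var_im`.
#' @export
predict_variance_iid <- function(nf, j, sigma2) {
  stopifnot(all(j >= 0), all(j < nf), sigma2 >= 0)
  list(var_re = sigma2 / 2^(nf - j - 1),
       var_im = sigma2 / 2^(nf - j + 1))
}

#' Exact per-sample weights of the impedance estimators
#'
#' Expands the estimator of one recovered component down to the raw record:
#' \eqn{\Re(\hat Z_j) = \hat S_j - \hat S_{j-1}} and
#' \eqn{\Im(\hat Z_j) = 2\hat S_{j-2} - \hat S_{j-1} - \hat Q_j} (with the
#' \eqn{j = 0, 1} special cases), each \eqn{\hat S, \hat Q} being an average
#' over its stage's sample set. The result is the exact coefficient of every
#' one of the \eqn{2^{n_f+1}} record samples in the estimate; under iid noise
#' of power \eqn{\sigma^2} the estimator variance is
#' \eqn{\sigma^2 \sum_n w_n^2}.
#'
#' @param nf Number of tones.
#' @param j Stage index, 0-based.
#' @param channel `"re"` or `"im"`.
#' @return Numeric weight vector of length \eqn{2^{n_f+1}}.
#' @export
effective_noise_weights <- function(nf, j, channel = c("re", "im")) {
  channel <- match.arg(channel)
  stopifnot(j >= 0, j < nf)
  N <- 2^(nf + 1)
  sw <- function(jj) { w <- numeric(N); w[s_indices(nf, jj)] <- 2^-(nf - jj - 1); w }
  qw <- function(jj) { w <- numeric(N); w[q_indices(nf, jj)] <- 2^-(nf - jj - 1); w }
  if (channel == "re") {
    if (j == 0) sw(0) else sw(j) - sw(j - 1)
  } else {
    if (j == 0) -qw(0)
    else if (j == 1) -qw(1) - sw(0)
    else 2 * sw(j - 2) - sw(j - 1) - qw(j)
  }
}

#' @rdname effective_noise_weights
#' @param sigma2 Noise power at the ADC, V^2.
#' @return `predict_variance_weights` returns a list with vectors `var_re`,
#'   `var_im` over all stages.
#' @export
predict_variance_weights <- function(nf, sigma2) {
  j <- 0:(nf - 1)
  list(
    var_re = sigma2 * vapply(j, function(jj) sum(effective_noise_weights(nf, jj, "re")^2), 0),
    var_im = sigma2 * vapply(j, function(jj) sum(effective_noise_weights(nf, jj, "im")^2), 0)
  )
}

#' Per-tone SNR prediction for a CPE load
#'
#' Signal-to-noise ratio of the real-part estimator,
#' \eqn{\mathrm{SNR}_j = 2^{n_f-j-1}\,\Re(Z_j)^2 / \sigma^2}, with
#' \eqn{\Re(Z_j)} evaluated exactly from the CPE closed form. For
#' \eqn{\alpha = 1/2}, \eqn{\Re(Z_j)^2 \propto 2^j} cancels the
#' \eqn{2^{-j}} sample count exactly and the SNR is the same at every tone:
#' the tissue impedance grows toward low frequency at precisely the rate the
#' estimator noise does. For general \eqn{\alpha} the per-tone values differ.
#'
#' @param nf Number of tones.
#' @param sigma2 Noise power at the ADC, V^2.
#' @param cpe A [cpe_model()].
#' @param f0 Highest tone frequency, Hz.
#' @return Numeric vector of per-tone SNR (dimensionless), stage 0 first.
#' @export
predict_snr <- function(nf, sigma2, cpe, f0) {
  stopifnot(inherits(cpe, "bis_cpe"), sigma2 > 0, f0 > 0, nf >= 1)
  j <- 0:(nf - 1)
  z <- impedance(cpe, f0 / 2^j)
  2^(nf - j - 1) * Re(z)^2 / sigma2
}

#' Monte Carlo variance study of the full pipeline
#'
#' Repeats synthesize \eqn{\to} add seeded Gaussian noise \eqn{\to}
#' demodulate \eqn{\to} recover, and reports per-tone empirical variances of
#' \eqn{\Re(\hat Z_j)} and \eqn{\Im(\hat Z_j)}, normalized by the injected
#' noise power. Standard errors come from the normal-theory \eqn{\chi^2}
#' sampling distribution of a variance,
#' \eqn{\mathrm{SE}(\hat\sigma^2) \approx \hat\sigma^2 \sqrt{2/(T-1)}}.
#' The per-tone means converge to the true spectrum (the estimator is
#' unbiased) and the variances grow as \eqn{2^j} toward low frequency — the
#' 1/f evolution: halving the tone frequency halves the number of averaged
#' samples.
#'
#' @param model Impedance model (or complex `Zi` vector).
#' @param grid A [build_grid()] object.
#' @param sigma Noise standard deviation at the ADC, volts.
#' @param trials Number of random trials (\eqn{\ge 2}; \eqn{\ge 100} for
#'   meaningful standard errors).
#' @param seed Integer seed.
#' @return Class `"bis_mc"`: empirical `var_re`/`var_im`, normalized
#'   variances, their standard errors, per-tone means, the true spectrum, and
#'   the two analytic predictions ([predict_variance_iid()] and
#'   [predict_variance_weights()]) for side-by-side comparison.
#' @export
monte_carlo_variance <- function(model, grid, sigma, trials = 1000, seed = NULL) {
  stopifnot(inherits(grid, "bis_grid"), sigma >= 0, trials >= 2)
  nf <- grid$nf
  Zi <- if (inherits(model, "bis_model")) evaluate_on_grid(model, grid) else as.complex(model)
  clean <- sample_adc(Zi, grid)        # noiseless reference record
  v0 <- clean$values
  re_mat <- matrix(0, trials, nf)
  im_mat <- matrix(0, trials, nf)
  with_seed(seed, {
    for (tr in seq_len(trials)) {
      s <- new_stream(v0 + stats::rnorm(length(v0), 0, sigma), grid)
      z <- recover_spectrum(demodulate(s))$impedance
      re_mat[tr, ] <- Re(z)
      im_mat[tr, ] <- Im(z)
    }
  })
  var_re <- apply(re_mat, 2, stats::var)
  var_im <- apply(im_mat, 2, stats::var)
  se_fac <- sqrt(2 / (trials - 1))
  s2 <- sigma^2
  structure(list(
    trials = as.integer(trials), seed = seed, sigma = sigma,
    var_re = var_re, var_im = var_im,
    norm_var_re = var_re / s2, norm_var_im = var_im / s2,
    se_var_re = var_re * se_fac, se_var_im = var_im * se_fac,
    mean_re = colMeans(re_mat), mean_im = colMeans(im_mat),
    truth = Zi,
    iid = predict_variance_iid(nf, 0:(nf - 1), s2),
    weights = predict_variance_weights(nf, s2),
    grid = grid
  ), class = "bis_mc")
}

#' @export
print.bis_mc <- function(x, ...) {
  nf <- length(x$var_re)
  cat(sprintf("Monte Carlo variance study: %d trials, sigma = %g\n", x$trials, x$sigma))
  df <- data.frame(
    stage = 0:(nf - 1),
    frequency_hz = x$grid$frequencies,
    norm_var_re = signif(x$norm_var_re, 4),
    norm_var_im = signif(x$norm_var_im, 4),
    weights_re = signif(x$weights$var_re / x$sigma^2, 4),
    weights_im = signif(x$weights$var_im / x$sigma^2, 4),
    iid_re = signif(x$iid$var_re / x$sigma^2, 4),
    iid_im = signif(x$iid$var_im / x$sigma^2, 4)
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Noise sweep report
#'
#' Runs [monte_carlo_variance()] and lays the empirical, closed-form and
#' weight-accounting predictions side by side, one row per tone, together
#' with the empirical real-channel SNR. This is the table behind the
#' `noise-sweep` command of the bundled CLI script.
#'
#' @inheritParams monte_carlo_variance
#' @return A data.frame with columns `tone_index`, `frequency_hz`,
#'   `var_re_empirical`, `var_im_empirical`, `var_re_iid`, `var_im_iid`,
#'   `var_re_weights`, `var_im_weights`, `snr_empirical`.
#' @export
noise_sweep <- function(model, grid, sigma, trials = 1000, seed = NULL) {
  mc <- monte_carlo_variance(model, grid, sigma, trials, seed)
  nf <- grid$nf
  data.frame(
    tone_index = 0:(nf - 1),
    frequency_hz = grid$frequencies,
    var_re_empirical = mc$var_re,
    var_im_empirical = mc$var_im,
    var_re_iid = mc$iid$var_re,
    var_im_iid = mc$iid$var_im,
    var_re_weights = mc$weights$var_re,
    var_im_weights = mc$weights$var_im,
    snr_empirical = Re(mc$truth)^2 / mc$var_re
  )
}
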