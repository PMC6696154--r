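test_that("accumulator averages of a constant stream are the constant", {
  g <- build_grid(250e3, 5)
  d <- demodulate(sample_stream(rep(3.25, g$record_length), g))
  expect_equal(d$S, rep(3.25, 5))
  expect_equal(d$Q, rep(3.25, 5))
  expect_equal(d$counts, 2^(5 - (0:4) - 1))
})

test_that("a pure tone at f0 lands where the index formulas predict", {
  # v[n] = A cos(pi n / 2): direct index enumeration gives
  # S0 = A, Q0 = 0, S1 = A, Q1 = -A
  g <- build_grid(250e3, 3)
  A <- 2.5
  v <- A * cos(pi * (0:(g$record_length - 1)) / 2)
  d <- demodulate(sample_stream(v, g))
  expect_equal(d$S[1:2], c(A, A))
  expect_equal(d$Q[1:2], c(0, -A))
  # consistency with the analytic alias model for Z0 = A alone
  fa <- forward_alias(c(A + 0i, 0i, 0i))
  expect_equal(d$S, fa$S)
  expect_equal(d$Q, fa$Q)
})

test_that("demodulation of the noiseless synthesis equals the analytic forward model", {
  g <- ref_grid()
  Zi <- evaluate_on_grid(ref_model(), g)
  d <- demodulate(sample_adc(Zi, g))
  fa <- forward_alias(Zi)
  expect_lt(rel_err(d$S, fa$S), 1e-9)
  expect_lt(rel_err(d$Q, fa$Q), 1e-9)
})

test_that("demodulation is linear and multi-period streams average per period", {
  g <- build_grid(250e3, 4)
  set.seed(21)
  x <- rnorm(g$record_length); y <- rnorm(g$record_length)
  dx <- demodulate(sample_stream(x, g))
  dy <- demodulate(sample_stream(y, g))
  dz <- demodulate(sample_stream(2 * x - 3 * y, g))
  expect_equal(dz$S, 2 * dx$S - 3 * dy$S)
  expect_equal(dz$Q, 2 * dx$Q - 3 * dy$Q)

  d2 <- demodulate(sample_stream(c(x, y), g))
  expect_equal(d2$S, (dx$S + dy$S) / 2)
  expect_equal(d2$Q, (dx$Q + dy$Q) / 2)

  expect_error(demodulate(sample_stream(rnorm(48), g)), "multiple of the record length")
})

test_that("stage index sets nest in-phase and keep quadrature disjoint", {
  nf <- 6
  s_idx <- function(j) 2^(j + 2) * (0:(2^(nf - j - 1) - 1))
  q_idx <- function(j) 2^j * (4 * (0:(2^(nf - j - 1) - 1)) + 1)
  for (j in 1:(nf - 1)) {
    expect_true(all(s_idx(j) %in% s_idx(j - 1)))  # decimation by 2 between stages
  }
  for (j in 0:(nf - 1)) {
    # quadrature samples of stage j (odd multiples of 2^j) never collide with
    # the in-phase samples of stage j-1 or deeper (multiples of 2^(j+1));
    # shallower in-phase sets DO share them - the covariance the noise
    # analysis has to account for
    for (m in max(0, j - 1):(nf - 1)) {
      expect_length(intersect(q_idx(j), s_idx(m)), 0)
    }
    if (j >= 2) expect_gt(length(intersect(q_idx(j), s_idx(0))), 0)
  }
})

test_that("fixed-point accumulation matches an exact integer oracle (nf = 4)", {
  g <- build_grid(250e3, 4)
  set.seed(8)
  codes <- sample(-128:127, 32, replace = TRUE)  # hand-sized 8-bit record
  fp <- fixed_point_config(nb = 10, input_bits = 8, nf = 4)
  d <- demodulate_fixed_point(sample_stream(codes, g), fp)

  # independent enumeration: literal 0-based index sets for nf = 4
  s_sets <- list(c(0, 4, 8, 12, 16, 20, 24, 28), c(0, 8, 16, 24), c(0, 16), 0)
  q_sets <- list(c(1, 5, 9, 13, 17, 21, 25, 29), c(2, 10, 18, 26), c(4, 20), 8)
  for (j in 0:3) {
    g_bits <- 4 - j - 1
    adder <- 8 + g_bits
    dropped <- max(0, adder - 10)
    for (ch in 1:2) {
      idx <- (if (ch == 1) s_sets else q_sets)[[j + 1]] + 1
      acc <- sum(codes[idx])
      expected <- (acc %/% 2^dropped) * 2^dropped / 2^g_bits
      got <- if (ch == 1) d$S[j + 1] else d$Q[j + 1]
      expect_equal(got, expected)
    }
  }
  expect_identical(d$multiplications, 0L)
})

test_that("fixed point agrees with float within one output LSB and cannot overflow", {
  g <- build_grid(250e3, 8)
  fp <- fixed_point_config(nb = 16, input_bits = 12, nf = 8)
  expect_equal(fp$adder_bits, 12 + (8 - (0:7) - 1))
  set.seed(30)
  for (rep in 1:5) {
    codes <- sample(-2048:2047, g$record_length, replace = TRUE)
    st <- sample_stream(codes, g)
    dfx <- demodulate_fixed_point(st, fp)
    dfl <- demodulate(st)
    lsb <- dfx$width_report$output_lsb
    expect_true(all(abs(dfx$S - dfl$S) <= lsb))
    expect_true(all(abs(dfx$Q - dfl$Q) <= lsb))
  }

  # constant full-scale-positive input: truncation is exact on constants
  dconst <- demodulate_fixed_point(sample_stream(rep(2047, g$record_length), g), fp)
  expect_equal(dconst$S, rep(2047, 8))
  expect_equal(dconst$Q, rep(2047, 8))

  # full-scale-negative saturates every adder exactly at its lower bound
  dneg <- demodulate_fixed_point(sample_stream(rep(-2048, g$record_length), g), fp)
  expect_equal(dneg$S, rep(-2048, 8))

  # optional round-to-nearest halves the worst-case truncation error
  set.seed(31)
  codes_r <- sample(-2048:2047, g$record_length, replace = TRUE)
  dfn <- demodulate_fixed_point(sample_stream(codes_r, g), fp, rounding = "nearest")
  dfl_r <- demodulate(sample_stream(codes_r, g))
  expect_true(all(abs(dfn$S - dfl_r$S) <= dfn$width_report$output_lsb / 2))
  expect_true(all(abs(dfn$Q - dfl_r$Q) <= dfn$width_report$output_lsb / 2))

  # nb as wide as the widest adder: no LSB is ever dropped, results exact
  fp_wide <- fixed_point_config(nb = 19, input_bits = 12, nf = 8)
  codes <- sample(-2048:2047, g$record_length, replace = TRUE)
  dfx <- demodulate_fixed_point(sample_stream(codes, g), fp_wide)
  dfl <- demodulate(sample_stream(codes, g))
  expect_equal(dfx$S, dfl$S)
  expect_equal(dfx$Q, dfl$Q)

  expect_error(demodulate_fixed_point(sample_stream(rep(4096, g$record_length), g), fp),
               "exceed the declared input width")
  expect_error(demodulate_fixed_point(sample_stream(rnorm(g$record_length), g), fp),
               "not quantized")
})

test_that("quantized ADC streams feed fixed-point demodulation in volts", {
  g <- ref_grid()
  Zi <- evaluate_on_grid(ref_model(), g) / 3000  # keep within a 1 V full scale
  st <- sample_adc(Zi, g, adc_config(resolution_bits = 12, full_scale = 1))
  fp <- fixed_point_config(nb = 16, input_bits = 12, nf = 8)
  dfx <- demodulate_fixed_point(st, fp)
  dfl <- demodulate(st)
  expect_true(all(abs(dfx$S - dfl$S) <= dfx$width_report$output_lsb))
  # recovered spectrum from the bit-true path tracks the model to quantizer accuracy
  sp <- recover_spectrum(dfx)
  expect_lt(max(Mod(sp$impedance - Zi)), 20 * st$quantum)
})

test_that("DC removal restores the offset-free result exactly (noiseless)", {
  g <- ref_grid()
  Zi <- evaluate_on_grid(ref_model(), g)
  clean <- sample_adc(Zi, g)
  offset <- sample_adc(Zi, g, adc_config(dc_offset = 0.1))
  d_clean <- demodulate(clean)
  d_off <- remove_dc(demodulate(offset), offset)
  expect_equal(d_off$S, d_clean$S)
  expect_equal(d_off$Q, d_clean$Q)
  expect_equal(d_off$dc_estimate, 0.1)

  # zero stream stays zero
  z <- remove_dc(demodulate(sample_stream(rep(0, g$record_length), g)),
                 sample_stream(rep(0, g$record_length), g))
  expect_equal(z$S, rep(0, 8))

  # end to end: recovered spectra agree to < 1e-9 relative
  sp_clean <- recover_spectrum(d_clean)
  sp_off <- recover_spectrum(d_off)
  expect_lt(rel_err(sp_off$impedance, sp_clean$impedance), 1e-9)
})

test_that("operation counts follow the 2(2^nf - 1) closed form", {
  for (nf in c(1, 4, 8)) {
    g <- build_grid(250e3, nf)
    ops <- count_operations(sample_stream(rnorm(g$record_length), g))
    expect_equal(ops$additions, 2 * (2^nf - 1))
    expect_equal(ops$multiplications, 0L)
  }
})

test_that("demod results serialize to JSON with S, Q and counts", {
  g <- build_grid(250e3, 3)
  d <- demodulate(sample_stream(rnorm(g$record_length), g))
  txt <- demod_to_json(d)
  back <- jsonlite::fromJSON(txt)
  expect_equal(back$S, d$S)
  expect_equal(back$Q, d$Q)
  expect_equal(back$counts, d$counts)
  expect_equal(back$mode, "float")
})
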