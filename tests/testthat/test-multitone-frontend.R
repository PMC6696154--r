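test_that("grid geometry follows the power-of-two design", {
  g <- build_grid(250e3, 8)
  expect_equal(g$frequencies,
               c(250000, 125000, 62500, 31250, 15625, 7812.5, 3906.25, 1953.125))
  expect_equal(g$fclk, 1e6)
  expect_equal(g$record_length, 512L)
  expect_equal(g$global_period, 2^7 / 250e3)
  expect_equal(g$points_per_decade, log2(10))

  g1 <- build_grid(1000, 1)
  expect_equal(g1$frequencies, 1000)
  expect_equal(g1$record_length, 4L)

  expect_error(build_grid(250e3, 0), "positive integer")
  expect_error(build_grid(-1, 4), "positive")
})

test_that("current synthesis sums unit cosines (default) and is real for hermitian excitation", {
  g <- build_grid(250e3, 8)
  expect_equal(synthesize_current(g, 0), 8)

  g1 <- build_grid(1000, 1)
  t <- seq(0, 2e-3, length.out = 33)
  expect_equal(synthesize_current(g1, t), cos(2 * pi * 1000 * t))

  # derived: term-by-term sum at t = 1/(2 f0), nf = 3
  g3 <- build_grid(250e3, 3)
  t0 <- 1 / (2 * g3$f0)
  expect_equal(synthesize_current(g3, t0), cos(pi) + cos(pi / 2) + cos(pi / 4))

  # hermitian excitation with arbitrary complex amplitudes: the two-sided
  # complex synthesis (independent oracle) must be real and equal the output
  set.seed(11)
  amps <- complex(real = runif(8, -1, 1), imaginary = runif(8, -1, 1))
  exc <- excitation_spec(g, amps)
  tt <- runif(50, 0, g$global_period)
  two_sided <- sapply(tt, function(t)
    sum(amps * exp(2i * pi * g$frequencies * t) +
        Conj(amps) * exp(-2i * pi * g$frequencies * t)))
  expect_lt(max(abs(Im(two_sided))) / max(abs(two_sided)), 1e-12)
  expect_equal(synthesize_current(g, tt, exc), Re(two_sided))
})

test_that("voltage synthesis scales each tone by its complex impedance", {
  g <- ref_grid()
  Zi <- evaluate_on_grid(ref_model(), g)

  # resistor load: v = R * i
  t <- seq(0, g$global_period, length.out = 17)
  expect_equal(synthesize_voltage(rep(75 + 0i, 8), g, t), 75 * synthesize_current(g, t))

  # t = 0 projects onto the sum of real parts
  expect_equal(synthesize_voltage(Zi, g, 0), sum(Re(Zi)))

  # derived: direct 8-term summation at one clock tick
  t1 <- 1 / g$fclk
  oracle <- sum(Mod(Zi) * cos(2 * pi * g$frequencies * t1 + Arg(Zi)))
  expect_equal(synthesize_voltage(Zi, g, t1), oracle)

  expect_error(synthesize_voltage(Zi[1:3], g, 0), "per tone")
})

test_that("the ideal ADC reproduces the continuous voltage at exact clock times", {
  g <- ref_grid()
  Zi <- evaluate_on_grid(ref_model(), g)
  st <- sample_adc(Zi, g)
  n <- 0:(g$record_length - 1)
  expect_identical(st$values, synthesize_voltage(Zi, g, n / g$fclk))
  expect_equal(g$fclk, 1e6)

  # noiseless sampling is exactly periodic over the record
  st2 <- sample_adc(Zi, g, periods = 2)
  expect_equal(st2$values[1:512], st2$values[513:1024])
})

test_that("quantization is midtread with symmetric clipping", {
  g <- build_grid(1000, 1)
  # independent enumeration of the 12-bit midtread quantizer over +/-1 V:
  # levels k*q for integer k in [-2048, 2047], q = 2/4096
  q <- 2 / 2^12
  adc <- adc_config(resolution_bits = 12, full_scale = 1)
  st <- sample_adc(rep(0.5 + 0i, 1) * 1, g, adc)  # pure 0.5 V cosine tone
  v_exact <- 0.5 * cos(2 * pi * 1000 * (0:3) / 4000)
  expect_equal(st$values, pmin(pmax(round(v_exact / q), -2048), 2047) * q)
  expect_equal(st$codes[1], 1024)  # 0.5 V sits exactly on level 1024

  # over-range input clips with a warning
  big <- adc_config(resolution_bits = 8, full_scale = 0.25)
  expect_warning(sample_adc(rep(1 + 0i, 1), g, big), "clipped")
})

test_that("noise, jitter and seeding behave as configured", {
  g <- build_grid(250e3, 4)
  Zi <- evaluate_on_grid(cpe_model(1e-4, 0.5), g)

  a <- sample_adc(Zi, g, adc_config(noise_sigma = 0.1, seed = 99))
  b <- sample_adc(Zi, g, adc_config(noise_sigma = 0.1, seed = 99))
  expect_identical(a$values, b$values)  # bit-reproducible under a fixed seed
  c2 <- sample_adc(Zi, g, adc_config(noise_sigma = 0.1, seed = 100))
  expect_false(identical(a$values, c2$values))

  clean <- sample_adc(Zi, g)
  jit <- sample_adc(Zi, g, adc_config(jitter_sigma = 1e-9, seed = 5))
  expect_false(identical(clean$values, jit$values))
  # tiny jitter perturbs values only slightly
  expect_lt(max(abs(jit$values - clean$values)), 0.05 * max(abs(clean$values)))

  off <- sample_adc(Zi, g, adc_config(dc_offset = 0.25))
  expect_equal(off$values, clean$values + 0.25)
})

test_that("sample streams round-trip through CSV losslessly", {
  g <- build_grid(250e3, 5)
  st <- sample_adc(evaluate_on_grid(demo_circuit(), g), g,
                   adc_config(noise_sigma = 0.01, seed = 3), periods = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(st, path)
  back <- read_stream_csv(path)
  expect_identical(back$values, st$values)
  expect_equal(back$grid$f0, g$f0)
  expect_equal(back$grid$nf, g$nf)
  expect_equal(back$adc$noise_sigma, 0.01)

  expect_error(sample_stream(rnorm(37), g), "multiple of the record length")
})
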