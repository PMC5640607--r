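test_that("inverse regression reproduces the worked-example arithmetic", {
  fit <- data.frame(slope_a = 0.108, intercept_b = 11.77)
  b <- data.frame(heading_deg = 0, time_ms = 0, rate_hz = 11.77)
  expect_equal(decode_neuron(b, fit)$decoded_deg, 0)
  b$rate_hz <- 15.01
  expect_equal(decode_neuron(b, fit)$decoded_deg, 30, tolerance = 1e-9)
})

test_that("decoding inverts the tuning line at machine precision", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, -1, 1); if (abs(a) < 0.01) a <- 0.05
    b0 <- runif(1, 0, 30)
    x <- runif(5, -40, 40)
    binned <- data.frame(heading_deg = x, time_ms = 0,
                         rate_hz = a * x + b0)
    out <- decode_neuron(binned, data.frame(slope_a = a, intercept_b = b0))
    expect_equal(out$decoded_deg, x, tolerance = 1e-9)
  }
  expect_error(decode_neuron(data.frame(rate_hz = 1),
                             data.frame(slope_a = 0, intercept_b = 1)),
               "slope")
})

test_that("population readout is the median with midpoint convention", {
  d <- tibble::tibble(neuron_id = 1:3, heading_deg = 30, time_ms = 0,
                      decoded_deg = c(28, 30, 35))
  expect_equal(decode_population(d)$decoded_deg, 30)
  d4 <- tibble::tibble(neuron_id = 1:4, heading_deg = 30, time_ms = 0,
                       decoded_deg = c(10, 20, 30, 50))
  expect_equal(decode_population(d4)$decoded_deg, 25)
})

test_that("median readout ignores symmetric-error neuron pairs", {
  base <- tibble::tibble(neuron_id = 1:5, heading_deg = 0, time_ms = 0,
                         decoded_deg = c(-2, -1, 0, 1, 2))
  with_pair <- dplyr::bind_rows(
    base,
    tibble::tibble(neuron_id = 6:7, heading_deg = 0, time_ms = 0,
                   decoded_deg = c(-7, 7))
  )
  expect_equal(decode_population(base)$decoded_deg,
               decode_population(with_pair)$decoded_deg)
})

test_that("median readout is unbiased under symmetric noise", {
  set.seed(9)
  errs <- vapply(seq_len(50), function(i) {
    d <- tibble::tibble(neuron_id = 1:31, heading_deg = 15, time_ms = 0,
                        decoded_deg = 15 + rnorm(31, 0, 5))
    decode_population(d)$decoded_deg - 15
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(50))
})

test_that("bin-wise rank test separates and collapses as constructed", {
  bins <- peri_bins()
  set.seed(4)
  # fully separated noiseless decodes: every bin significant
  sep <- tidyr::expand_grid(neuron_id = 1:9, time_ms = bins) |>
    dplyr::mutate(heading_deg = rep(c(-30, 0, 30), each = 3)[neuron_id],
                  decoded_deg = heading_deg + neuron_id / 10)
  res <- binwise_separation_test(sep)
  expect_true(all(res$significant))

  # identical decodes in every heading: nothing significant
  same <- dplyr::mutate(sep, decoded_deg = 1)
  expect_false(any(binwise_separation_test(same)$significant))

  # collapse decodes to a point only within [80, 160): exactly those bins
  # lose significance
  coll <- dplyr::mutate(sep, decoded_deg = ifelse(
    time_ms >= 80 & time_ms < 160, 0, decoded_deg))
  res2 <- binwise_separation_test(coll)
  collapsed <- res2$time_ms >= 80 & res2$time_ms < 160
  expect_false(any(res2$significant[collapsed]))
  expect_true(all(res2$significant[!collapsed]))
})

test_that("two-bin running mean lands on midpoints", {
  d <- data.frame(time_ms = c(0, 20), decoded_deg = c(10, 20))
  out <- running_mean2(d)
  expect_equal(out$time_ms, 10)
  expect_equal(out$decoded_deg, 15)

  const <- data.frame(time_ms = peri_bins(), decoded_deg = 7)
  out2 <- running_mean2(const)
  expect_true(all(out2$decoded_deg == 7))
  expect_equal(out2$time_ms, peri_bins()[-33] + 10)

  alt <- data.frame(time_ms = seq(0, 180, 20),
                    decoded_deg = rep(c(0, 10), 5))
  expect_true(all(running_mean2(alt)$decoded_deg == 5))
})

test_that("compression curve is flat at 1 for constant separation", {
  d <- tidyr::expand_grid(heading_deg = c(-30, 0, 30),
                          time_ms = peri_bins()) |>
    dplyr::mutate(decoded_deg = heading_deg)
  cc <- compression_curve(d)
  expect_true(all(abs(cc$normalized_sd - 1) < 1e-12))
  expect_true(attr(cc, "flat"))
  expect_true(is.na(t_max_compression(cc)))
})

test_that("compression curve finds a constructed collapse", {
  d <- tidyr::expand_grid(heading_deg = c(-30, 0, 30),
                          time_ms = peri_bins()) |>
    dplyr::mutate(decoded_deg = ifelse(time_ms == 100, 0, heading_deg))
  cc <- compression_curve(d)
  expect_equal(t_max_compression(cc), 100)
  expect_equal(min(cc$normalized_sd), 0)
  expect_equal(attr(cc, "min_normalized_sd"), 0)
})

test_that("normalization-window mean is 1 by construction", {
  set.seed(11)
  for (i in 1:10) {
    d <- tidyr::expand_grid(heading_deg = c(-30, -15, 0, 15, 30),
                            time_ms = peri_bins()) |>
      dplyr::mutate(decoded_deg = heading_deg * runif(dplyr::n(), 0.2, 1.5))
    cc <- compression_curve(d)
    norm_bins <- (cc$time_ms >= -200 & cc$time_ms < -100) |
      (cc$time_ms >= 200 & cc$time_ms < 300)
    expect_lt(abs(mean(cc$normalized_sd[norm_bins]) - 1), 1e-9)
  }
})

test_that("degenerate heading series are rejected", {
  d <- tidyr::expand_grid(heading_deg = c(-30, 0, 30),
                          time_ms = peri_bins()) |>
    dplyr::mutate(decoded_deg = 0)
  expect_error(compression_curve(d), "degenerate")
  expect_error(compression_curve(dplyr::filter(
    dplyr::mutate(d, decoded_deg = heading_deg), heading_deg == 0)),
    "2 heading")
})

test_that("an unmodulated noisy population has a flat compression curve", {
  m <- run_suppression_model("identity", n_repetitions = 20, seed = 6)
  cc <- m$compression
  expect_true(all(cc$normalized_sd > 0.9 & cc$normalized_sd < 1.1))
})
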