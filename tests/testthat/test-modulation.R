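test_that("mean-subtracted modulation has the 33-bin arithmetic", {
  flat <- make_flat_binned(10)
  m <- response_modulation(flat)
  expect_true(all(m$modulation_hz == 0))

  # one bin dropped to zero: that bin sits 10 * 32/33 below the window mean
  dip <- dplyr::mutate(flat, rate_hz = ifelse(time_ms == 0, 0, 10))
  md <- response_modulation(dip)
  expect_equal(md$modulation_hz[md$time_ms == 0], -10 * 32 / 33)
  expect_equal(unique(md$modulation_hz[md$time_ms != 0]), 10 / 33)
  expect_equal(sum(md$modulation_hz), 0)
})

test_that("bootstrap CI is degenerate for identical neurons and reproducible", {
  tc <- tidyr::expand_grid(neuron_id = 1:5, time_ms = peri_bins()) |>
    dplyr::mutate(modulation_hz = cos(time_ms / 50))
  ci <- bootstrap_ci(tc, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, ci$mean)
  expect_equal(ci$ci_high, ci$mean)

  set.seed(12)
  tc2 <- dplyr::mutate(tc, modulation_hz = modulation_hz + rnorm(165))
  expect_identical(bootstrap_ci(tc2, n_boot = 200, seed = 3),
                   bootstrap_ci(tc2, n_boot = 200, seed = 3))
  expect_warning(bootstrap_ci(tc2, n_boot = 50, seed = 1), "noisy")
  expect_error(bootstrap_ci(dplyr::filter(tc, neuron_id == 1)), "2 neurons")
})

test_that("bootstrap CI covers the true mean at close to nominal rate", {
  set.seed(21)
  covered <- vapply(seq_len(200), function(i) {
    tc <- tibble::tibble(neuron_id = 1:30, time_ms = 0,
                         modulation_hz = rnorm(30))
    ci <- bootstrap_ci(tc, n_boot = 500)
    ci$ci_low <= 0 && ci$ci_high >= 0
  }, logical(1))
  # percentile bootstrap at n = 30 runs slightly below nominal
  expect_gt(mean(covered), 0.88)
  expect_lte(mean(covered), 1)
})

test_that("condition assignment follows the slope sign", {
  bins <- peri_bins()
  binned <- tidyr::expand_grid(neuron_id = 1:3,
                               heading_deg = c(-30, 0, 30),
                               time_ms = bins) |>
    dplyr::mutate(rate_hz = 10, n_snippets = 10L)
  fits <- tibble::tibble(neuron_id = 1:3, slope_a = c(-0.2, 0.2, 0))
  out <- assign_conditions(binned, fits)

  # zero-slope neuron excluded; 0 deg responses unused
  expect_false(3 %in% out$neuron_id)
  expect_false(0 %in% out$heading_deg)
  # leftward-tuned: leftward heading is congruent, rightward incongruent
  n1 <- dplyr::filter(out, neuron_id == 1)
  expect_equal(unique(n1$condition[n1$heading_deg == -30]), "congruent")
  expect_equal(unique(n1$condition[n1$heading_deg == 30]), "incongruent")
  # rightward-tuned: the reverse
  n2 <- dplyr::filter(out, neuron_id == 2)
  expect_equal(unique(n2$condition[n2$heading_deg == 30]), "congruent")
  expect_equal(unique(n2$condition[n2$heading_deg == -30]), "incongruent")
  # every included neuron contributes once to each condition
  tab <- dplyr::count(out, neuron_id, condition)
  expect_equal(nrow(tab), 4)
  expect_equal(unique(tab$n), length(bins))
})

test_that("modulation index is the peri/late rate ratio", {
  expect_equal(modulation_index(make_flat_binned(10))$index, 1)
  halved <- make_flat_binned(10, gain = 0.5, gain_window = c(40, 160))
  expect_equal(modulation_index(halved)$index, 0.5)
  zero_late <- make_flat_binned(10, gain = 0, gain_window = c(200, 460))
  res <- modulation_index(zero_late)
  expect_false(res$defined)
  expect_true(is.na(res$index))
})

test_that("an applied gain is recovered as the median index", {
  set.seed(8)
  idx <- vapply(seq_len(50), function(i) {
    lam <- 20 * 0.02 * 100          # 20 Hz, 20 ms bins, 100 snippets
    g <- ifelse(peri_bins() >= 40 & peri_bins() < 160, 0.7, 1)
    b <- tibble::tibble(neuron_id = 1, heading_deg = 0,
                        time_ms = peri_bins(),
                        rate_hz = rpois(33, lam * g) / (0.02 * 100))
    modulation_index(b)$index
  }, numeric(1))
  expect_lt(abs(median(idx) - 0.7), 0.05)
})

test_that("sign tests point in the condition-specific direction", {
  no_mod <- tibble::tibble(condition = rep(c("congruent", "incongruent"), 10),
                           index = 1)
  res <- index_sign_tests(no_mod, seed = 1)
  expect_true(all(res$p_sign == 1))
  expect_true(all(res$median == 1))

  supp <- tibble::tibble(condition = "congruent", index = rep(0.8, 20))
  res2 <- index_sign_tests(supp, seed = 2)
  expect_equal(res2$median, 0.8)
  # sign-test arithmetic: all 20 below 1 under a fair coin
  expect_equal(res2$p_sign, 0.5^20)
  expect_lt(res2$p_sign, 0.05)

  enh <- tibble::tibble(condition = "incongruent", index = rep(1.3, 12))
  expect_equal(index_sign_tests(enh, seed = 3)$p_sign, 0.5^12)
})

test_that("kernel extraction divides by the flank mean", {
  flat <- tibble::tibble(time_ms = peri_bins(), rate_hz = 12)
  k <- extract_kernels(flat)$global
  expect_true(all(k$gain == 1))

  dip <- tibble::tibble(time_ms = peri_bins(),
                        rate_hz = ifelse(peri_bins() >= 60 &
                                           peri_bins() < 100, 5, 10),
                        condition = "congruent")
  k2 <- extract_kernels(dip)$congruent
  expect_equal(k2$gain[k2$time_ms == 60], 0.5)
  expect_equal(k2$gain[k2$time_ms == -200], 1)
  fm <- mean(k2$gain[k2$time_ms < -100 | k2$time_ms >= 100])
  expect_lt(abs(fm - 1), 1e-9)
})

test_that("enhancement peaks later than suppression on selective data", {
  set.seed(31)
  kern <- model_kernels()
  tc <- purrr::map_dfr(1:40, function(i) {
    b <- 10 + runif(1, -2, 2)
    dplyr::bind_rows(
      tibble::tibble(neuron_id = i, condition = "congruent",
                     time_ms = peri_bins(),
                     rate_hz = b * kern$congruent$gain + rnorm(33, 0, 0.5)),
      tibble::tibble(neuron_id = i, condition = "incongruent",
                     time_ms = peri_bins(),
                     rate_hz = b * kern$incongruent$gain + rnorm(33, 0, 0.5))
    )
  })
  avg <- dplyr::summarise(tc, rate_hz = mean(rate_hz),
                          .by = c("condition", "time_ms"))
  t_supp <- avg$time_ms[avg$condition == "congruent"][
    which.min(avg$rate_hz[avg$condition == "congruent"])]
  t_enh <- avg$time_ms[avg$condition == "incongruent"][
    which.max(avg$rate_hz[avg$condition == "incongruent"])]
  expect_gt(t_enh, t_supp)
  expect_true(abs((t_enh - t_supp) - 40) <= 20)
})
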