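fs <- 250
tt <- (0:499) / fs

test_that("magnitude is the peak absolute amplitude", {
  expect_equal(compute_magnitude(10 * cos(2 * pi * 10 * tt)), 10)
  expect_equal(compute_magnitude(numeric(500)), 0)
  x <- c(rnorm(498), -12, 7)
  x[abs(x) > 6] <- 0; x[499] <- -12; x[500] <- 7
  expect_equal(compute_magnitude(x), 12)
})

test_that("periodogram concentrates a 10 Hz line, satisfies Parseval, and is flat for white noise", {
  x <- sin(2 * pi * 10 * tt)
  sp <- compute_spectrum(x)
  in_line <- band_power(sp, 9.5, 10.5, lower_closed = TRUE)
  expect_gt(in_line / band_power(sp, 0.5, 47), 0.95)

  # Parseval for the windowed signal
  w <- hann_oracle(500)
  expect_equal(sum(sp$power), mean((x * w)^2), tolerance = 1e-12)

  set.seed(31)
  acc <- numeric(251)
  for (i in 1:1000) acc <- acc + compute_spectrum(rnorm(500))$power
  acc <- acc / 1000
  sel <- sp$frequencies >= 1 & sp$frequencies <= 46
  expect_lt(max(abs(acc[sel] / mean(acc[sel]) - 1)), 0.10)
})

test_that("band powers and ratios match the direct-DFT oracle to 1e-9", {
  set.seed(32)
  x <- rnorm(500, sd = 8)
  sp <- compute_spectrum(x)
  so <- spectrum_oracle(x)
  expect_equal(sp$power, so$power, tolerance = 1e-9)
  for (band in list(c(0.5, 47), c(8, 13), c(13, 30), c(4, 8), c(30, 47), c(1, 4)))
    expect_equal(band_power(sp, band[1], band[2]),
                 band_power_oracle(so, band[1], band[2]), tolerance = 1e-9)
})

test_that("power ratios follow the printed band definitions", {
  # pure 10 Hz line: all power in the alpha band
  sp <- compute_spectrum(sin(2 * pi * 10 * tt))
  pr <- compute_power_ratios(sp)
  expect_gt(pr$alpha_pr, 0.95)
  expect_lt(pr$beta_pr, 0.05)

  # exactly flat synthetic spectrum: delta_r = log(24 bins / 6 bins) = log 4
  flat <- structure(list(frequencies = seq(0, 125, by = 0.5),
                         power = rep(1, 251), fs = 250, n = 500),
                    class = "eeg_spectrum")
  prf <- compute_power_ratios(flat)
  expect_equal(prf$delta_r, log(4), tolerance = 1e-12)
  expect_equal(prf$beta_r, log(band_power(flat, 30, 47, FALSE) /
                                 band_power(flat, 11, 20, FALSE)), tolerance = 1e-12)

  # band partition identity holds exactly for any spectrum
  set.seed(33)
  for (i in 1:5) {
    pr2 <- compute_power_ratios(compute_spectrum(rnorm(500)))
    expect_equal(pr2$bg_alpha_plus + pr2$delta_pr + pr2$theta_pr, 1,
                 tolerance = 1e-12)
    expect_true(all(unlist(pr2[c("alpha_pr", "beta_pr", "delta_pr",
                                 "theta_pr", "bg_alpha_plus")]) >= 0))
    expect_true(all(unlist(pr2[c("alpha_pr", "beta_pr", "delta_pr",
                                 "theta_pr", "bg_alpha_plus")]) <= 1))
  }

  # degenerate signal: zero denominator bands -> NA markers with warnings
  w <- capture_warnings(pr3 <- compute_power_ratios(compute_spectrum(numeric(500))))
  expect_true(any(grepl("undefined feature", w)))
  expect_true(all(is.na(unlist(pr3))))
})

test_that("bispectrum: zero signal, quadratic phase coupling, Gaussian decay", {
  zero <- compute_bispectrum(list(numeric(500), numeric(500), numeric(500)))
  expect_true(all(zero$magnitude == 0))

  # coupled triple (6, 10, 16 Hz, locked phases) vs uncoupled
  set.seed(34)
  mk <- function(coupled) {
    lapply(1:3, function(i) {
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      p3 <- if (coupled) p1 + p2 else runif(1, 0, 2 * pi)
      cos(2 * pi * 6 * tt + p1) + cos(2 * pi * 10 * tt + p2) +
        cos(2 * pi * 16 * tt + p3)
    })
  }
  peak_at <- function(bis, f1, f2) bis$magnitude[bis$f1 == f1 & bis$f2 == f2]
  bc <- compute_bispectrum(mk(TRUE))
  peak_c <- peak_at(bc, 6, 10)
  others <- bc$magnitude[!(bc$f1 == 6 & bc$f2 == 10) & bc$fsum >= 1]
  expect_gt(peak_c / (mean(others) + 1e-300), 50)

  # uncoupled windows: the complex 3-window mean at (6,10) behaves like the
  # mean of 3 random unit phasors, ~1/sqrt(3) of the phase-locked magnitude
  pk_unc <- replicate(40, peak_at(compute_bispectrum(mk(FALSE)), 6, 10))
  expect_gt(peak_c / mean(pk_unc), 1.3)
  expect_lt(mean(pk_unc) / peak_c, 0.85)

  # Gaussian noise, many averaged estimates: the (6,10) magnitude collapses
  # relative to the coupled case
  pk_noise <- replicate(30,
    peak_at(compute_bispectrum(lapply(1:3, function(i) rnorm(500))), 6, 10))
  expect_lt(mean(pk_noise) / peak_c, 0.05)
})

test_that("SynchFastSlow follows log(B[0.5-47]/B[40-47]) and matches brute force", {
  fake <- function(num, den) {
    structure(list(f1 = c(5, 21), f2 = c(5, 21), fsum = c(10, 42),
                   magnitude = c(num - den, den), n_windows = 3, fs = 250, n = 500),
              class = "bispectrum")
  }
  expect_equal(compute_synch_fast_slow(fake(2, 1)), log(2 / 1))
  expect_equal(compute_synch_fast_slow(fake(exp(1), 1)), 1)
  b0 <- fake(1, 1)  # B[0.5-47] == B[40-47]
  b0$magnitude <- c(0, 1)
  expect_equal(compute_synch_fast_slow(b0), 0)

  set.seed(35)
  subs <- lapply(1:3, function(i) rnorm(500, sd = 5))
  bis <- compute_bispectrum(subs)
  expect_equal(band_bispectrum(bis, 0.5, 47),
               bispectrum_band_oracle(subs, 0.5, 47), tolerance = 1e-9)
  expect_equal(compute_synch_fast_slow(bis),
               log(bispectrum_band_oracle(subs, 0.5, 47) /
                     bispectrum_band_oracle(subs, 40, 47)), tolerance = 1e-9)
})

test_that("log energy entropy: direct values and refinement growth", {
  expect_equal(compute_log_energy_entropy(rep(0.25, 4)), 4 * log(0.25)^2)
  expect_equal(4 * log(0.25)^2, 7.6872482, tolerance = 1e-7)
  expect_equal(compute_log_energy_entropy(1), 0)

  # splitting any bin's mass strictly increases the value
  set.seed(36)
  for (i in 1:20) {
    p <- as.vector(prop.table(runif(4)))
    j <- sample(4, 1)
    frac <- runif(1, 0.1, 0.9)
    p_split <- c(p[-j], p[j] * frac, p[j] * (1 - frac))
    expect_gt(compute_log_energy_entropy(p_split), compute_log_energy_entropy(p))
  }
  expect_error(compute_log_energy_entropy(numeric(0)), "empty support")
})

test_that("Renyi entropy: uniform, closed form, Shannon limit, alpha monotonicity", {
  for (n in c(2, 5, 94)) {
    for (a in c(0.25, 0.5, 2))
      expect_equal(compute_renyi_entropy(rep(1 / n, n), alpha = a), log(n))
  }
  expect_equal(compute_renyi_entropy(c(0.5, 0.25, 0.25), alpha = 0.5),
               2 * log(sqrt(0.5) + sqrt(0.25) + sqrt(0.25)))
  expect_equal(2 * log(sqrt(0.5) + sqrt(0.25) + sqrt(0.25)), 1.0695999935,
               tolerance = 1e-9)

  set.seed(37)
  p <- as.vector(prop.table(runif(10)))
  shannon <- -sum(p * log(p))
  expect_equal(compute_renyi_entropy(p, alpha = 1 - 1e-7), shannon, tolerance = 1e-5)
  expect_equal(compute_renyi_entropy(p, alpha = 1 + 1e-7), shannon, tolerance = 1e-5)
  expect_error(compute_renyi_entropy(p, alpha = 1), "Shannon")

  h <- vapply(c(0.1, 0.3, 0.5, 0.9, 1.5, 2, 5), function(a)
    compute_renyi_entropy(p, alpha = a), numeric(1))
  expect_true(all(diff(h) <= 1e-12))
})

test_that("probability model sources behave as documented", {
  set.seed(38)
  x <- rnorm(500, sd = 6)
  pm_sp <- probability_model(x, "spectral_bins")
  expect_length(pm_sp$p, 94)                      # 0.5-47 Hz at 0.5 Hz bins
  expect_equal(sum(pm_sp$p), 1)
  pm_se <- probability_model(x, "sample_energy")
  expect_equal(sum(pm_se$p), 1)
  pm_h <- probability_model(x, "amplitude_histogram", n_bins = 16)
  expect_length(pm_h$p, 16)
  expect_equal(sum(pm_h$p), 1)
  pm_e <- probability_model(x, "energy")
  expect_false(pm_e$normalized)
  expect_equal(pm_e$p, x^2)
})

test_that("scaling the signal scales magnitude and leaves shape features unchanged", {
  set.seed(39)
  x <- rnorm(750, sd = 5)
  cfg <- feature_config(filter = FALSE, probability_source = "spectral_bins")
  f1 <- compute_feature_vector(x, cfg)
  f3 <- compute_feature_vector(3 * x, cfg)
  expect_equal(f3[["magnitude"]], 3 * f1[["magnitude"]])
  shape <- c("beta_r", "delta_r", "alpha_pr", "beta_pr", "delta_pr",
             "theta_pr", "bg_alpha_plus", "synch_fast_slow",
             "log_energy_entropy", "renyi_entropy")
  expect_equal(f3[shape], f1[shape], tolerance = 1e-9)

  cfg2 <- feature_config(filter = FALSE, probability_source = "sample_energy")
  g1 <- compute_feature_vector(x, cfg2)
  g3 <- compute_feature_vector(3 * x, cfg2)
  expect_equal(g3[c("log_energy_entropy", "renyi_entropy")],
               g1[c("log_energy_entropy", "renyi_entropy")], tolerance = 1e-9)
})

test_that("epoch feature vector averages the three sub-epochs and composes from parts", {
  # a 2 Hz tone has period 125 samples, so the three sub-epochs are identical
  x <- 7 * sin(2 * pi * 2 * (0:749) / 250)
  cfg <- feature_config(filter = FALSE)
  fv <- compute_feature_vector(x, cfg)
  sub1 <- make_subepochs(x)[[1]]
  expect_equal(fv[["magnitude"]], compute_magnitude(sub1))
  expect_equal(fv[["delta_pr"]],
               compute_power_ratios(compute_spectrum(sub1$eeg))$delta_pr)

  # component-wise independent recomputation on a random epoch
  set.seed(40)
  y <- rnorm(750, sd = 4)
  fv2 <- compute_feature_vector(y, cfg)
  subs <- make_subepochs(y)
  per <- sapply(subs, function(se) {
    sp <- compute_spectrum(se$eeg)
    pr <- compute_power_ratios(sp)
    pm <- probability_model(se$eeg, "energy")
    c(magnitude = compute_magnitude(se$eeg), unlist(pr),
      log_energy_entropy = compute_log_energy_entropy(pm),
      renyi_entropy = compute_renyi_entropy(pm, 0.5))
  })
  expect_equal(fv2[["magnitude"]], mean(per["magnitude", ]))
  expect_equal(fv2[["alpha_pr"]], mean(per["alpha_pr", ]))
  expect_equal(fv2[["log_energy_entropy"]], mean(per["log_energy_entropy", ]))
  expect_equal(fv2[["renyi_entropy"]], mean(per["renyi_entropy", ]))
  expect_equal(fv2[["synch_fast_slow"]],
               compute_synch_fast_slow(compute_bispectrum(subs)))
})
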