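test_that("baseline normalization reproduces constructed LTP magnitudes", {
  flat <- generate_ltp_series(100, 1.0, noise_sd = 0, seed = 1)
  expect_equal(normalize_timecourse(flat)$ltp_percent, 100)
  expect_true(all(flat$amplitude_pa == 100))
  step <- generate_ltp_series(100, 2.18, noise_sd = 0, seed = 1)
  res <- normalize_timecourse(step)
  expect_equal(res$ltp_percent, 218)
  expect_equal(res$baseline_mean, 100)
  # baseline-window normalized mean is 1 by construction
  nb <- res$normalized$normalized[res$normalized$time_s >= -480 &
                                    res$normalized$time_s <= 0]
  expect_equal(mean(nb), 1)
})

test_that("normalization is scale invariant and sign insensitive", {
  s <- generate_ltp_series(120, 1.7, noise_sd = 4, seed = 3)
  r1 <- normalize_timecourse(s)
  s2 <- s
  s2$amplitude_pa <- -5 * s$amplitude_pa # inward currents, different gain
  r2 <- normalize_timecourse(s2, event_time = 0,
                             baseline_window = c(-480, 0),
                             post_window = c(1800, 2400))
  expect_equal(r2$normalized$normalized, r1$normalized$normalized)
  expect_equal(r2$ltp_percent, r1$ltp_percent)
})

test_that("noisy synthetic LTP recovers the generator's ratio", {
  s <- generate_ltp_series(100, 2.18, noise_sd = 5, seed = 17)
  res <- normalize_timecourse(s)
  n_post <- sum(s$time_s >= 1800 & s$time_s <= 2400)
  sem <- 5 / sqrt(n_post)
  expect_lt(abs(res$ltp_percent - 218), 3 * sem)
})

test_that("paired-pulse ratio is a plain amplitude ratio", {
  expect_equal(paired_pulse_ratio(90, 171), 1.9)
  expect_equal(paired_pulse_ratio(55, 55), 1)
  expect_equal(paired_pulse_ratio(80, 0), 0)
  expect_equal(paired_pulse_ratio(-90, -171), 1.9) # unit/sign invariance
  expect_error(paired_pulse_ratio(0, 50), class = "spinemorph_parameter_error")
})

test_that("NMDAR/AMPAR ratio uses magnitudes", {
  expect_equal(nmdar_ampar_ratio(36, 100), 36)
  expect_equal(nmdar_ampar_ratio(-50, 50), 100)
  expect_equal(nmdar_ampar_ratio(36, -100), nmdar_ampar_ratio(-36, 100))
  expect_error(nmdar_ampar_ratio(10, 0), class = "spinemorph_parameter_error")
})

test_that("tonic current shift compares last-minute window means", {
  t <- seq(0, 900, by = 1)
  flat <- tibble::tibble(time_s = t, holding_pa = 120)
  expect_equal(tonic_current_shift(flat, drug_onset = 300), 0)
  stepped <- tibble::tibble(time_s = t,
                            holding_pa = ifelse(t < 300, 120, 120 - 34))
  expect_equal(tonic_current_shift(stepped, drug_onset = 300), 34)
  # pure linear drift: difference equals drift rate times the separation
  # of the two window centres
  drift <- tibble::tibble(time_s = t, holding_pa = 100 + 0.02 * t)
  sep <- mean(t[t >= 600 & t <= 660]) - mean(t[t >= 240 & t < 300])
  expect_equal(tonic_current_shift(drift, drug_onset = 300),
               -0.02 * sep, tolerance = 1e-9)
  expect_error(tonic_current_shift(flat, drug_onset = 890),
               class = "spinemorph_parameter_error")
})

test_that("displacement index follows its defining formula", {
  expect_equal(displacement_index(30, 30), 50)
  expect_equal(displacement_index(68.2, 31.8), 68.2)
  expect_equal(displacement_index(12, 0), 100)
  expect_error(displacement_index(0, 0),
               class = "spinemorph_undefined_index_error")
  # novel + familiar indices partition 100%
  set.seed(3)
  tn <- runif(20, 1, 60)
  tf <- runif(20, 1, 60)
  expect_equal(displacement_index(tn, tf) + displacement_index(tf, tn),
               rep(100, 20))
})

test_that("novel-arm fraction is time share in percent", {
  expect_equal(novel_arm_fraction(c(n = 20, s = 20, o = 20), "n"), 100 / 3)
  expect_equal(novel_arm_fraction(c(n = 10, s = 0, o = 0), "n"), 100)
  expect_equal(novel_arm_fraction(c(n = 40.5, s = 30, o = 29.5), "n"), 40.5)
  expect_error(novel_arm_fraction(c(n = 0, s = 0), "n"),
               class = "spinemorph_parameter_error")
})

test_that("specific binding subtracts, normalizes, averages and clips", {
  one <- specific_binding(0.85, 0.10, 0.010)
  expect_equal(one$specific_binding, 75)
  zero <- specific_binding(0.4, 0.4, 0.010)
  expect_equal(zero$specific_binding, 0)
  expect_false(zero$clipped)
  # duplicates are averaged before subtraction
  dup <- specific_binding(c(0.8, 0.9), c(0.1, 0.1), c(0.01, 0.01),
                          id = c("a", "a"))
  expect_equal(dup$specific_binding, (0.85 - 0.1) / 0.01)
  neg <- specific_binding(0.2, 0.3, 0.01)
  expect_equal(neg$specific_binding, 0)
  expect_true(neg$clipped)
  expect_error(specific_binding(1, 0.1, 0), class = "spinemorph_parameter_error")
})

test_that("behavioral generator means follow the preference parameter", {
  none <- generate_behavior_trials(list(g = list(preference = 0.5)), 400,
                                   seed = 2)
  di <- displacement_index(none$t_novel, none$t_familiar)
  expect_lt(abs(mean(di) - 50), 3 * sd(di) / sqrt(400))
  full <- generate_behavior_trials(list(g = list(preference = 1)), 50,
                                   seed = 3)
  expect_true(all(full$t_familiar == 0))
  expect_equal(displacement_index(full$t_novel, full$t_familiar), rep(100, 50))
  pref <- generate_behavior_trials(list(g = list(preference = 0.68)), 200,
                                   seed = 4)
  di2 <- displacement_index(pref$t_novel, pref$t_familiar)
  expect_lt(abs(mean(di2) - 68), 3 * sd(di2) / sqrt(200))
})

test_that("y-maze trials have three arms summing sensibly", {
  ym <- generate_behavior_trials(list(g = list(preference = 0.405)), 300,
                                 seed = 5, task = "ymaze")
  fr <- vapply(seq_len(nrow(ym)), function(i)
    novel_arm_fraction(c(ym$t_novel[i], ym$t_start[i], ym$t_other[i]), 1),
    numeric(1))
  expect_lt(abs(mean(fr) - 40.5), 3 * sd(fr) / sqrt(300))
})

test_that("binding generator round-trips its target density", {
  bp <- generate_binding_points(38, n_animals = 20, cv = 0.05, seed = 6)
  sb <- specific_binding(bp$total, bp$nonspecific, bp$protein, bp$id)
  expect_equal(nrow(sb), 20)
  expect_lt(abs(mean(sb$specific_binding) - 38) / 38, 0.1)
})

test_that("ltp glance() summarizes the result", {
  g <- glance(normalize_timecourse(generate_ltp_series(100, 2, 0, seed = 1)))
  expect_named(g, c("baseline_mean", "ltp_percent", "n_sweeps"))
  expect_equal(g$ltp_percent, 200)
})
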