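test_that("head volume follows the sphere model", {
  expect_equal(head_volume(0.44), pi / 6 * 0.44^3)
  expect_equal(head_volume(1), pi / 6)
  expect_equal(head_volume(0.6) / head_volume(0.3), 8)
  expect_equal(head_volume(0.1, model = "user_supplied", volume = 0.2), 0.2)
  expect_error(head_volume(-1), class = "spinemorph_parameter_error")
})

test_that("neck cross-section follows the disc model", {
  expect_equal(neck_cross_section(0.2), pi / 4 * 0.04)
  expect_equal(neck_cross_section(2 / sqrt(pi)), 1)
  expect_equal(neck_cross_section(0.4) / neck_cross_section(0.2), 4)
  expect_error(neck_cross_section(0), class = "spinemorph_parameter_error")
})

test_that("compartmentalization factor is V L / A", {
  expect_equal(compartmentalization_factor(0.05, 0.2, 0.03), 1 / 3)
  expect_equal(compartmentalization_factor(1, 1, 1), 1)
  expect_error(compartmentalization_factor(1, -1, 1),
               class = "spinemorph_parameter_error")
})

test_that("compensating morphology changes leave cf unchanged", {
  # wild-type-like baseline
  d0 <- 0.44
  L0 <- 0.38
  w0 <- 0.16
  cf0 <- compartmentalization_factor(head_volume(d0), L0,
                                     neck_cross_section(w0))
  # larger head, shorter neck; the neck widens by exactly the factor that
  # cancels both changes
  d1 <- d0 * 1.11
  L1 <- L0 * 0.74
  w1 <- w0 * sqrt((d1 / d0)^3 * (L1 / L0))
  cf1 <- compartmentalization_factor(head_volume(d1), L1,
                                     neck_cross_section(w1))
  expect_lt(abs(cf1 - cf0), 1e-12)
  expect_gt(d1, d0)
  expect_lt(L1, L0)
  expect_gt(w1, w0)
})

test_that("cf scales as length squared under isotropic rescaling", {
  for (k in c(0.5, 2, 3.7)) {
    cf1 <- compartmentalization_factor(head_volume(0.44), 0.38,
                                       neck_cross_section(0.16))
    cfk <- compartmentalization_factor(head_volume(0.44 * k), 0.38 * k,
                                       neck_cross_section(0.16 * k))
    expect_equal(cfk, cf1 * k^2, tolerance = 1e-12)
  }
})

test_that("the time constant is cf over D", {
  expect_equal(diffusion_time_constant(1.35, 0.45), 3)
  expect_equal(diffusion_time_constant(0.7, 0.7), 1)
  expect_equal(diffusion_time_constant(1.35, 0.9),
               diffusion_time_constant(1.35, 0.45) / 2)
  expect_error(diffusion_time_constant(1, 0),
               class = "spinemorph_parameter_error")
})

test_that("add_compartmentalization appends V, A, cf, tau per spine", {
  tbl <- tibble::tibble(head_width = c(0.44, NA), neck_length = c(0.38, 0.3),
                        neck_width = c(0.16, 0.2))
  out <- add_compartmentalization(tbl, D = 0.45)
  expect_equal(out$cf[1], pi / 6 * 0.44^3 * 0.38 / (pi / 4 * 0.16^2))
  expect_equal(out$tau[1], out$cf[1] / 0.45)
  expect_true(is.na(out$cf[2]))
})

test_that("simulated recovery equilibrates and respects stability", {
  rc <- simulate_diffusional_recovery(0.02, 0.05, 0.05, D = 0.45, t_end = 0.5)
  expect_gt(rc$concentration[length(rc$time)], 0.99)
  expect_true(all(diff(rc$time) > 0))
  expect_true(all(rc$concentration <= 1 + 1e-9))
  expect_error(simulate_diffusional_recovery(0.05, 0.5, 0.01, D = 0.5,
                                             dt = 1),
               class = "spinemorph_configuration_error")
})

test_that("fast-equilibration limit recovers within five time constants", {
  rc <- simulate_diffusional_recovery(0.25, 0.05, 0.2, D = 0.45)
  tau <- attr(rc, "tau_analytic")
  at5 <- rc$concentration[which(rc$time >= 5 * tau)[1]]
  expect_gt(at5, 0.99)
})

test_that("fitted tau matches V L / (A D) in the long-neck-resistance regime", {
  rc <- simulate_diffusional_recovery(0.05, 0.5, 0.01, D = 0.5)
  tau <- fit_exponential_tau(rc)$tau
  expect_lt(abs(tau / 5 - 1), 0.10)
})

test_that("exponential fitting is exact on exact inputs and rescales", {
  t <- seq(0, 12, by = 0.05)
  curve <- tibble::tibble(time = t, concentration = 1 - exp(-t / 2))
  fit <- fit_exponential_tau(curve)
  expect_lt(abs(fit$tau - 2), 1e-4)
  for (k in c(0.5, 3)) {
    ck <- tibble::tibble(time = t * k, concentration = 1 - exp(-t / 2))
    expect_lt(abs(fit_exponential_tau(ck)$tau / (2 * k) - 1), 1e-4)
  }
})

test_that("the one-compartment reduction breaks down for bulky necks", {
  # neck volume comparable to the head: single-exponential tau deviates
  V <- 0.01
  L <- 1
  A <- 0.01 # A L / V = 1
  rc <- simulate_diffusional_recovery(V, L, A, D = 0.45)
  tau <- fit_exponential_tau(rc)$tau
  expect_gt(abs(tau / attr(rc, "tau_analytic") - 1), 0.10)
})
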