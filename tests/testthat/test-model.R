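test_that("the ODE right-hand side matches the compartment equations", {
  state <- setNames(numeric(7), c("A_gut", "A_liver", "G_a", "P_gut", "G_p",
                                  "B_gut", "G_b"))
  parms <- c(unclass(rate_constants()), V = 11.25)
  # all rates zero: zero derivative for any state
  st <- state; st[] <- c(9.6, 1, 0.5, 4, 0.2, 0.9, 0.1)
  expect_equal(scfa_ode(0, st, parms)[[1]], rep(0, 7), ignore_attr = TRUE)
  # acetate gut arithmetic
  parms2 <- parms; parms2[c("k1a", "k0a")] <- c(0.01, 0.02)
  st2 <- state; st2["A_gut"] <- 9.6
  d <- scfa_ode(0, st2, parms2)[[1]]
  expect_equal(d[[1]], -0.288)
  expect_equal(d[[2]], 0.096)
  # plasma clearance is independent of V
  for (V in c(5, 11.25, 20)) {
    p3 <- parms; p3["k2"] <- 0.02; p3["V"] <- V
    st3 <- state; st3["G_p"] <- 1
    expect_equal(scfa_ode(0, st3, p3)[[1]][[5]], -0.02)
  }
  expect_error(scfa_ode(0, state, c(unclass(rate_constants()), V = 0)),
               "volume")
})

test_that("gut pool decays with the expected half-life", {
  k <- rate_constants(k0a = log(2) / 100)
  st <- gutflux:::.simulate_states(k, tracer_dose(), subject_profile(),
                                   times = c(50, 100))
  expect_equal(st$A_gut[st$time == 100], 4.8, tolerance = 1e-6)
})

test_that("simulated G_p matches the two-exponential closed form", {
  k <- rate_constants(k1p = 0.004, k0p = 0.009, k2 = 0.015)
  dose <- tracer_dose(); sub <- subject_profile()
  times <- seq(5, 300, by = 5)
  sim <- simulate_curves(k, dose, sub, times)
  gp <- sim$value[sim$source == "propionate"]
  expect_equal(gp, bateman_gp(times, 0.004, 0.009, 0.015, 4, sub$v_plasma_l),
               tolerance = 1e-7)
})

test_that("the full system matches its matrix-exponential solution", {
  setup <- ref_setup()
  times <- c(10, 60, 150, 210)
  st <- gutflux:::.simulate_states(setup$k, setup$dose, setup$subject, times)
  oracle <- expm_states(times, unclass(setup$k), setup$dose,
                        setup$subject$v_plasma_l)
  for (nm in colnames(oracle))
    expect_equal(st[[nm]], unname(oracle[, nm]), tolerance = 1e-7)
})

test_that("label is conserved on every branch", {
  setup <- ref_setup()
  k <- unclass(setup$k); V <- setup$subject$v_plasma_l
  st <- gutflux:::.simulate_states(setup$k, setup$dose, setup$subject,
                                   times = c(60, 210), cumulative = TRUE)
  last <- st[nrow(st), ]
  # pools + integrated losses + integrated clearance == delivered dose
  tot_a <- last$A_gut + last$A_liver + V * last$G_a +
    k[["k0a"]] * last$int_A + k[["k2"]] * V * last$int_Ga
  tot_p <- last$P_gut + V * last$G_p + k[["k0p"]] * last$int_P +
    k[["k2"]] * V * last$int_Gp
  tot_b <- last$B_gut + V * last$G_b + k[["k0b"]] * last$int_B +
    k[["k2"]] * V * last$int_Gb
  expect_equal(tot_a, 9.6, tolerance = 1e-6 * 9.6)
  expect_equal(tot_p, 4, tolerance = 1e-6 * 4)
  expect_equal(tot_b, 0.9, tolerance = 1e-6 * 0.9)
})

test_that("curves stay non-negative for random non-negative constants", {
  set.seed(11)
  for (i in 1:10) {
    k <- random_rate_constants()
    sim <- simulate_curves(k, tracer_dose(), subject_profile(),
                           times = seq(1, 400, by = 20))
    expect_true(all(sim$value >= -1e-10))
  }
})

test_that("simulation rejects invalid time grids", {
  setup <- ref_setup()
  expect_error(simulate_curves(setup$k, setup$dose, setup$subject,
                               times = c(-5, 10)), ">= 0")
  expect_error(simulate_curves(setup$k, setup$dose, setup$subject,
                               times = c(10, 10, 20)), "increasing")
})

test_that("dose constructors compute the delivered pools", {
  d <- dose_from_infusion()
  expect_equal(unname(d$mmol), c(9.6, 4, 0.9))
  expect_error(tracer_dose(acetate = -1), ">= 0")
  expect_error(subject_profile(body_weight_kg = 0), "> 0")
  expect_equal(subject_profile(body_weight_kg = 80)$v_plasma_l, 12)
})
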