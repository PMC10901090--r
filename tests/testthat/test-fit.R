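noiseless_curves <- function(setup, times = seq(0, 210, 15)) {
  simulate_curves(setup$k, setup$dose, setup$subject, times)
}

test_that("weighted SSE matches its definition and scaling law", {
  setup <- ref_setup()
  obs <- noiseless_curves(setup)
  obs$sd <- 0.01
  # observed equals simulation -> zero
  expect_equal(weighted_sse(obs, setup$k, setup$dose, setup$subject), 0,
               tolerance = 1e-12)
  # one point, residual 0.2, sd 0.1 -> 4
  one <- data.frame(subject = "s", time_min = 60, source = "propionate",
                    value = 0, sd = 0.1)
  pred <- simulate_curves(setup$k, setup$dose, setup$subject, 60)
  one$value <- pred$value[pred$source == "propionate"] - 0.2
  expect_equal(weighted_sse(one, setup$k, setup$dose, setup$subject), 4,
               tolerance = 1e-9)
  # doubling all sd divides the objective by 4
  obs2 <- obs; obs2$value <- obs2$value + 0.02
  sse1 <- weighted_sse(obs2, setup$k, setup$dose, setup$subject)
  obs2$sd <- obs2$sd * 2
  expect_equal(weighted_sse(obs2, setup$k, setup$dose, setup$subject),
               sse1 / 4, tolerance = 1e-9)
  obs_bad <- obs; obs_bad$sd <- 0
  expect_error(weighted_sse(obs_bad, setup$k, setup$dose, setup$subject),
               "sd")
})

test_that("the two RMSE forms agree on ranking", {
  setup <- ref_setup()
  obs <- noiseless_curves(setup)
  expect_equal(rmse(obs, setup$k, setup$dose, setup$subject), 0)
  # two candidate parameter sets rank identically under both forms
  k_off1 <- setup$k; k_off1["k2"] <- 0.02
  k_off2 <- setup$k; k_off2["k2"] <- 0.05
  lit <- sapply(list(k_off1, k_off2), function(kk)
    rmse(obs, kk, setup$dose, setup$subject, form = "literal"))
  conv <- sapply(list(k_off1, k_off2), function(kk)
    rmse(obs, kk, setup$dose, setup$subject, form = "conventional"))
  expect_equal(order(lit), order(conv))
  expect_equal(conv, sqrt(lit / nrow(obs)))
})

test_that("noiseless data give near-exact recovery of the six free constants", {
  setup <- ref_setup()
  obs <- noiseless_curves(setup)
  free <- c("k1a", "k1p", "k1b", "k2", "k0a", "k0b")
  truth <- unclass(setup$k)[free]
  fit <- fit_rate_constants(obs, setup$dose, setup$subject,
                            start = setNames(2 * truth, free))
  expect_true(fit$converged)
  expect_lt(max(abs(unclass(fit$estimated)[free] - truth) / truth), 1e-3)
  expect_equal(fit$fractions, fractional_incorporation(setup$k),
               tolerance = 1e-3)
  # default cold start lands on the same optimum
  fit2 <- fit_rate_constants(obs, setup$dose, setup$subject)
  expect_lt(max(abs(unclass(fit2$estimated)[free] - truth) / truth), 1e-3)
})

test_that("fit is invariant to curve row order", {
  setup <- ref_setup()
  obs <- noiseless_curves(setup)
  obs$sd <- 0.005
  set.seed(3)
  obs$value <- pmax(0, obs$value + rnorm(nrow(obs), 0, 0.002))
  fit1 <- fit_rate_constants(obs, setup$dose, setup$subject)
  fit2 <- fit_rate_constants(obs[sample(nrow(obs)), ], setup$dose,
                             setup$subject)
  expect_equal(unclass(fit1$estimated), unclass(fit2$estimated),
               tolerance = 1e-6)
})

test_that("zero-information data push uptake constants to the lower bound", {
  setup <- ref_setup()
  obs <- data.frame(subject = "s",
                    time_min = rep(seq(15, 210, 15), 3),
                    source = rep(c("acetate", "propionate", "butyrate"),
                                 each = 14),
                    value = 0, sd = 0.01)
  fit <- fit_rate_constants(obs, setup$dose, setup$subject)
  est <- unclass(fit$estimated)
  expect_equal(unname(est[c("k1a", "k1p", "k1b")]), rep(0, 3),
               tolerance = 1e-8)
})

test_that("grid search returns the generating node on a small exact grid", {
  setup <- ref_setup()
  obs <- noiseless_curves(setup)
  grids <- list(kLa = c(0.004, 0.0071, 0.012), k0p = c(0.006, 0.0109, 0.016))
  gs <- grid_fix(obs, setup$dose, setup$subject, grids = grids)
  expect_equal(unname(gs$fixed), c(0.0071, 0.0109))
  expect_equal(nrow(gs$table), 9)
  # single-point grid returns that point
  gs1 <- grid_fix(obs, setup$dose, setup$subject,
                  grids = list(kLa = 0.0071, k0p = 0.0109))
  expect_equal(unname(gs1$fixed), c(0.0071, 0.0109))
  expect_error(grid_fix(obs, setup$dose, setup$subject,
                        grids = list(kLa = 2, k0p = 0.01)), "\\[0, 1\\]")
})

test_that("default grid is log-spaced on [1e-4, 1] plus zero", {
  g <- default_grid()
  expect_equal(length(g), 51)
  expect_equal(g[1], 0)
  expect_equal(range(g[-1]), c(1e-4, 1))
})

test_that("fractional incorporation is the rate-constant ratio", {
  expect_equal(
    fractional_incorporation(rate_constants(k1p = 0.01, k0p = 0.03))[["propionate"]],
    0.25)
  expect_equal(
    fractional_incorporation(rate_constants(k1b = 0.01, k0b = 0))[["butyrate"]], 1)
  expect_equal(
    fractional_incorporation(rate_constants(k0a = 0.01))[["acetate"]], 0)
  expect_true(is.na(
    fractional_incorporation(rate_constants())[["acetate"]]))
})
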