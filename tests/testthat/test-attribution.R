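test_that("expected-labelling designs encode the scrambling patterns", {
  g <- glucose_design()
  expect_equal(unname(g$matrix[, "acetate"]), c(0.5, 0.5, 0, 0, 0, 0, 0))
  expect_equal(unname(g$matrix[, "propionate"]), c(0, 0, 0.5, 0.5, 0, 0, 0))
  expect_equal(unname(g$matrix[, "butyrate"]), c(0, 0.5, 0.5, 0, 0, 0, 0))
  expect_equal(g$stoichiometry[["butyrate"]], 2)
  c6 <- citrate_design()
  expect_equal(unname(c6$matrix[, "acetate"]), c(0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(c6$matrix[, "butyrate"]), c(0, 0, 1, 0, 0, 0, 0))
  expect_equal(ncol(c6$matrix), 2)  # no propionate route to citrate
  expect_equal(c6$stoichiometry[["butyrate"]], 2)
})

compose <- function(design, coef) {
  x <- as.vector(design$matrix[, names(coef)] %*% coef)
  x[1] <- x[1] + (1 - sum(coef))
  mid(design$metabolite, x, is_excess = TRUE)
}

test_that("attribution recovers known coefficients from noiseless MIDs", {
  g <- glucose_design()
  truth <- c(acetate = 0.05, propionate = 0.3, butyrate = 0.1)
  at <- attribute_sources(compose(g, truth), g)
  expect_equal(at$coefficients, truth, tolerance = 1e-8)
  expect_lt(at$residual_norm, 1e-10)
  expect_gt(at$condition_number, 1)  # overlapping columns at M+1/M+2

  cd <- citrate_design()
  truth_c <- c(acetate = 0.02, butyrate = 0.08)
  expect_equal(attribute_sources(compose(cd, truth_c), cd)$coefficients,
               truth_c, tolerance = 1e-8)

  # all-zero excess gives zero coefficients
  zero <- mid("glucose", c(1, rep(0, 6)), is_excess = TRUE)
  expect_equal(unname(attribute_sources(zero, g)$coefficients), rep(0, 3))
})

test_that("noiseless recovery holds across random coefficient vectors", {
  set.seed(7)
  g <- glucose_design()
  for (i in 1:25) {
    truth <- setNames(stats::runif(3, 0, 0.2),
                      c("acetate", "propionate", "butyrate"))
    at <- attribute_sources(compose(g, truth), g)
    expect_equal(at$coefficients, truth, tolerance = 1e-8)
  }
})

test_that("coefficients are invariant to positive rescaling of the system", {
  g <- glucose_design()
  truth <- c(acetate = 0.04, propionate = 0.12, butyrate = 0.06)
  m <- compose(g, truth)
  scaled <- mid("glucose", m$values * 3, is_excess = TRUE)
  # both sides scale: regressing the scaled excess on the scaled design
  g3 <- g; g3$matrix <- g$matrix  # design unchanged; coefficients absorb scale
  at <- attribute_sources(scaled, g3)
  expect_equal(at$coefficients, 3 * truth, tolerance = 1e-8)
})

test_that("dose normalisation follows stoichiometry and delivered amounts", {
  g <- glucose_design()
  x <- 0.05
  truth <- c(acetate = x, propionate = x, butyrate = x)
  at <- attribute_sources(compose(g, truth), g, dose = tracer_dose())
  # equal raw coefficients -> contributions proportional to
  # 1/(stoich * dose), rescaled by the acetate dose
  expected <- x / (c(1, 1, 2) * c(9.6, 4, 0.9)) * 9.6
  expect_equal(unname(at$normalized_contribution), expected, tolerance = 1e-12)
  expect_equal(at$normalized_contribution[["acetate"]], x)
  expect_error(attribute_sources(compose(g, truth), g,
                                 dose = tracer_dose(acetate = 0)),
               "positive")
})

test_that("attribution rejects mismatched inputs", {
  g <- glucose_design()
  expect_error(attribute_sources(mid("citrate", c(1, rep(0, 6)),
                                     is_excess = TRUE), g), "metabolite")
  expect_error(attribute_sources(mid("glucose", c(1, 0, 0), is_excess = TRUE),
                                 g), "length")
  expect_error(attribute_sources(mid("glucose", c(0.5, 0.5, rep(0, 5))), g),
               "excess")
})

test_that("the enrichment screen flags only isotopologues above threshold", {
  m <- mid("propionyl-carnitine",
           c(0.98, 0.001, 0.002, 0.017, rep(0, 7)), n_carbons = 10,
           is_excess = TRUE)
  hit <- screen_enrichment(m, threshold = 0.005)
  expect_equal(hit$iso_index, 3L)       # M+3 only
  expect_equal(nrow(screen_enrichment(m, threshold = 0.05)), 0)
})
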