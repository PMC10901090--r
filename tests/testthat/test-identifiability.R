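test_that("collinearity index handles canonical column geometries", {
  # two orthogonal columns
  S <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_equal(collinearity_index(S, c("a", "b")), 1)
  # two identical columns: rank deficiency, infinite index
  S2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_equal(collinearity_index(S2, c("a", "b")), Inf)
  # two unit columns at 60 degrees: Gram eigenvalues 3/2 and 1/2
  S3 <- cbind(a = c(1, 0), b = c(cos(pi / 3), sin(pi / 3)))
  expect_equal(collinearity_index(S3, c("a", "b")), sqrt(2), tolerance = 1e-12)
  expect_error(collinearity_index(S, "a"), "at least 2")
})

test_that("index is invariant to positive column rescaling and monotone in subset size", {
  set.seed(5)
  S <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(collinearity_index(S, c("a", "b", "c")),
               collinearity_index(sweep(S, 2, c(10, 0.1, 3, 1, 1), "*"),
                                  c("a", "b", "c")),
               tolerance = 1e-10)
  # superset index >= subset index, across random cases
  for (i in 1:20) {
    Si <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, letters[1:4]))
    expect_gte(collinearity_index(Si, letters[1:4]) + 1e-12,
               collinearity_index(Si, letters[1:3]))
  }
})

test_that("index agrees with a brute-force smallest-singular-value oracle", {
  set.seed(9)
  for (i in 1:10) {
    S <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, letters[1:5]))
    sub <- sample(letters[1:5], 3)
    Sn <- apply(S[, sub], 2, function(x) x / sqrt(sum(x^2)))
    expect_equal(collinearity_index(S, sub), 1 / min(svd(Sn)$d),
                 tolerance = 1e-10)
  }
})

test_that("sensitivity scaling and zero-column flagging behave as defined", {
  setup <- ref_setup()
  times <- seq(15, 210, 30)
  # parameter with no influence: k0a when no acetate is delivered
  no_ac <- tracer_dose(acetate = 0)
  S <- sensitivity_matrix(setup$k, no_ac, setup$subject, times = times)
  expect_true(all(S[, "k0a"] == 0))
  expect_true(all(c("k1a", "kLa", "k0a") %in% attr(S, "zero_columns")))
  # a zero-valued parameter yields a zero scaled column
  k0 <- setup$k; k0["k1b"] <- 0
  S0 <- sensitivity_matrix(k0, setup$dose, setup$subject, times = times)
  expect_true("k1b" %in% attr(S0, "zero_columns"))
})

test_that("finite-difference sensitivity matches the analytic k2 derivative", {
  k <- rate_constants(k1p = 0.004, k0p = 0.009, k2 = 0.015)
  dose <- tracer_dose(); sub <- subject_profile()
  times <- seq(15, 210, 15)
  S <- sensitivity_matrix(k, dose, sub, times = times)
  i_p <- attr(S, "sources") == "propionate"
  w <- attr(S, "weights")[i_p]
  analytic <- bateman_gp_dk2(times, 0.004, 0.009, 0.015, 4, sub$v_plasma_l) *
    0.015 / w
  expect_equal(unname(S[i_p, "k2"]), analytic, tolerance = 1e-5)
})

test_that("subset enumeration is exhaustive and respects duplicates", {
  # all-orthogonal 8-column matrix: everything identifiable up to size 8
  S <- diag(8); colnames(S) <- paste0("p", 1:8)
  rep <- identifiable_subsets(S)
  expect_equal(nrow(rep), 247)  # sum_{k=2..8} choose(8, k)
  expect_equal(attr(rep, "max_identifiable_size"), 8L)
  expect_true(all(rep$identifiable))
  # duplicate a column: no identifiable subset may contain the pair
  S2 <- S; S2[, "p2"] <- S2[, "p1"]
  rep2 <- identifiable_subsets(S2)
  both <- grepl("p1", rep2$subset) & grepl("p2\\b", rep2$subset)
  expect_true(all(!rep2$identifiable[both]))
  expect_true(all(rep2$identifiable[!both]))
})

test_that("the reference regime identifies six of the eight constants", {
  setup <- ref_setup()
  S <- sensitivity_matrix(setup$k, setup$dose, setup$subject,
                          times = seq(-15, 210, 15))
  rep <- identifiable_subsets(S, threshold = 20)
  expect_equal(attr(rep, "max_identifiable_size"), 6L)
  # kLa is part of the data-poor pair; fixing it plus the selected second
  # parameter leaves an identifiable six-parameter set
  sel <- select_second_fixed(S, first = "kLa")
  remaining <- setdiff(colnames(S), c("kLa", sel$second))
  expect_lt(collinearity_index(S, remaining), 20)
})
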