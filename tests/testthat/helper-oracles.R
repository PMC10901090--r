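# Independent oracles used across the test files. None of these call the
# package's own simulation or correction code paths.

# Brute-force natural-abundance pattern: enumerate all 2^n labelling states
# of the n - j non-tracer carbons of a fragment with j tracer carbons and
# accumulate the probability of each observed mass shift.
enumerate_na_column <- function(n, j, p) {
  free <- n - j
  shifts <- numeric(n + 1)
  if (free == 0) {
    shifts[j + 1] <- 1
  } else {
    for (state in 0:(2^free - 1)) {
      bits <- as.integer(intToBits(state))[seq_len(free)]
      prob <- prod(ifelse(bits == 1, p, 1 - p))
      shifts[j + sum(bits) + 1] <- shifts[j + sum(bits) + 1] + prob
    }
  }
  shifts
}

# Two-exponential (Bateman) closed form for the propionate branch:
# G_p(t) = k1p P0 / (V (k2 - a)) (e^{-a t} - e^{-k2 t}), a = k1p + k0p.
bateman_gp <- function(t, k1p, k0p, k2, P0, V) {
  a <- k1p + k0p
  k1p * P0 / (V * (k2 - a)) * (exp(-a * t) - exp(-k2 * t))
}

# Analytic derivative of the closed form with respect to k2.
bateman_gp_dk2 <- function(t, k1p, k0p, k2, P0, V) {
  a <- k1p + k0p
  -k1p * P0 / (V * (k2 - a)^2) * (exp(-a * t) - exp(-k2 * t)) +
    k1p * P0 / (V * (k2 - a)) * t * exp(-k2 * t)
}

# Matrix-exponential solution of the full 7-state linear system.
expm_states <- function(t, k, dose, V) {
  A <- matrix(0, 7, 7,
              dimnames = list(NULL, c("A_gut", "A_liver", "G_a",
                                      "P_gut", "G_p", "B_gut", "G_b")))
  A[1, 1] <- -(k[["k1a"]] + k[["k0a"]])
  A[2, 1] <- k[["k1a"]];  A[2, 2] <- -k[["kLa"]]
  A[3, 2] <- k[["kLa"]] / V; A[3, 3] <- -k[["k2"]]
  A[4, 4] <- -(k[["k1p"]] + k[["k0p"]])
  A[5, 4] <- k[["k1p"]] / V; A[5, 5] <- -k[["k2"]]
  A[6, 6] <- -(k[["k1b"]] + k[["k0b"]])
  A[7, 6] <- k[["k1b"]] / V; A[7, 7] <- -k[["k2"]]
  y0 <- c(dose$mmol[["acetate"]], 0, 0, dose$mmol[["propionate"]], 0,
          dose$mmol[["butyrate"]], 0)
  out <- t(vapply(t, function(tt)
    as.vector(Matrix::expm(A * tt) %*% y0), numeric(7)))
  colnames(out) <- colnames(A)
  out
}

# Random non-degenerate rate constants on the scales of this problem.
random_rate_constants <- function() {
  v <- 10^stats::runif(8, -3.3, -1.3)
  rate_constants(k1a = v[1], k1p = v[2], k1b = v[3], kLa = v[4], k2 = v[5],
                 k0a = v[6], k0p = v[7], k0b = v[8])
}

ref_setup <- function() {
  list(k = reference_rate_constants(), dose = tracer_dose(),
       subject = subject_profile())
}
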