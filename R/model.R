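#' Apparent first-order rate constants of the compartment model
#'
#' The eight rate constants (min^-1) of the gut-liver-plasma model:
#'
#' * `k1a` — uptake of acetate from gut to liver;
#' * `k1p`, `k1b` — lumped uptake + conversion to plasma glucose for
#'   propionate and butyrate;
#' * `kLa` — conversion of liver acetate to glucose delivered to plasma;
#' * `k2` — clearance of labelled glucose from plasma (source-independent);
#' * `k0a`, `k0p`, `k0b` — loss of each SCFA to fates other than glucose.
#'
#' @param k1a,k1p,k1b,kLa,k2,k0a,k0p,k0b Non-negative rates in min^-1.
#' @return A named numeric vector of class `"rate_constants"`.
#' @export
rate_constants <- function(k1a = 0, k1p = 0, k1b = 0, kLa = 0, k2 = 0,
                           k0a = 0, k0p = 0, k0b = 0) {
  k <- c(k1a = k1a, k1p = k1p, k1b = k1b, kLa = kLa, k2 = k2,
         k0a = k0a, k0p = k0p, k0b = k0b)
  if (any(!is.finite(k)) || any(k < 0))
    stop("all rate constants must be finite and >= 0")
  structure(k, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> (min^-1)\n")
  print(setNames(round(unclass(x), 6), names(x)))
  invisible(x)
}

.K_NAMES <- c("k1a", "k1p", "k1b", "kLa", "k2", "k0a", "k0p", "k0b")

#' Reference rate constants of the synthetic-data generator
#'
#' The generator-truth kinetic regime for an adult-human intraintestinal
#' 13C-SCFA bolus: `kLa = 0.0071` and `k0p = 0.0109` min^-1 (the two
#' constants that must be fixed by grid search in this regime), and the
#' remaining six set so that the fractional incorporations
#' `k1x / (k1x + k0x)` are exactly 0.12 (acetate), 0.23 (propionate) and
#' 0.79 (butyrate), with `k2 = 0.015` min^-1 (fractional plasma glucose
#' turnover of roughly 2 mg/kg/min at 5 mM and 0.15 L/kg), `k0a = 0.04`
#' (most delivered acetate is oxidised or exchanged) and `k0b = 0.002`
#' (butyrate loss smallest). These are generator conventions for producing
#' realistic curves, not estimates for any cohort.
#'
#' @return A [rate_constants()] vector.
#' @export
reference_rate_constants <- function() {
  k0a <- 0.04; k0p <- 0.0109; k0b <- 0.002
  rate_constants(
    k1a = 0.12 / 0.88 * k0a,
    k1p = 0.23 / 0.77 * k0p,
    k1b = 0.79 / 0.21 * k0b,
    kLa = 0.0071, k2 = 0.015, k0a = k0a, k0p = k0p, k0b = k0b)
}

#' Delivered tracer dose
#'
#' Amounts of 13C-SCFA delivered into the gut lumen, in mmol, defining the
#' initial gut pool sizes of the model. Defaults are 9.6 mmol acetate,
#' 4 mmol propionate and 0.9 mmol butyrate.
#'
#' @param acetate,propionate,butyrate Delivered amounts, mmol, >= 0.
#' @param delivery_time_min Time of delivery; the model's time origin.
#' @return An object of class `"tracer_dose"` with fields `mmol` (named
#'   vector) and `delivery_time_min`.
#' @export
tracer_dose <- function(acetate = 9.6, propionate = 4, butyrate = 0.9,
                        delivery_time_min = 0) {
  mmol <- c(acetate = acetate, propionate = propionate, butyrate = butyrate)
  if (any(!is.finite(mmol)) || any(mmol < 0))
    stop("delivered amounts must be finite and >= 0")
  structure(list(mmol = mmol, delivery_time_min = delivery_time_min),
            class = "tracer_dose")
}

#' Tracer dose from infusate composition
#'
#' Converts an infusate composition (molar concentration of each Na-13C-SCFA
#' salt and infused volume) into delivered mmol. The default composition,
#' 0.96 M acetate / 0.40 M propionate / 0.09 M butyrate in 10 mL, delivers
#' 9.6 / 4 / 0.9 mmol.
#'
#' @param molarity Named vector of SCFA concentrations in mol/L.
#' @param volume_ml Infused volume in mL.
#' @param delivery_time_min Time of delivery (minutes).
#' @return A [tracer_dose()].
#' @export
dose_from_infusion <- function(molarity = c(acetate = 0.96, propionate = 0.40,
                                            butyrate = 0.09),
                               volume_ml = 10, delivery_time_min = 0) {
  stopifnot(all(c("acetate", "propionate", "butyrate") %in% names(molarity)),
            volume_ml > 0)
  mmol <- molarity * volume_ml   # mol/L * mL == mmol
  tracer_dose(mmol[["acetate"]], mmol[["propionate"]], mmol[["butyrate"]],
              delivery_time_min)
}

#' Subject plasma-volume profile
#'
#' Plasma volume is assumed constant at 0.15 L per kg body weight; it
#' converts the mmol gut/liver pools to the mM plasma glucose pools.
#'
#' @param subject Subject identifier.
#' @param body_weight_kg Body weight, kg, > 0.
#' @param v_plasma_l Plasma volume in L; default `0.15 * body_weight_kg`.
#' @return An object of class `"subject_profile"`.
#' @export
subject_profile <- function(subject = "average", body_weight_kg = 75,
                            v_plasma_l = 0.15 * body_weight_kg) {
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("`body_weight_kg` must be > 0")
  if (!is.finite(v_plasma_l) || v_plasma_l <= 0)
    stop("`v_plasma_l` must be > 0")
  structure(list(subject = as.character(subject),
                 body_weight_kg = body_weight_kg, v_plasma_l = v_plasma_l),
            class = "subject_profile")
}

.STATE_NAMES <- c("A_gut", "A_liver", "G_a", "P_gut", "G_p", "B_gut", "G_b")

#' Right-hand side of the three-compartment tracer ODE system
#'
#' State (units): gut pools `A_gut`, `P_gut`, `B_gut` and liver pool
#' `A_liver` in mmol; plasma 13C-glucose pools `G_a`, `G_p`, `G_b` in mM
#' (labelled-glucose equivalents per source SCFA). The system is
#'
#' \deqn{dA_{gut}/dt = -(k_{1a}+k_{0a}) A_{gut}}
#' \deqn{dA_{liver}/dt = k_{1a} A_{gut} - k_{La} A_{liver}}
#' \deqn{dG_a/dt = (k_{La} A_{liver} - k_2 V G_a)/V}
#' \deqn{dP_{gut}/dt = -(k_{1p}+k_{0p}) P_{gut}, \quad
#'       dG_p/dt = (k_{1p} P_{gut} - k_2 V G_p)/V}
#' \deqn{dB_{gut}/dt = -(k_{1b}+k_{0b}) B_{gut}, \quad
#'       dG_b/dt = (k_{1b} B_{gut} - k_2 V G_b)/V}
#'
#' where `V` is the plasma volume in L; the 1/V factor converts mmol fluxes
#' into mM concentration changes. The signature follows [deSolve::ode()].
#'
#' @param t Time (min); unused (the system is autonomous).
#' @param state Named state vector (`A_gut`, `A_liver`, `G_a`, `P_gut`,
#'   `G_p`, `B_gut`, `G_b`).
#' @param parms Named parameter vector: the eight rate constants plus `V`
#'   (plasma volume, L).
#' @return A list whose first element is the derivative vector.
#' @export
scfa_ode <- function(t, state, parms) {
  p <- as.list(parms)
  if (p$V <= 0) stop("plasma volume must be > 0")
  s <- as.list(state)
  d <- c(
    A_gut   = -(p$k1a + p$k0a) * s$A_gut,
    A_liver = p$k1a * s$A_gut - p$kLa * s$A_liver,
    G_a     = (p$kLa * s$A_liver - p$k2 * p$V * s$G_a) / p$V,
    P_gut   = -(p$k1p + p$k0p) * s$P_gut,
    G_p     = (p$k1p * s$P_gut - p$k2 * p$V * s$G_p) / p$V,
    B_gut   = -(p$k1b + p$k0b) * s$B_gut,
    G_b     = (p$k1b * s$B_gut - p$k2 * p$V * s$G_b) / p$V)
  list(d)
}

# integrate the system; optionally with cumulative integrals of the gut and
# plasma pools appended (for conservation checks and AUC computation).
.simulate_states <- function(k, dose, subject, times, cumulative = FALSE,
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(k, "rate_constants"), inherits(dose, "tracer_dose"),
            inherits(subject, "subject_profile"))
  if (any(times < 0)) stop("simulation times must be >= 0 (post-delivery)")
  if (is.unsorted(times, strictly = TRUE))
    stop("simulation times must be strictly increasing")
  y0 <- c(A_gut = dose$mmol[["acetate"]], A_liver = 0, G_a = 0,
          P_gut = dose$mmol[["propionate"]], G_p = 0,
          B_gut = dose$mmol[["butyrate"]], G_b = 0)
  parms <- c(unclass(k), V = subject$v_plasma_l)
  rhs <- scfa_ode
  if (cumulative) {
    y0 <- c(y0, int_A = 0, int_P = 0, int_B = 0,
            int_Ga = 0, int_Gp = 0, int_Gb = 0)
    rhs <- function(t, state, parms) {
      d <- scfa_ode(t, state[.STATE_NAMES], parms)[[1L]]
      list(c(d, int_A = state[["A_gut"]], int_P = state[["P_gut"]],
             int_B = state[["B_gut"]], int_Ga = state[["G_a"]],
             int_Gp = state[["G_p"]], int_Gb = state[["G_b"]]))
    }
  }
  tt <- times
  prepend <- tt[1L] > 0
  if (prepend) tt <- c(0, tt)
  out <- deSolve::ode(y0, tt, rhs, parms, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE integration failed: ", paste(attr(out, "istate"), collapse = " "))
  out <- as.data.frame(out)
  if (prepend) out <- out[-1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate plasma 13C-glucose enrichment curves
#'
#' Integrates the compartment model from the delivered dose (initial state
#' `(A0, 0, 0, P0, 0, B0, 0)`) with a stiff-capable solver (`lsoda`,
#' relative tolerance 1e-8, absolute 1e-12 by default) and returns the three
#' plasma 13C-glucose pools at the requested times.
#'
#' @param k [rate_constants()].
#' @param dose [tracer_dose()].
#' @param subject [subject_profile()].
#' @param times Strictly increasing times (min) >= 0.
#' @param rtol,atol Solver tolerances.
#' @return A long data frame of class `"enrichment_curves"` with columns
#'   `subject`, `time_min`, `source` (acetate/propionate/butyrate), `value`
#'   (mM labelled-glucose equivalents) and `sd` (NA for simulations).
#' @examples
#' sim <- simulate_curves(reference_rate_constants(), tracer_dose(),
#'                        subject_profile(), times = seq(0, 210, 15))
#' head(sim)
#' @export
simulate_curves <- function(k, dose, subject, times, rtol = 1e-8,
                            atol = 1e-12) {
  st <- .simulate_states(k, dose, subject, times, rtol = rtol, atol = atol)
  out <- data.frame(
    subject = subject$subject,
    time_min = rep(st$time, 3L),
    source = rep(c("acetate", "propionate", "butyrate"), each = nrow(st)),
    value = c(st$G_a, st$G_p, st$G_b),
    sd = NA_real_)
  class(out) <- c("enrichment_curves", "data.frame")
  out
}

# model predictions at arbitrary (possibly pre-delivery) times; the tracer
# signal is identically zero before delivery.
.predict_values <- function(k, dose, subject, times, sources) {
  pos <- sort(unique(times[times > 0]))
  G <- matrix(0, length(pos), 3L,
              dimnames = list(NULL, c("acetate", "propionate", "butyrate")))
  if (length(pos)) {
    st <- .simulate_states(k, dose, subject, pos)
    G[, "acetate"] <- st$G_a; G[, "propionate"] <- st$G_p
    G[, "butyrate"] <- st$G_b
  }
  vapply(seq_along(times), function(i) {
    if (times[i] <= 0) 0 else G[match(times[i], pos), sources[i]]
  }, numeric(1))
}
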