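#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: an
#' intraintestinal bolus of 13C-SCFA (9.6 / 4 / 0.9 mmol acetate /
#' propionate / butyrate) in a small cohort of adult subjects, plasma
#' sampled every 15 min from 15 min before delivery to 210 min after, with
#' additive measurement noise on the 13C-glucose enrichment curves and
#' multiplicative noise on the raw MIDs.
#'
#' Subject-level rate constants are log-normal around the reference truth
#' (median = truth) with coefficient of variation `cv_k`; body weights are
#' normal, truncated below at `body_weight_min_kg`.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_subjects Cohort size (default 8).
#' @param body_weight_mean_kg,body_weight_sd_kg,body_weight_min_kg Body
#'   weight distribution (default 75 +- 10 kg, truncated at 50).
#' @param true_k Generator-truth [rate_constants()]
#'   (default [reference_rate_constants()]).
#' @param cv_k Inter-subject log-normal CV on every rate constant
#'   (default 0.2).
#' @param dose [tracer_dose()] (default 9.6/4/0.9 mmol at t = 0).
#' @param schedule_min Sampling schedule in minutes relative to delivery
#'   (default `seq(-15, 210, by = 15)`).
#' @param noise_frac Enrichment-curve noise sd as a fraction of each curve's
#'   maximum (default 0.05).
#' @param glucose_contrib,citrate_contrib Per-SCFA labelling coefficients
#'   composing the excess glucose / citrate MIDs (plateau labelling).
#' @param pcarn_excess_m3 Excess M+3 fraction of propionyl-carnitine.
#' @param p13C Natural 13C abundance used to convolve raw MIDs.
#' @param mid_noise_cv Multiplicative noise CV on raw MID entries
#'   (default 0.01).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_subjects = 8L,
                             body_weight_mean_kg = 75, body_weight_sd_kg = 10,
                             body_weight_min_kg = 50,
                             true_k = reference_rate_constants(), cv_k = 0.2,
                             dose = tracer_dose(),
                             schedule_min = seq(-15, 210, by = 15),
                             noise_frac = 0.05,
                             glucose_contrib = c(acetate = 0.004,
                                                 propionate = 0.010,
                                                 butyrate = 0.012),
                             citrate_contrib = c(acetate = 0.008,
                                                 butyrate = 0.015),
                             pcarn_excess_m3 = 0.02,
                             p13C = 0.0107, mid_noise_cv = 0.01) {
  stopifnot(inherits(true_k, "rate_constants"), inherits(dose, "tracer_dose"),
            n_subjects >= 1, body_weight_mean_kg > 0, cv_k >= 0,
            noise_frac >= 0, !is.unsorted(schedule_min, strictly = TRUE))
  if (!any(schedule_min > 0))
    stop("the sampling schedule has no post-delivery points")
  if (sum(glucose_contrib) > 1 || sum(citrate_contrib) > 1)
    stop("labelling contributions must sum to at most 1")
  structure(as.list(environment()), class = "generator_config")
}

.subject_draws <- function(cfg) {
  bw <- rnorm(cfg$n_subjects, cfg$body_weight_mean_kg, cfg$body_weight_sd_kg)
  while (any(bw < cfg$body_weight_min_kg)) {
    i <- bw < cfg$body_weight_min_kg
    bw[i] <- rnorm(sum(i), cfg$body_weight_mean_kg, cfg$body_weight_sd_kg)
  }
  sdlog <- sqrt(log(1 + cfg$cv_k^2))
  lapply(seq_len(cfg$n_subjects), function(i) {
    kk <- unclass(cfg$true_k)
    ks <- kk * exp(rnorm(length(kk), 0, sdlog))
    list(profile = subject_profile(sprintf("S%02d", i), body_weight_kg = bw[i]),
         k = structure(setNames(ks, names(kk)), class = "rate_constants"))
  })
}

#' Generate synthetic plasma 13C-glucose enrichment curves
#'
#' Simulates the compartment model per subject with subject-level constants,
#' samples on the configured schedule (pre-delivery points carry zero
#' signal), adds i.i.d. Gaussian noise with sd equal to `noise_frac` of
#' each curve's maximum, and clips at zero. Fully reproducible from the
#' seed.
#'
#' @param cfg A [generator_config()].
#' @return A list: `curves` (long data frame `subject`, `time_min`,
#'   `source`, `value`, `sd` = the known noise sd) and `truth` (per-subject
#'   constants, profiles, the truth [rate_constants()] and fractional
#'   incorporations).
#' @export
generate_enrichment_curves <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  subs <- .subject_draws(cfg)
  out <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    src <- rep(c("acetate", "propionate", "butyrate"),
               each = length(cfg$schedule_min))
    tt <- rep(cfg$schedule_min, 3L)
    val <- .predict_values(s$k, cfg$dose, s$profile, tt, src)
    df <- data.frame(subject = s$profile$subject, time_min = tt, source = src,
                     value = val, sd = NA_real_)
    for (sc in unique(src)) {
      j <- df$source == sc
      nsd <- cfg$noise_frac * max(df$value[j])
      df$sd[j] <- if (nsd > 0) nsd else NA_real_  # NA: noiseless curve
      if (nsd > 0) df$value[j] <- pmax(0, df$value[j] + rnorm(sum(j), 0, nsd))
    }
    out[[i]] <- df
  }
  curves <- do.call(rbind, out)
  class(curves) <- c("enrichment_curves", "data.frame")
  list(curves = curves,
       truth = list(k = cfg$true_k,
                    fractions = fractional_incorporation(cfg$true_k),
                    subject_k = lapply(subs, `[[`, "k"),
                    profiles = lapply(subs, `[[`, "profile"),
                    seed = cfg$seed))
}

#' Average enrichment curves across subjects
#'
#' Collapses per-subject curves to the across-subject mean at each
#' (time, source), with the across-subject standard deviation as `sd` —
#' the weighting used for averaged-data fits. Zero sds (e.g. pre-delivery
#' points where every subject reads exactly 0) are floored at the smallest
#' positive sd of the same curve so weighted objectives stay finite.
#'
#' @param curves Long curves data frame with multiple subjects.
#' @return An `"enrichment_curves"` data frame with `subject = "average"`.
#' @export
average_curves <- function(curves) {
  curves <- .check_curves(curves)
  ag <- stats::aggregate(value ~ time_min + source, curves, mean)
  sds <- stats::aggregate(value ~ time_min + source, curves, stats::sd)
  ag$sd <- sds$value
  for (sc in unique(ag$source)) {
    i <- ag$source == sc
    pos <- ag$sd[i][ag$sd[i] > 0 & !is.na(ag$sd[i])]
    floor_sd <- if (length(pos)) min(pos) else 1
    ag$sd[i][is.na(ag$sd[i]) | ag$sd[i] <= 0] <- floor_sd
  }
  out <- data.frame(subject = "average", time_min = ag$time_min,
                    source = ag$source, value = ag$value, sd = ag$sd)
  out <- out[order(match(out$source, c("acetate", "propionate", "butyrate")),
                   out$time_min), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_curves", "data.frame")
  out
}

# compose a full excess MID from labelling-design columns and coefficients:
# labelled mass from the design, M0 as the complement so the vector sums to 1.
.compose_excess <- function(design, coef) {
  x <- as.vector(design$matrix[, names(coef), drop = FALSE] %*% coef)
  x[1L] <- x[1L] + (1 - sum(coef))
  x
}

#' Generate synthetic raw mass-isotopologue distributions
#'
#' Composes excess MIDs for plasma glucose and citrate from the configured
#' per-SCFA contributions via the expected-labelling designs, plus a
#' propionyl-carnitine MID whose only excess is at M+3 (direct conjugation
#' of delivered `[1,2,3-13C3]`-propionate to carnitine). Each excess MID is
#' convolved with natural 13C abundance, perturbed with multiplicative
#' noise, clipped and renormalised — yielding valid raw distributions as a
#' GC-MS pipeline would report them.
#'
#' @param cfg A [generator_config()].
#' @return A list: `mids` (long data frame `subject`, `time_min`,
#'   `metabolite`, `n_carbons`, `iso_index`, `value`, `is_excess` = 0) and
#'   `truth` (contribution coefficients per metabolite).
#' @export
generate_raw_mids <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  times <- cfg$schedule_min[cfg$schedule_min > 0]
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  specs <- list(
    glucose = list(n = 6L, excess = .compose_excess(glucose_design(),
                                                    cfg$glucose_contrib)),
    citrate = list(n = 6L, excess = .compose_excess(citrate_design(),
                                                    cfg$citrate_contrib)),
    `propionyl-carnitine` = list(
      n = 10L,
      excess = c(1 - cfg$pcarn_excess_m3, 0, 0, cfg$pcarn_excess_m3,
                 rep(0, 7L))))
  rows <- list()
  for (sub in subjects) for (tm in times) for (met in names(specs)) {
    sp <- specs[[met]]
    C <- correction_matrix(sp$n, natural_abundance_model(cfg$p13C))
    raw <- as.vector(C %*% sp$excess)
    if (cfg$mid_noise_cv > 0)
      raw <- pmax(0, raw * (1 + rnorm(length(raw), 0, cfg$mid_noise_cv)))
    raw <- raw / sum(raw)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sub, time_min = tm, metabolite = met, n_carbons = sp$n,
      iso_index = 0:sp$n, value = raw, is_excess = 0L)
  }
  list(mids = do.call(rbind, rows),
       truth = list(glucose_contrib = cfg$glucose_contrib,
                    citrate_contrib = cfg$citrate_contrib,
                    pcarn_excess_m3 = cfg$pcarn_excess_m3,
                    excess = lapply(specs, `[[`, "excess"),
                    seed = cfg$seed))
}
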