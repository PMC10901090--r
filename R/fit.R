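# --- observed-curve helpers -------------------------------------------------

.check_curves <- function(observed) {
  need <- c("time_min", "source", "value")
  if (!all(need %in% names(observed)))
    stop("curves need columns ", paste(need, collapse = ", "))
  if (nrow(observed) == 0L) stop("empty curve set")
  if (!all(observed$source %in% c("acetate", "propionate", "butyrate")))
    stop("unknown source in curves")
  observed
}

# per-point weights: the reported sd where available, otherwise the
# curve-wise maximum absolute value (one pooled scale per source curve).
.curve_weights <- function(observed) {
  w <- if ("sd" %in% names(observed)) observed$sd else rep(NA_real_, nrow(observed))
  if (any(!is.na(w) & w <= 0)) stop("per-point sd must be > 0 where given")
  for (src in unique(observed$source)) {
    i <- observed$source == src
    if (anyNA(w[i])) {
      fallback <- max(abs(observed$value[i]))
      if (fallback <= 0) fallback <- 1
      w[i][is.na(w[i])] <- fallback
    }
  }
  w
}

# --- objectives -------------------------------------------------------------

#' Weighted sum-of-squares objective
#'
#' \deqn{SSE = \sum_i \left(\frac{\hat Y_i - Y_i}{s_i}\right)^2}
#' over every point of the three observed enrichment curves, where the
#' simulation is evaluated at the observed times and `s_i` is the per-point
#' standard deviation (across subjects for an averaged fit). When a curve
#' carries no sd, a single pooled scale — the curve maximum — is used.
#'
#' @param observed Curves data frame (`time_min`, `source`, `value`,
#'   optional `sd`).
#' @param k,dose,subject Model inputs as in [simulate_curves()].
#' @return The scalar weighted SSE.
#' @export
weighted_sse <- function(observed, k, dose, subject) {
  sum(.weighted_residuals(observed, k, dose, subject)^2)
}

.weighted_residuals <- function(observed, k, dose, subject) {
  observed <- .check_curves(observed)
  w <- .curve_weights(observed)
  pred <- .predict_values(k, dose, subject, observed$time_min, observed$source)
  (pred - observed$value) / w
}

#' Unweighted residual objective for grid ranking
#'
#' The grid-search ranking objective: in its `"literal"` form the plain sum
#' of squared residuals \eqn{\sum_i (\hat Y_i - Y_i)^2}; in its
#' `"conventional"` form \eqn{\sqrt{SSR / n}}. The two are related by a
#' strictly increasing transform, so grid rankings are identical under
#' either.
#'
#' @inheritParams weighted_sse
#' @param form `"literal"` (default, used for grid ranking) or
#'   `"conventional"`.
#' @return A scalar objective value.
#' @export
rmse <- function(observed, k, dose, subject,
                 form = c("literal", "conventional")) {
  form <- match.arg(form)
  observed <- .check_curves(observed)
  pred <- .predict_values(k, dose, subject, observed$time_min, observed$source)
  ssr <- sum((pred - observed$value)^2)
  if (form == "literal") ssr else sqrt(ssr / nrow(observed))
}

# --- fitting ----------------------------------------------------------------

#' Fit the identifiable rate constants
#'
#' Bound-constrained nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) on the weighted residuals of the three glucose
#' enrichment curves. By default `kLa` and `k0p` are held fixed at the values
#' selected by [grid_fix()] for this regime (0.0071 and 0.0109 min^-1) and
#' the six remaining constants are estimated. Works on averaged curves (with
#' across-subject sd as weights) or on a single subject's curves.
#'
#' Standard errors are asymptotic, from the Jacobian of the weighted
#' residuals at the optimum; p-values are two-sided t-tests of each constant
#' against zero.
#'
#' @inheritParams weighted_sse
#' @param fixed Named vector of constants to hold fixed.
#' @param start Named vector of starting values for the free constants
#'   (default 0.01 min^-1 each).
#' @param lower,upper Box bounds for the free constants (defaults 0 and 1).
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return A `"fit_result"` list: `estimated` ([rate_constants()] of all
#'   eight), `free`, `fixed`, `se`, `p_value`, `sse` (weighted), `rmse`
#'   (unweighted SSR), `fractions` (fractional incorporations at the
#'   optimum), `converged`, `n_obs`, `df`.
#' @export
fit_rate_constants <- function(observed, dose, subject,
                               fixed = c(kLa = 0.0071, k0p = 0.0109),
                               start = NULL, lower = 0, upper = 1,
                               control = minpack.lm::nls.lm.control(maxiter = 200)) {
  observed <- .check_curves(observed)
  if (!all(names(fixed) %in% .K_NAMES))
    stop("unknown fixed parameter name(s): ",
         paste(setdiff(names(fixed), .K_NAMES), collapse = ", "))
  free <- setdiff(.K_NAMES, names(fixed))
  if (is.null(start)) start <- setNames(rep(0.01, length(free)), free)
  if (!setequal(names(start), free))
    stop("`start` must name exactly the free parameters")
  start <- start[free]
  lower <- rep_len(lower, length(free)); upper <- rep_len(upper, length(free))

  make_k <- function(par) {
    k <- setNames(numeric(8L), .K_NAMES)
    k[names(fixed)] <- fixed
    k[free] <- pmax(par, 0)
    class(k) <- "rate_constants"
    k
  }
  resid_fun <- function(par)
    .weighted_residuals(observed, make_k(par), dose, subject)

  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun, control = control)
  k_hat <- make_k(fit$par)
  n <- nrow(observed); p <- length(free); dof <- n - p
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  se <- pval <- setNames(rep(NA_real_, p), free)
  if (!is.null(sm)) {
    cf <- sm$coefficients
    se[rownames(cf)] <- cf[, "Std. Error"]
    pval[rownames(cf)] <- cf[, "Pr(>|t|)"]
  }
  at_bound <- free[fit$par <= lower + 1e-12 & start > lower |
                   fit$par >= upper - 1e-12]
  # a free parameter resting on a bound is legitimate but its asymptotic
  # inference is not; warn so the caller can inspect
  if (length(at_bound) && any(fit$par[at_bound] >= upper - 1e-12))
    warning("free parameter(s) at the upper bound: ",
            paste(at_bound, collapse = ", "))
  structure(list(
    estimated = k_hat, free = free, fixed = fixed,
    se = se, p_value = pval,
    sse = sum(fit$fvec^2),
    rmse = rmse(observed, k_hat, dose, subject, form = "literal"),
    fractions = fractional_incorporation(k_hat),
    converged = fit$info %in% 1:3, info = fit$info,
    message = fit$message, n_obs = n, df = dof),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      sprintf("(weighted SSE %.4g, n = %d)\n", x$sse, x$n_obs))
  tab <- data.frame(estimate = unclass(x$estimated)[x$free],
                    std_error = x$se[x$free], p_value = x$p_value[x$free])
  print(signif(tab, 4))
  cat("fixed:", paste(names(x$fixed), signif(x$fixed, 4), sep = " = ",
                      collapse = ", "), "\n")
  cat("fractional incorporation:",
      paste(names(x$fractions), round(x$fractions, 3), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Default grid for fixing non-identifiable constants
#'
#' Fifty logarithmically spaced values on `[1e-4, 1]` plus 0: rate constants
#' are scale parameters, so a log grid covers the admissible range `[0, 1]`
#' evenly in order of magnitude.
#'
#' @param n Number of log-spaced points (default 50).
#' @return A sorted numeric vector of length `n + 1` starting at 0.
#' @export
default_grid <- function(n = 50) c(0, 10^seq(-4, 0, length.out = n))

#' Grid search for the two fixed rate constants
#'
#' For every pair on the `kLa` x `k0p` grid, holds the pair fixed, refits
#' the six free constants by [fit_rate_constants()], and records the
#' unweighted residual objective ([rmse()], literal form). Returns the pair
#' with the smallest objective; exact ties go to the smallest `kLa`, then
#' the smallest `k0p`. With the full [default_grid()] this is a long-running
#' batch computation (2601 refits); supply smaller grids for interactive
#' work.
#'
#' @inheritParams fit_rate_constants
#' @param params The two parameters to fix (default `c("kLa", "k0p")`).
#' @param grids List of two numeric grids in `[0, 1]`, named as `params`.
#' @param ... Passed to [fit_rate_constants()].
#' @return A list with `fixed` (named vector: the selected pair),
#'   `objective`, and `table` (one row per grid pair).
#' @export
grid_fix <- function(observed, dose, subject,
                     params = c("kLa", "k0p"),
                     grids = list(kLa = default_grid(), k0p = default_grid()),
                     ...) {
  stopifnot(length(params) == 2L, setequal(names(grids), params))
  g1 <- sort(unique(grids[[params[1L]]])); g2 <- sort(unique(grids[[params[2L]]]))
  if (!length(g1) || !length(g2) || any(c(g1, g2) < 0) || any(c(g1, g2) > 1))
    stop("grids must be non-empty with values in [0, 1]")
  tab <- expand.grid(v2 = g2, v1 = g1)[, c("v1", "v2")]  # v1-major order
  tab$objective <- NA_real_
  best <- NULL; best_obj <- Inf; n_fail <- 0L
  for (i in seq_len(nrow(tab))) {
    fixed <- setNames(c(tab$v1[i], tab$v2[i]), params)
    obj <- tryCatch({
      f <- fit_rate_constants(observed, dose, subject, fixed = fixed, ...)
      f$rmse
    }, error = function(e) NA_real_)
    tab$objective[i] <- obj
    if (is.na(obj)) { n_fail <- n_fail + 1L; next }
    if (obj < best_obj) { best_obj <- obj; best <- fixed }  # strict: first
  }                                                        # (smallest) wins ties
  if (is.null(best)) stop("all grid fits failed")
  names(tab)[1:2] <- params
  list(fixed = best, objective = best_obj, table = tab, n_failed = n_fail)
}

#' Fractional incorporation from rate constants
#'
#' Fraction of each delivered 13C-SCFA incorporated into plasma glucose, as
#' the ratio of the conversion rate to the total disappearance rate:
#' `k1a/(k1a+k0a)`, `k1p/(k1p+k0p)`, `k1b/(k1b+k0b)`. Equals the
#' AUC x clearance / dose fraction on the fully extrapolated model curve
#' (see [fraction_auc()]).
#'
#' @param k [rate_constants()].
#' @return Named vector `(acetate, propionate, butyrate)` in `[0, 1]`;
#'   `NA` where `k1x + k0x = 0`.
#' @export
fractional_incorporation <- function(k) {
  stopifnot(inherits(k, "rate_constants"))
  num <- unclass(k)[c("k1a", "k1p", "k1b")]
  den <- num + unclass(k)[c("k0a", "k0p", "k0b")]
  out <- ifelse(den > 0, num / den, NA_real_)
  setNames(out, c("acetate", "propionate", "butyrate"))
}
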