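#' Mass-isotopologue distribution (MID)
#'
#' Constructs a MID object: the fractional abundances of the isotopologues
#' M0..M+n of one metabolite fragment with `n_carbons` carbons, at one time
#' point. Raw (measured) MIDs are non-negative and are normalised to sum to 1;
#' excess (natural-abundance-corrected) MIDs may carry a negative M0 entry and
#' small negative noise on the labelled entries.
#'
#' @param metabolite Metabolite (fragment) identifier, e.g. `"glucose"`.
#' @param values Numeric vector of length `n_carbons + 1` (M0..M+n).
#' @param n_carbons Number of carbons in the fragment; defaults to
#'   `length(values) - 1`.
#' @param time_min Sampling time in minutes relative to tracer delivery.
#' @param subject Subject identifier.
#' @param is_excess Logical; `TRUE` marks a natural-abundance-corrected
#'   (excess) distribution.
#' @param tol Numerical tolerance for the non-negativity and sum checks.
#'
#' @return An object of class `"mid"`: a list with fields `metabolite`,
#'   `n_carbons`, `values`, `time_min`, `subject`, `is_excess`.
#' @examples
#' m <- mid("glucose", c(0.9, 0.06, 0.04))
#' total_enrichment(m)
#' @export
mid <- function(metabolite, values, n_carbons = length(values) - 1L,
                time_min = NA_real_, subject = NA_character_,
                is_excess = FALSE, tol = 1e-9) {
  values <- as.numeric(values)
  if (length(values) != n_carbons + 1L)
    stop("`values` must have length n_carbons + 1 (M0..M+n), got ",
         length(values), " for n_carbons = ", n_carbons)
  if (n_carbons < 1L) stop("`n_carbons` must be >= 1")
  if (!is_excess) {
    if (any(values < -tol))
      stop("raw MID values must be non-negative")
    values <- pmax(values, 0)
    s <- sum(values)
    if (s <= 0) stop("raw MID values sum to zero; cannot normalise")
    values <- values / s
  } else {
    if (any(values[-1L] < -1e-6))
      warning("excess MID has labelled entries below -1e-6; ",
              "check the correction inputs")
  }
  structure(
    list(metabolite = as.character(metabolite), n_carbons = as.integer(n_carbons),
         values = values, time_min = time_min, subject = subject,
         is_excess = isTRUE(is_excess)),
    class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s (%d carbons)%s%s\n", x$metabolite, x$n_carbons,
              if (x$is_excess) ", excess" else ", raw",
              if (is.finite(x$time_min)) sprintf(", t = %g min", x$time_min) else ""))
  v <- setNames(round(x$values, 6), paste0("M", 0:x$n_carbons))
  print(v)
  invisible(x)
}

#' Atom-fraction 13C enrichment of a MID
#'
#' Total enrichment of a distribution on an atom basis:
#' \deqn{\sum_{m \ge 1} x_m \, m / n}
#' i.e. the average fraction of the fragment's carbons carrying label. For an
#' excess MID this is the tracer-derived 13C atom-fraction excess.
#'
#' @param dist A [mid()] object (raw or excess form).
#' @return A single number in \[-tol, 1\].
#' @examples
#' total_enrichment(mid("x", c(0.5, 0, 0.5)))  # 0.5
#' @export
total_enrichment <- function(dist) {
  stopifnot(inherits(dist, "mid"))
  sum(dist$values * (0:dist$n_carbons)) / dist$n_carbons
}
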