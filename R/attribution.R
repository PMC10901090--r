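#' Expected-labelling design for plasma glucose
#'
#' Expected isotopologue patterns of plasma glucose derived from each
#' delivered 13C-SCFA, based on known gluconeogenic routes and carbon
#' scrambling at the symmetric fumarate step of the TCA cycle:
#'
#' * `[1-13C1]`-acetate enters as `[1-13C1]`-acetyl-CoA and, after fumarate
#'   scrambling, contributes equally to M0 and M+1 glucose.
#' * `[1,2,3-13C3]`-propionate enters via succinate; scrambling yields
#'   oxaloacetate isotopologues that contribute equally to M+3 and M+2
#'   glucose.
#' * `[1,2,3,4-13C4]`-butyrate is split into two `[1,2-13C2]`-acetyl-CoA;
#'   scrambling yields equal M+1 and M+2 glucose, and one butyrate labels two
#'   glucose units (stoichiometry 2).
#'
#' @param n_carbons Number of glucose fragment carbons (default 6).
#' @return A `"labeling_design"` object: a column matrix over M0..M+n with one
#'   column per source SCFA, plus `stoichiometry` (labelled-product units per
#'   delivered molecule) and `metabolite` attributes.
#' @export
glucose_design <- function(n_carbons = 6L) {
  D <- matrix(0, n_carbons + 1L, 3L,
              dimnames = list(paste0("M", 0:n_carbons),
                              c("acetate", "propionate", "butyrate")))
  D[c("M0", "M1"), "acetate"] <- 0.5
  D[c("M2", "M3"), "propionate"] <- 0.5
  D[c("M1", "M2"), "butyrate"] <- 0.5
  .labeling_design(D, stoichiometry = c(acetate = 1, propionate = 1, butyrate = 2),
                   metabolite = "glucose")
}

#' Expected-labelling design for plasma citrate
#'
#' `[1-13C1]`-acetate yields one `[1-13C1]`-citrate (M+1); each
#' `[1,2,3,4-13C4]`-butyrate yields two `[1,2-13C2]`-citrate molecules (M+2,
#' stoichiometry 2). No propionate-to-citrate pattern is modelled, so the
#' design has two columns.
#'
#' @param n_carbons Number of citrate fragment carbons (default 6).
#' @return A `"labeling_design"` object; see [glucose_design()].
#' @export
citrate_design <- function(n_carbons = 6L) {
  D <- matrix(0, n_carbons + 1L, 2L,
              dimnames = list(paste0("M", 0:n_carbons),
                              c("acetate", "butyrate")))
  D["M1", "acetate"] <- 1
  D["M2", "butyrate"] <- 1
  .labeling_design(D, stoichiometry = c(acetate = 1, butyrate = 2),
                   metabolite = "citrate")
}

.labeling_design <- function(D, stoichiometry, metabolite) {
  stopifnot(all(D >= 0), all(abs(colSums(D) - 1) < 1e-12))
  structure(list(matrix = D, stoichiometry = stoichiometry,
                 metabolite = metabolite),
            class = "labeling_design")
}

#' @export
print.labeling_design <- function(x, ...) {
  cat(sprintf("<labeling_design> %s, sources: %s\n", x$metabolite,
              paste(colnames(x$matrix), collapse = ", ")))
  print(x$matrix)
  cat("stoichiometry:", paste(names(x$stoichiometry), x$stoichiometry,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Attribute excess labelling to the delivered SCFA
#'
#' Regresses an excess MID on the expected per-SCFA labelling columns over
#' the observable labelled isotopologues M+1..M+n (the M0 row is excluded:
#' excess M0 is the complement of the labelled fractions and would
#' double-count information). Coefficients are constrained non-negative by
#' default (contributions are physical amounts); set `nonneg = FALSE` for the
#' unconstrained ordinary least-squares solution.
#'
#' When a dose is supplied, contributions are rescaled to compare transfer
#' efficiency across SCFA: coefficient / (stoichiometry x delivered mmol),
#' normalised to the delivered acetate amount, so acetate's normalised
#' contribution equals its raw coefficient.
#'
#' @param excess An excess-form [mid()] whose metabolite matches the design.
#' @param design A [glucose_design()] or [citrate_design()].
#' @param dose Optional [tracer_dose()] used for the normalised contribution.
#' @param nonneg Constrain coefficients to be non-negative (default `TRUE`).
#' @return An `"attribution"` object: list with `coefficients`,
#'   `normalized_contribution` (or `NULL` without dose), `residual_norm`, and
#'   `condition_number` of the restricted design (large values signal
#'   overlapping columns, e.g. butyrate shares M+1 with acetate and M+2 with
#'   propionate in the glucose design).
#' @examples
#' d <- glucose_design()
#' x <- 0.3 * d$matrix[, "propionate"] + 0.1 * d$matrix[, "butyrate"]
#' x[1] <- 1 - sum(x[-1])
#' attribute_sources(mid("glucose", x, is_excess = TRUE), d)
#' @export
attribute_sources <- function(excess, design, dose = NULL, nonneg = TRUE) {
  stopifnot(inherits(excess, "mid"), inherits(design, "labeling_design"))
  if (!excess$is_excess)
    stop("`excess` must be a natural-abundance-corrected (excess) MID")
  if (!identical(excess$metabolite, design$metabolite))
    stop("MID metabolite '", excess$metabolite, "' does not match design '",
         design$metabolite, "'")
  D <- design$matrix
  if (length(excess$values) != nrow(D))
    stop("MID length does not match the design (", nrow(D), " isotopologues)")
  A <- D[-1L, , drop = FALSE]              # drop the M0 row
  if (any(colSums(A) == 0))
    stop("design has an all-zero column over the labelled isotopologues")
  b <- excess$values[-1L]
  cf <- if (nonneg) {
    pracma::lsqnonneg(A, b)$x
  } else {
    as.vector(qr.solve(A, b))
  }
  names(cf) <- colnames(D)
  kappa <- {
    sv <- svd(A, nu = 0, nv = 0)$d
    sv[1L] / sv[length(sv)]
  }
  norm_contrib <- NULL
  if (!is.null(dose)) {
    stopifnot(inherits(dose, "tracer_dose"))
    dmmol <- dose$mmol[names(cf)]
    if (any(is.na(dmmol)) || any(dmmol <= 0))
      stop("dose must supply a positive amount for every design source")
    norm_contrib <- cf / (design$stoichiometry[names(cf)] * dmmol) *
      dose$mmol[["acetate"]]
  }
  structure(list(coefficients = cf, normalized_contribution = norm_contrib,
                 residual_norm = sqrt(sum((A %*% cf - b)^2)),
                 condition_number = kappa, metabolite = design$metabolite,
                 subject = excess$subject, time_min = excess$time_min),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution> %s (condition number %.2f)\n", x$metabolite,
              x$condition_number))
  print(round(x$coefficients, 6))
  if (!is.null(x$normalized_contribution)) {
    cat("normalised to delivered acetate:\n")
    print(round(x$normalized_contribution, 6))
  }
  invisible(x)
}

#' Screen a MID for unexpected enrichment
#'
#' Pass-through screen for metabolite classes with no modelled labelling
#' route (amino acids, fatty acids, acyl-carnitines): flags every labelled
#' isotopologue whose excess fraction exceeds a threshold. For example,
#' propionyl-carnitine M+3 — direct binding of delivered
#' `[1,2,3-13C3]`-propionate to carnitine — is detected this way.
#'
#' @param excess An excess-form [mid()].
#' @param threshold Excess fraction above which an isotopologue is flagged
#'   (default 0.005).
#' @return A data frame with columns `metabolite`, `iso_index`, `value` for
#'   flagged isotopologues (zero rows if none).
#' @export
screen_enrichment <- function(excess, threshold = 0.005) {
  stopifnot(inherits(excess, "mid"))
  idx <- which(excess$values[-1L] > threshold)
  data.frame(metabolite = rep(excess$metabolite, length(idx)),
             iso_index = idx, value = excess$values[idx + 1L],
             row.names = NULL)
}
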