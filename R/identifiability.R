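#' Scaled sensitivity matrix of the model outputs
#'
#' Sensitivity of every observation (each time point of each of the three
#' glucose curves) to every rate constant, in the parameter-scaled,
#' observation-scaled form used for collinearity analysis:
#' \deqn{S_{ij} = \frac{\partial \hat Y_i}{\partial \theta_j}
#'       \cdot \frac{\theta_j}{w_i}}
#' computed by central finite differences with relative step `rel_step`.
#' Scaling by \eqn{\theta_j} makes columns comparable across parameters of
#' different magnitude; \eqn{w_i} puts the three curves on a common scale.
#' The default observation scale is the curve-wise maximum (the variable
#' scaling of classic sensitivity/collinearity analysis, which reproduces
#' the six-of-eight identifiability structure of this regime);
#' `weighting = "sd"` instead uses the per-point standard deviation of
#' `observed`, matching the weighting of the fit objective.
#'
#' A parameter with value 0 has an identically zero scaled column and is
#' structurally unidentifiable at that point; such columns are flagged in
#' the `"zero_columns"` attribute.
#'
#' @param k [rate_constants()] at which to evaluate (strictly inside the
#'   bounds for parameters you intend to differentiate).
#' @param dose,subject Model inputs.
#' @param times Observation times (min); pre-delivery times contribute
#'   zero-signal rows.
#' @param weights Optional explicit per-observation scales `w_i`, a vector
#'   of `3 * length(times)` (rows ordered source-major: acetate block, then
#'   propionate, then butyrate); overrides `weighting`.
#' @param observed Optional curves data frame; when given, `times` (and the
#'   observation scales) are taken from it.
#' @param weighting Observation scaling rule when `weights` is not given:
#'   `"curve_max"` (default) or `"sd"` (requires `observed` with an sd
#'   column).
#' @param rel_step Relative finite-difference step (default 1e-6).
#' @return A numeric matrix (observations x 8) of class
#'   `"sensitivity_matrix"`, columns named after the rate constants, with
#'   attributes `times`, `sources`, `weights`, `zero_columns` and `scaling`.
#' @export
sensitivity_matrix <- function(k, dose, subject, times = NULL, weights = NULL,
                               observed = NULL,
                               weighting = c("curve_max", "sd"),
                               rel_step = 1e-6) {
  stopifnot(inherits(k, "rate_constants"))
  weighting <- match.arg(weighting)
  if (!is.null(observed)) {
    observed <- .check_curves(observed)
    # keep observation order: source-major, time within source
    observed <- observed[order(match(observed$source,
                                     c("acetate", "propionate", "butyrate")),
                               observed$time_min), ]
    tt <- observed$time_min
    src <- observed$source
    if (is.null(weights) && weighting == "sd")
      weights <- .curve_weights(observed)
  } else {
    if (is.null(times)) stop("supply `times` or `observed`")
    if (weighting == "sd") stop("`weighting = \"sd\"` requires `observed`")
    tt <- rep(times, 3L)
    src <- rep(c("acetate", "propionate", "butyrate"), each = length(times))
  }
  pred0 <- .predict_values(k, dose, subject, tt, src)
  if (is.null(weights)) {
    # curve-wise maximum of the observed values when given, else of the
    # model prediction
    base <- if (!is.null(observed)) observed$value else pred0
    weights <- numeric(length(pred0))
    for (s in unique(src)) {
      m <- max(abs(base[src == s]))
      weights[src == s] <- if (m > 0) m else 1
    }
  }
  if (length(weights) != length(pred0) || any(weights <= 0))
    stop("`weights` must be positive, one per observation")
  kk <- unclass(k)
  S <- matrix(0, length(pred0), length(.K_NAMES),
              dimnames = list(NULL, .K_NAMES))
  for (j in seq_along(.K_NAMES)) {
    th <- kk[.K_NAMES[j]]
    if (th == 0) next  # zero column: structurally unidentifiable here
    h <- rel_step * th
    kp <- kk; kp[j] <- th + h; km <- kk; km[j] <- th - h
    class(kp) <- class(km) <- "rate_constants"
    dY <- (.predict_values(kp, dose, subject, tt, src) -
           .predict_values(km, dose, subject, tt, src)) / (2 * h)
    S[, j] <- dY * th / weights
  }
  zero_cols <- .K_NAMES[colSums(abs(S)) == 0]
  structure(S, class = c("sensitivity_matrix", "matrix", "array"),
            times = tt, sources = src, weights = weights,
            zero_columns = zero_cols,
            scaling = "dY/dtheta * theta / w (relative parameter scaling)")
}

#' Collinearity index of a parameter subset
#'
#' Each selected column of the sensitivity matrix is normalised to unit
#' Euclidean norm, giving \eqn{\tilde S}; the index is
#' \deqn{\gamma = 1 / \sqrt{\lambda_{\min}(\tilde S^\top \tilde S)}.}
#' \eqn{\gamma = 1} for mutually orthogonal columns; large values mean the
#' parameters' effects on the observed outputs are nearly linearly
#' dependent, so the subset is practically unidentifiable. A subset
#' containing a zero column has infinite index.
#'
#' @param S A [sensitivity_matrix()] (or any numeric matrix with named
#'   columns).
#' @param subset Column names or indices, at least 2.
#' @return The scalar index (`>= 1`, possibly `Inf`).
#' @export
collinearity_index <- function(S, subset) {
  Ssub <- S[, subset, drop = FALSE]
  if (ncol(Ssub) < 2L) stop("subset must contain at least 2 parameters")
  nrm <- sqrt(colSums(Ssub^2))
  if (any(nrm == 0)) return(Inf)
  Sn <- sweep(Ssub, 2L, nrm, "/")
  lam <- min(eigen(crossprod(Sn), symmetric = TRUE, only.values = TRUE)$values)
  if (lam <= 0) Inf else 1 / sqrt(lam)
}

#' Exhaustive identifiability report over parameter subsets
#'
#' Computes the collinearity index of every subset of the model parameters
#' of sizes 2..8 (247 subsets) and reports, for the given threshold, the
#' largest subset size for which at least one subset is identifiable
#' (index below the threshold). A threshold of 20 is the conventional
#' identifiability cut-off.
#'
#' @param S A [sensitivity_matrix()].
#' @param threshold Identifiability cut-off on the index (default 20).
#' @param sizes Subset sizes to enumerate (default `2:ncol(S)`).
#' @return A `"collinearity_report"`: a data frame with columns `subset`
#'   (e.g. `"k1a+k2"`), `size`, `index`, `identifiable`, with attributes
#'   `threshold` and `max_identifiable_size`.
#' @export
identifiable_subsets <- function(S, threshold = 20, sizes = 2:ncol(S)) {
  pn <- colnames(S)
  rows <- list()
  for (sz in sizes) {
    cm <- combn(length(pn), sz)
    idx <- apply(cm, 2L, function(ii) collinearity_index(S, pn[ii]))
    rows[[length(rows) + 1L]] <- data.frame(
      subset = apply(cm, 2L, function(ii) paste(pn[ii], collapse = "+")),
      size = sz, index = idx, identifiable = idx < threshold)
  }
  rep <- do.call(rbind, rows)
  ok <- rep$size[rep$identifiable]
  structure(rep, threshold = threshold,
            max_identifiable_size = if (length(ok)) max(ok) else 0L,
            class = c("collinearity_report", "data.frame"))
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat(sprintf(
    "<collinearity_report> %d subsets, threshold %g, max identifiable size %d\n",
    nrow(x), attr(x, "threshold"), attr(x, "max_identifiable_size")))
  by_size <- split(x, x$size)
  for (b in by_size) {
    best <- b[which.min(b$index), ]
    cat(sprintf("  size %d: %3d/%3d identifiable; best %s (index %.2f)\n",
                best$size, sum(b$identifiable), nrow(b), best$subset,
                best$index))
  }
  invisible(x)
}

#' Select the second parameter to fix alongside kLa
#'
#' Given that `kLa` must be fixed (the unobserved liver intermediate leaves
#' it data-poor), selects the companion parameter whose fixing makes the
#' remaining six free parameters best identifiable: the candidate minimising
#' the collinearity index of the complementary six-parameter subset.
#'
#' @param S A [sensitivity_matrix()].
#' @param first The parameter already chosen to be fixed (default `"kLa"`).
#' @return A list with `second` (the selected parameter name) and `table`
#'   (index of the remaining-six subset for each candidate).
#' @export
select_second_fixed <- function(S, first = "kLa") {
  pn <- colnames(S)
  stopifnot(first %in% pn)
  cand <- setdiff(pn, first)
  idx <- vapply(cand, function(p)
    collinearity_index(S, setdiff(pn, c(first, p))), numeric(1))
  list(second = cand[which.min(idx)],
       table = data.frame(candidate = cand, remaining_index = idx,
                          row.names = NULL))
}
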