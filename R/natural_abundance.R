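#' Natural-abundance model for 13C correction
#'
#' Parameters of the isotope model used to build the correction matrix. Only
#' carbon is considered: every non-tracer carbon of the fragment is 13C with
#' probability `p13C` independently. The default 0.0107 is the standard
#' terrestrial natural abundance of 13C.
#'
#' @param p13C Fractional natural abundance of 13C, in \[0, 1).
#' @return An object of class `"na_model"`.
#' @export
natural_abundance_model <- function(p13C = 0.0107) {
  if (!is.numeric(p13C) || length(p13C) != 1L || p13C < 0 || p13C >= 1)
    stop("`p13C` must be a single number in [0, 1)")
  structure(list(p13C = p13C), class = "na_model")
}

#' Natural-abundance correction matrix
#'
#' Builds the (n+1) x (n+1) matrix `C` whose entry (i, j) is the probability
#' that a molecule carrying j tracer-labelled carbons is observed at nominal
#' mass shift i, the remaining n - j carbons being 13C-labelled at natural
#' abundance independently (binomial). Measured raw fractions `m` relate to
#' the true excess fractions `x` by `m = C x`; [correct_natural_abundance()]
#' inverts this relation by constrained least squares.
#'
#' Columns are lower-triangular (a tracer shift cannot decrease) and each
#' column sums to 1 since mass shifts up to n are always representable.
#'
#' @param n_carbons Number of fragment carbons, >= 1.
#' @param model A [natural_abundance_model()].
#' @return A numeric matrix of order `n_carbons + 1` with dimnames
#'   `M0..M+n` (observed) by `M0..M+n` (true).
#' @examples
#' correction_matrix(1)            # [[0.9893, 0], [0.0107, 1]]
#' correction_matrix(2, natural_abundance_model(0))  # identity
#' @export
correction_matrix <- function(n_carbons, model = natural_abundance_model()) {
  if (!is.numeric(n_carbons) || length(n_carbons) != 1L || n_carbons < 1)
    stop("`n_carbons` must be a single integer >= 1")
  stopifnot(inherits(model, "na_model"))
  n <- as.integer(n_carbons)
  p <- model$p13C
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    # j tracer carbons fixed; the other n - j carbons add k natural 13C
    C[(j + 1L):(n + 1L), j + 1L] <- dbinom(0:(n - j), n - j, p)
  }
  dimnames(C) <- list(observed = paste0("M", 0:n), true = paste0("M", 0:n))
  C
}

#' Correct a raw MID for natural 13C abundance
#'
#' Solves `C x ~= raw` for the excess fractional distribution `x` by least
#' squares, with non-negativity enforced on the labelled entries M+1..M+n
#' (M0 is left unconstrained, so the excess M0 can be negative when labelled
#' species displace the monoisotopic peak). The solution is renormalised to
#' sum to 1 and returned as an excess-form [mid()].
#'
#' With `p13C = 0` the matrix is the identity and the input is returned
#' unchanged (up to normalisation).
#'
#' @param raw A raw-form [mid()].
#' @param model A [natural_abundance_model()].
#' @return An excess-form [mid()] with the same metadata.
#' @examples
#' C <- correction_matrix(6)
#' truth <- c(0.6, 0, 0.4, 0, 0, 0, 0)
#' raw <- mid("glucose", as.vector(C %*% truth))
#' correct_natural_abundance(raw)$values  # recovers truth
#' @export
correct_natural_abundance <- function(raw, model = natural_abundance_model()) {
  stopifnot(inherits(raw, "mid"))
  if (raw$is_excess)
    stop("input MID is already in excess form")
  C <- correction_matrix(raw$n_carbons, model)
  y <- raw$values
  if (length(y) != ncol(C))
    stop("MID length does not match the correction matrix order")
  if (rcond(C) < 1e-12)
    stop("correction matrix is numerically singular (p13C too close to 1?)")
  x <- .solve_m0_free_nnls(C, y)
  s <- sum(x)
  if (abs(s) > 1e-12) x <- x / s
  mid(raw$metabolite, x, n_carbons = raw$n_carbons, time_min = raw$time_min,
      subject = raw$subject, is_excess = TRUE)
}

# least squares min ||A z - y|| with z[1] free and z[-1] >= 0:
# project out the first column, run NNLS on the projected system, then
# back-substitute the free coordinate.
.solve_m0_free_nnls <- function(A, y) {
  a0 <- A[, 1L]
  P <- diag(length(y)) - tcrossprod(a0) / sum(a0^2)
  rest <- pracma::lsqnonneg(P %*% A[, -1L, drop = FALSE], as.vector(P %*% y))$x
  z0 <- sum(a0 * (y - A[, -1L, drop = FALSE] %*% rest)) / sum(a0^2)
  c(z0, rest)
}
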