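#' Mass isotopomer distribution (MID) primitives
#'
#' An MID for an n-carbon species is a numeric vector of length `n + 1`
#' holding the fractional abundances of the mass isotopomers M+0 ... M+n.
#' MIDs are represented throughout the package as plain numeric vectors;
#' a *missing* MID (peak not measured in an experiment) is represented as
#' `NULL`, never as an all-zero vector.
#'
#' @name mid
NULL

#' Validate an MID vector
#'
#' Checks that `x` is a non-negative numeric vector summing to 1 within
#' tolerance. Used internally before any arithmetic on MIDs.
#'
#' @param x numeric vector of mass-isotopomer fractions (length n + 1).
#' @param tol tolerance on the deviation of `sum(x)` from 1.
#' @return `x`, invisibly, after validation.
#' @export
validate_mid <- function(x, tol = 1e-6) {
  if (!is.numeric(x) || length(x) < 1L) {
    abort("an MID must be a numeric vector of length >= 1", class = "midtrace_error")
  }
  if (anyNA(x)) abort("MID contains NA fractions", class = "midtrace_error")
  if (any(x < 0)) abort("MID contains negative fractions", class = "midtrace_error")
  if (abs(sum(x) - 1) > tol) {
    abort(sprintf("MID fractions sum to %.6g, not 1", sum(x)), class = "midtrace_error")
  }
  invisible(x)
}

#' Normalize raw mass-isotopomer abundances to an MID
#'
#' Divides each mass-isotopomer abundance (e.g. an integrated LCMS peak
#' area) by the total across all isotopomers, so the result sums to 1.
#' Small negative values (from baseline subtraction) are clipped to zero
#' before normalizing.
#'
#' @param x numeric vector of raw non-negative abundances, M+0 first.
#' @param neg_tol negative entries with magnitude below this are clipped
#'   to 0; larger negatives are an error.
#' @return a normalized MID (numeric vector summing to 1).
#' @examples
#' mid_normalize(c(2, 2))       # c(0.5, 0.5)
#' mid_normalize(c(1, 0, 0))    # unchanged
#' @export
mid_normalize <- function(x, neg_tol = 1e-8) {
  if (!is.numeric(x) || length(x) < 1L) {
    abort("input must be a numeric vector of length >= 1", class = "midtrace_error")
  }
  if (anyNA(x)) abort("raw abundances contain NA", class = "midtrace_error")
  if (any(x < -abs(neg_tol))) {
    abort("raw abundances contain negative entries beyond tolerance",
          class = "midtrace_error")
  }
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) abort("empty MID: all abundances are zero", class = "midtrace_empty_mid")
  x / s
}

#' Convolve two MIDs
#'
#' The MID of a molecule formed by joining two carbon skeletons is the
#' convolution of the moiety MIDs: the distribution of the sum of two
#' independent labeled-carbon counts,
#' \deqn{(x^A \times x^C)_k = \sum_{i+j=k} x^A_i x^C_j .}
#'
#' @param a,c_ MIDs (numeric vectors). `c_` may be the length-1 vector
#'   `1` (a zero-carbon moiety), which acts as the identity.
#' @return an MID of length `length(a) + length(c_) - 1`.
#' @examples
#' mid_convolve(c(0.5, 0.5), c(0.5, 0.5))  # c(0.25, 0.5, 0.25)
#' @export
mid_convolve <- function(a, c_) {
  validate_mid(a)
  validate_mid(c_)
  na <- length(a)
  nc <- length(c_)
  out <- numeric(na + nc - 1L)
  # accumulate in ascending i so results are reproducible bit-for-bit
  for (i in seq_len(na)) {
    idx <- i:(i + nc - 1L)
    out[idx] <- out[idx] + a[i] * c_
  }
  out
}

#' Fractional 13C enrichment of an MID
#'
#' The average fraction of a compound's carbon atoms that are 13C,
#' \eqn{\sum_{i=1}^{n} i\, x_i / n}: 0 for a fully unlabeled compound and
#' 1 for a fully labeled one. `per_isotopomer = TRUE` switches to the
#' alternative reading \eqn{\sum_{i \ge 1} x_i / n} (the summed fraction
#' of labeled isotopomers divided by n), retained for sensitivity checks.
#'
#' @param x an MID.
#' @param per_isotopomer logical; use the unweighted isotopomer sum.
#' @return a number in `[0, 1]`.
#' @examples
#' mid_enrichment(c(0.5, 0, 0.5))  # 0.5
#' @export
mid_enrichment <- function(x, per_isotopomer = FALSE) {
  validate_mid(x)
  n <- length(x) - 1L
  if (n < 1L) abort("enrichment is undefined for a 0-carbon species",
                    class = "midtrace_error")
  if (per_isotopomer) sum(x[-1L]) / n else sum(seq_len(n) * x[-1L]) / n
}

#' Euclidean distance between two equal-carbon MIDs
#'
#' @param a,b MIDs with the same carbon count.
#' @return non-negative number; 0 iff the MIDs are identical.
#' @export
mid_euclidean <- function(a, b) {
  if (length(a) != length(b)) {
    abort("carbon-count mismatch: use the convolutant search for unequal sizes",
          class = "midtrace_error")
  }
  sqrt(sum((a - b)^2))
}

#' Unlabeled MID for an n-carbon species
#'
#' @param n_carbons non-negative integer.
#' @return the MID `c(1, 0, ..., 0)` of length `n_carbons + 1`.
#' @export
mid_unlabeled <- function(n_carbons) {
  c(1, numeric(n_carbons))
}
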