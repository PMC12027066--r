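#' Natural 13C abundance correction
#'
#' Naturally occurring 13C (about 1.07% of carbon) shifts part of each
#' mass isotopomer's signal upward in mass. With `j` tracer-labeled
#' carbons in an n-carbon species, the remaining `n - j` positions each
#' carry a natural 13C independently, so the measured isotopomer `k`
#' receives from the "clean" isotopomer `j` a Binomial contribution
#' \deqn{M_{kj} = \binom{n-j}{k-j} p^{k-j} (1-p)^{n-k}, \quad k \ge j,}
#' with `p` the natural 13C abundance. Correction solves the
#' lower-triangular system `measured = M corrected`, clips any negative
#' components (possible with noisy data), and renormalizes. Only carbon is
#' corrected: the tracer element is assumed to dominate and non-carbon
#' isotopes to have been handled upstream.
#'
#' @name natural_abundance
NULL

#' Binomial natural-abundance correction matrix
#'
#' @param n_carbons number of carbon atoms.
#' @param p13 natural 13C abundance (fraction; default 0.0107).
#' @return an `(n+1) x (n+1)` lower-triangular matrix mapping clean MIDs
#'   to measured MIDs; the identity when `p13 = 0`.
#' @export
correction_matrix <- function(n_carbons, p13 = 0.0107) {
  n <- as.integer(n_carbons)
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- j:n
    M[k + 1L, j + 1L] <- dbinom(k - j, size = n - j, prob = p13)
  }
  M
}

#' Apply the forward natural-abundance model
#'
#' Turns a clean (tracer-only) MID into the MID that would be measured in
#' the presence of natural 13C. Useful for simulating realistic data and
#' for round-trip testing of [correct_natural_abundance()].
#'
#' @param x a clean MID.
#' @inheritParams correction_matrix
#' @return the measured-scale MID.
#' @export
apply_natural_abundance <- function(x, p13 = 0.0107) {
  validate_mid(x)
  as.numeric(correction_matrix(length(x) - 1L, p13) %*% x)
}

#' Correct a measured MID for natural 13C
#'
#' @param x a measured MID.
#' @inheritParams correction_matrix
#' @return the corrected MID (non-negative, renormalized). When no
#'   clipping triggers this is the exact inverse of
#'   [apply_natural_abundance()]. The number of clipped components is
#'   attached as attribute `"n_clipped"`.
#' @export
correct_natural_abundance <- function(x, p13 = 0.0107) {
  validate_mid(x)
  M <- correction_matrix(length(x) - 1L, p13)
  sol <- solve(M, x)
  n_clipped <- sum(sol < 0)
  sol <- pmax(sol, 0)
  s <- sum(sol)
  if (s <= 0) abort("correction annihilated the MID", class = "midtrace_error")
  structure(sol / s, n_clipped = n_clipped)
}

#' Correct a whole peak table for natural 13C
#'
#' Returns a copy of the table with every MID corrected. The result is
#' flagged with attribute `corrected = TRUE`; distance functions warn if
#' given a corrected table, since the MID distance is defined on
#' uncorrected data.
#'
#' @param table a `peak_tbl`.
#' @inheritParams correction_matrix
#' @return a corrected `peak_tbl`.
#' @export
correct_peak_table <- function(table, p13 = 0.0107) {
  table$mids <- lapply(table$mids, function(m) {
    lapply(m, function(x) as.numeric(correct_natural_abundance(x, p13)))
  })
  out <- peak_table(as_tibble(table), experiments = experiments(table))
  attr(out, "corrected") <- TRUE
  out
}
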