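#' Biochemical relatedness from carbon contribution
#'
#' The gold standard used to evaluate the MID distance: the fraction `f`
#' of carbon that one metabolite contributes to another at the network's
#' flux state. To compute the contribution of A to B, A is turned into a
#' network substrate (its incoming label is replaced by a fully labeled
#' external source; all fluxes stay untouched so the flux state matches
#' the MID simulation), the steady-state EMU equations are solved, and
#' the 13C enrichment of B is read off. Since the fraction of B derived
#' from A need not equal the fraction of A derived from B, the symmetric
#' measure is \eqn{f(A,B) = \max} of the two directional contributions,
#' with `f(A, A) = 1`.
#'
#' @name relatedness
NULL

# Re-source a network so that `source_met` is a substrate.
.as_source <- function(network, source_met) {
  i <- match(source_met, network$metabolites$id)
  if (is.na(i)) abort(paste0("unknown metabolite: ", source_met),
                      class = "midtrace_error")
  network$metabolites$is_substrate[i] <- TRUE
  network
}

#' Carbon contribution of one metabolite to all others
#'
#' One steady-state solve with `source` fully labeled and every true
#' network substrate unlabeled; returns the enrichment of every
#' metabolite.
#'
#' @param network an `atom_network`.
#' @param source metabolite id acting as the (fully labeled) carbon
#'   source.
#' @return named numeric vector over all metabolites: the fraction of
#'   each metabolite's carbon derived from `source` (1 for `source`
#'   itself; 0 for metabolites unreachable from it).
#' @export
carbon_contribution_from <- function(network, source) {
  mod <- .as_source(network, source)
  tracer <- tracer_config(source, positions = "U", fraction = 1, purity = 1)
  ss <- simulate_steady_state(mod, tracer)
  vapply(names(ss), function(m) {
    if (length(ss[[m]]) <= 1L) 0 else mid_enrichment(mid_normalize(ss[[m]]))
  }, numeric(1))
}

#' Carbon contribution between two metabolites
#'
#' @inheritParams carbon_contribution_from
#' @param a source metabolite; `b` target metabolite.
#' @param b target metabolite id.
#' @return the directional contribution of `a` to `b` in `[0, 1]`.
#' @export
carbon_contribution <- function(network, a, b) {
  if (identical(a, b)) abort("a and b must differ", class = "midtrace_error")
  unname(carbon_contribution_from(network, a)[b])
}

#' Pairwise relatedness matrix
#'
#' Computes `f(A, B) = max(contribution A -> B, contribution B -> A)` for
#' every pair, using one modified-network steady-state solve per source
#' metabolite.
#'
#' @param network an `atom_network`.
#' @return a `relatedness` object: symmetric matrix of f values with unit
#'   diagonal; the directional contributions are kept in attribute
#'   `"contributions"` (rows = source, columns = target).
#' @export
relatedness_matrix <- function(network) {
  mets <- network$metabolites$id
  contrib <- matrix(0, length(mets), length(mets), dimnames = list(mets, mets))
  for (m in mets) contrib[m, ] <- carbon_contribution_from(network, m)[mets]
  f <- pmax(contrib, t(contrib))
  diag(f) <- 1
  structure(f, contributions = contrib, class = c("relatedness", "matrix"))
}

#' Label biochemically related pairs
#'
#' Pairs with `f > threshold` (strict) are positives.
#'
#' @param f a `relatedness` matrix (or plain symmetric matrix).
#' @param threshold relatedness cutoff, in (0, 1) (default 0.5).
#' @return a tibble of all unordered pairs: `peak_a`, `peak_b` (sorted
#'   ids), `f`, `related` (logical).
#' @export
related_pairs <- function(f, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)", class = "midtrace_error")
  }
  ids <- rownames(f)
  pairs <- which(upper.tri(f), arr.ind = TRUE)
  a <- ids[pairs[, 1]]; b <- ids[pairs[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  fv <- f[pairs]
  out <- tibble(peak_a = a, peak_b = b, f = fv, related = fv > threshold)
  out[order(out$peak_a, out$peak_b), , drop = FALSE]
}

#' Read / write a relatedness matrix as TSV
#' @param f a `relatedness` matrix.
#' @param path file path.
#' @export
write_relatedness <- function(f, path) {
  df <- as.data.frame(unclass(f))
  df <- cbind(id = rownames(f), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_relatedness
#' @export
read_relatedness <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  m <- vapply(df[, -1, drop = FALSE], as.numeric, numeric(nrow(df)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(df),
                                   dimnames = list(NULL, names(df)[-1]))
  rownames(m) <- df$id
  structure(m, class = c("relatedness", "matrix"))
}
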