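#' Convolution-based MID distances
#'
#' The distance between two peaks A (m carbons) and B (n carbons, m <= n)
#' compares B's MID against the convolution of A's MID with that of a
#' *convolutant* C — any peak in the table with n - m carbons, standing in
#' for the carbon moiety added in a pathway A + C -> B:
#' \deqn{d(A,B) = \min_C \sum_e \lVert x^{A,e} \times x^{C,e} - x^{B,e} \rVert}
#' where the sum runs over labeling experiments e and \eqn{\lVert\cdot\rVert}
#' is the Euclidean norm. For equal carbon counts (m = n) the distance is
#' the direct multi-experiment Euclidean distance (the unique 0-carbon
#' convolutant). If the table contains no convolutant of the required
#' size, the pair is assigned the largest distance observed across all
#' defined pairs (a sentinel, flagged in `status`). An experiment
#' contributes to the sum only when A, B and C all have an MID there;
#' candidates sharing no experiment with the pair are skipped.
#'
#' Distances are meant to be computed on MIDs *not* corrected for natural
#' 13C; passing a corrected table triggers a warning. The measure is
#' symmetric and non-negative but violates the triangle inequality, so it
#' is not a metric.
#'
#' @name mid_distance
NULL

.dist_warn_corrected <- function(table) {
  if (isTRUE(attr(table, "corrected"))) {
    warn(paste("this peak table has been corrected for natural 13C;",
               "MID distances are intended for uncorrected MIDs"))
  }
}

# Direct (equal-size) multi-experiment distance; exps in table order.
.direct_distance <- function(mids_a, mids_b, exps) {
  shared <- exps[exps %in% names(mids_a) & exps %in% names(mids_b)]
  if (length(shared) == 0) return(NULL)
  d <- 0
  for (e in shared) d <- d + sqrt(sum((mids_a[[e]] - mids_b[[e]])^2))
  list(distance = d, n_experiments = length(shared))
}

#' MID distance between one pair of peaks
#'
#' Computes `d(A, B)` for a single pair, searching all convolutants in
#' `table`. The missing-convolutant sentinel is a table-wide quantity, so
#' this function reports such pairs with `distance = NA` and
#' `status = "missing_convolutant"`; [pairwise_mid_distances()] fills in
#' the sentinel value.
#'
#' @param table a `peak_tbl`.
#' @param a,b peak ids (order irrelevant; the smaller-carbon peak plays A).
#' @param use_experiments optional subset of experiment ids.
#' @return a one-row tibble: `peak_a`, `peak_b`, `distance`,
#'   `best_convolutant` (`"direct"` for equal sizes, `"none"` when no
#'   convolutant exists), `n_experiments`, `status` (one of `"ok"`,
#'   `"direct"`, `"missing_convolutant"`, `"incomparable"`).
#' @export
mid_distance <- function(table, a, b, use_experiments = NULL) {
  .dist_warn_corrected(table)
  if (identical(a, b)) abort("a and b must differ", class = "midtrace_error")
  exps <- experiments(table)
  if (!is.null(use_experiments)) exps <- exps[exps %in% use_experiments]
  ia <- match(a, table$peak_id); ib <- match(b, table$peak_id)
  if (is.na(ia) || is.na(ib)) abort("unknown peak id", class = "midtrace_error")
  if (table$n_carbons[ia] > table$n_carbons[ib]) { tmp <- ia; ia <- ib; ib <- tmp }
  m <- table$n_carbons[ia]; n <- table$n_carbons[ib]
  mids_a <- table$mids[[ia]]; mids_b <- table$mids[[ib]]
  row <- tibble(peak_a = table$peak_id[ia], peak_b = table$peak_id[ib],
                distance = NA_real_, best_convolutant = NA_character_,
                n_experiments = 0L, status = "incomparable")
  shared_ab <- exps[exps %in% names(mids_a) & exps %in% names(mids_b)]
  if (length(shared_ab) == 0) return(row)
  if (m == n) {
    dd <- .direct_distance(mids_a, mids_b, exps)
    row$distance <- dd$distance; row$best_convolutant <- "direct"
    row$n_experiments <- dd$n_experiments; row$status <- "direct"
    return(row)
  }
  k <- n - m
  cand <- which(table$n_carbons == k)
  cand <- cand[order(table$peak_id[cand])]
  best <- Inf; best_id <- NA_character_; best_ne <- 0L
  for (ic in cand) {
    mids_c <- table$mids[[ic]]
    e_ok <- exps[exps %in% names(mids_a) & exps %in% names(mids_b) &
                 exps %in% names(mids_c)]
    if (length(e_ok) == 0) next
    d <- 0
    for (e in e_ok) {
      d <- d + sqrt(sum((mid_convolve(mids_a[[e]], mids_c[[e]]) - mids_b[[e]])^2))
    }
    if (d < best) { best <- d; best_id <- table$peak_id[ic]; best_ne <- length(e_ok) }
  }
  if (is.infinite(best)) {
    row$best_convolutant <- "none"; row$status <- "missing_convolutant"
  } else {
    row$distance <- best; row$best_convolutant <- best_id
    row$n_experiments <- best_ne; row$status <- "ok"
  }
  row
}

#' All pairwise MID distances
#'
#' Computes `d(A, B)` for every unordered pair of peaks. For each peak A
#' and candidate convolutant C the convolution is computed once per
#' experiment and reused across all targets B of matching size; results
#' are identical to per-pair [mid_distance()] calls. After the sweep, the
#' missing-convolutant sentinel (the maximum over all defined distances)
#' is written into pairs for which no convolutant of the required size
#' exists.
#'
#' @inheritParams mid_distance
#' @return a `mid_dist` tibble (one row per unordered pair) with the
#'   columns of [mid_distance()]; attributes `sentinel` (the global max
#'   used for missing-convolutant pairs), `peak_ids` and `experiments`.
#' @export
pairwise_mid_distances <- function(table, use_experiments = NULL) {
  .dist_warn_corrected(table)
  if (nrow(table) < 2) abort("need at least two peaks", class = "midtrace_error")
  exps <- experiments(table)
  if (!is.null(use_experiments)) exps <- exps[exps %in% use_experiments]
  ids <- table$peak_id
  nc <- table$n_carbons
  mids <- table$mids
  sizes <- sort(unique(nc))
  by_size <- split(seq_along(ids), nc)

  out <- vector("list", length(ids) * (length(ids) - 1L) / 2L)
  pos <- 0L
  emit <- function(ia, ib, distance, conv, ne, status) {
    pos <<- pos + 1L
    out[[pos]] <<- list(peak_a = ids[ia], peak_b = ids[ib], distance = distance,
                        best_convolutant = conv, n_experiments = ne,
                        status = status)
  }

  for (m in sizes) {
    Ai <- by_size[[as.character(m)]]
    for (n in sizes[sizes >= m]) {
      Bi <- by_size[[as.character(n)]]
      if (m == n) {
        for (p in seq_along(Ai)) {
          ia <- Ai[p]
          for (q in seq_along(Bi)) {
            ib <- Bi[q]
            if (ids[ib] <= ids[ia]) next
            dd <- .direct_distance(mids[[ia]], mids[[ib]], exps)
            if (is.null(dd)) emit(ia, ib, NA_real_, NA_character_, 0L, "incomparable")
            else emit(ia, ib, dd$distance, "direct", dd$n_experiments, "direct")
          }
        }
      } else {
        k <- n - m
        cand <- by_size[[as.character(k)]]
        cand <- cand[order(ids[cand])]
        for (ia in Ai) {
          mids_a <- mids[[ia]]
          # cache conv(A, C) per experiment, reused across every B of size n
          convs <- lapply(cand, function(ic) {
            mids_c <- mids[[ic]]
            e_ac <- exps[exps %in% names(mids_a) & exps %in% names(mids_c)]
            setNames(lapply(e_ac, function(e) {
              mid_convolve(mids_a[[e]], mids_c[[e]])
            }), e_ac)
          })
          for (ib in Bi) {
            mids_b <- mids[[ib]]
            shared_ab <- exps[exps %in% names(mids_a) & exps %in% names(mids_b)]
            if (length(shared_ab) == 0) {
              emit(ia, ib, NA_real_, NA_character_, 0L, "incomparable"); next
            }
            best <- Inf; best_id <- NA_character_; best_ne <- 0L
            for (ci in seq_along(cand)) {
              cv <- convs[[ci]]
              e_ok <- names(cv)[names(cv) %in% names(mids_b)]
              if (length(e_ok) == 0) next
              d <- 0
              for (e in e_ok) d <- d + sqrt(sum((cv[[e]] - mids_b[[e]])^2))
              if (d < best) {
                best <- d; best_id <- ids[cand[ci]]; best_ne <- length(e_ok)
              }
            }
            if (is.infinite(best)) emit(ia, ib, NA_real_, "none", 0L,
                                        "missing_convolutant")
            else emit(ia, ib, best, best_id, best_ne, "ok")
          }
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  defined <- res$status %in% c("ok", "direct")
  sentinel <- if (any(defined)) max(res$distance[defined]) else NA_real_
  res$distance[res$status == "missing_convolutant"] <- sentinel
  res <- res[order(res$peak_a, res$peak_b), , drop = FALSE]
  structure(res, sentinel = sentinel, peak_ids = ids, experiments = exps,
            class = c("mid_dist", class(res)))
}

#' @export
glance.mid_dist <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_defined = sum(x$status %in% c("ok", "direct")),
         n_missing_convolutant = sum(x$status == "missing_convolutant"),
         n_incomparable = sum(x$status == "incomparable"),
         sentinel = attr(x, "sentinel") %||% NA_real_)
}

#' Dense distance matrix from pairwise results
#'
#' @param d a `mid_dist` tibble.
#' @return a symmetric numeric matrix with zero diagonal; incomparable
#'   pairs are `NA`, missing-convolutant pairs carry the sentinel value.
#' @export
dist_matrix <- function(d) {
  ids <- attr(d, "peak_ids") %||% sort(unique(c(d$peak_a, d$peak_b)))
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(M) <- 0
  ia <- match(d$peak_a, ids); ib <- match(d$peak_b, ids)
  M[cbind(ia, ib)] <- d$distance
  M[cbind(ib, ia)] <- d$distance
  M
}

#' Nearest neighbors of a peak by MID distance
#'
#' @param d a `mid_dist` tibble.
#' @param peak_id the query peak.
#' @param k number of neighbors (capped at the number of other peaks).
#' @return a tibble of up to `k` rows, ascending by distance with ties
#'   broken by neighbor id: `peak_id`, `distance`, `best_convolutant`,
#'   `status`, `rank`. Incomparable pairs are excluded; sentinel pairs
#'   rank last at the sentinel value.
#' @export
nearest_neighbors <- function(d, peak_id, k = 20L) {
  if (k < 1) abort("k must be >= 1", class = "midtrace_error")
  ids <- attr(d, "peak_ids") %||% unique(c(d$peak_a, d$peak_b))
  if (!peak_id %in% ids) abort(paste0("unknown peak id: ", peak_id),
                               class = "midtrace_error")
  sub <- d[(d$peak_a == peak_id | d$peak_b == peak_id) & !is.na(d$distance), ,
           drop = FALSE]
  other <- ifelse(sub$peak_a == peak_id, sub$peak_b, sub$peak_a)
  ord <- order(sub$distance, other)
  res <- tibble(peak_id = other[ord], distance = sub$distance[ord],
                best_convolutant = sub$best_convolutant[ord],
                status = sub$status[ord])
  res <- head(res, k)
  res$rank <- seq_len(nrow(res))
  res
}

#' Distance-threshold network
#'
#' Undirected edges between all peak pairs with `d < cutoff` (strict, per
#' the conservative-cutoff convention). Incomparable pairs never form
#' edges.
#'
#' @param d a `mid_dist` tibble.
#' @param cutoff positive distance cutoff (default 0.7).
#' @return a tibble of edges: `peak_a`, `peak_b`, `distance`,
#'   `best_convolutant`, `status`.
#' @export
threshold_network <- function(d, cutoff = 0.7) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort("cutoff must be > 0", class = "midtrace_error")
  }
  keep <- !is.na(d$distance) & d$distance < cutoff
  as_tibble(d[keep, c("peak_a", "peak_b", "distance", "best_convolutant",
                      "status")])
}

#' Read / write pairwise distances as long-form TSV
#'
#' @param d a `mid_dist` tibble.
#' @param path file path.
#' @export
write_distances <- function(d, path) {
  readr::write_tsv(as_tibble(d), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  res <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  res$distance <- as.numeric(res$distance)
  res$n_experiments <- as.integer(res$n_experiments)
  defined <- res$status %in% c("ok", "direct")
  sentinel <- if (any(defined)) max(res$distance[defined]) else NA_real_
  structure(res, sentinel = sentinel,
            peak_ids = unique(c(res$peak_a, res$peak_b)),
            class = c("mid_dist", class(res)))
}
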