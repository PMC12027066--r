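#' Precision-recall evaluation of MID distances
#'
#' Distances are scored against gold-standard "biochemically related"
#' pair labels by sweeping a threshold over the distance values: at each
#' threshold, pairs at or below it are predicted related. Pairs carrying
#' the missing-convolutant sentinel hold no information and are excluded
#' from the sweep (reported separately); incomparable pairs likewise.
#' The area under the precision-recall curve (AUPR) uses trapezoidal
#' integration over recall, with an initial point at recall 0 and the
#' precision of the smallest threshold. A random ranking yields AUPR
#' close to the prevalence of positive pairs.
#'
#' @name evaluation
NULL

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Join distances with labels; returns distance + related for usable pairs.
.labeled_distances <- function(d, labels, include_sentinel = FALSE) {
  keep_status <- c("ok", "direct", if (include_sentinel) "missing_convolutant")
  dd <- d[d$status %in% keep_status & !is.na(d$distance), , drop = FALSE]
  lab <- setNames(labels$related, .pair_key(labels$peak_a, labels$peak_b))
  rel <- lab[.pair_key(dd$peak_a, dd$peak_b)]
  dd <- dd[!is.na(rel), , drop = FALSE]
  dd$related <- as.logical(rel[!is.na(rel)])
  dd
}

#' Precision-recall curve and AUPR
#'
#' @param d a `mid_dist` tibble (or any tibble with `peak_a`, `peak_b`,
#'   `distance`, `status`).
#' @param labels pair labels as returned by [related_pairs()]: a tibble
#'   with `peak_a`, `peak_b`, `related`.
#' @param include_sentinel rank missing-convolutant pairs last instead of
#'   excluding them.
#' @return a `pr_curve`: tibble of `(threshold, tp, fp, precision,
#'   recall)` points with attributes `aupr`, `prevalence`, `n_positive`,
#'   `n_pairs`, `n_excluded`.
#' @export
precision_recall <- function(d, labels, include_sentinel = FALSE) {
  dd <- .labeled_distances(d, labels, include_sentinel)
  P <- sum(dd$related)
  if (P == 0) abort("no positive pairs among usable distances",
                    class = "midtrace_error")
  ord <- order(dd$distance)
  x <- dd$distance[ord]
  y <- dd$related[ord]
  cum_tp <- cumsum(y)
  n_at <- seq_along(y)
  last <- !duplicated(x, fromLast = TRUE)  # group ties: take each threshold once
  thr <- x[last]
  tp <- cum_tp[last]
  npred <- n_at[last]
  precision <- tp / npred
  recall <- tp / P
  curve <- tibble(threshold = thr, tp = tp, fp = npred - tp,
                  precision = precision, recall = recall)
  r <- c(0, recall)
  p <- c(precision[1], precision)
  aupr <- sum(diff(r) * (head(p, -1) + p[-1]) / 2)
  structure(curve,
            aupr = aupr, prevalence = P / nrow(dd), n_positive = P,
            n_pairs = nrow(dd), n_excluded = sum(!d$status %in% c("ok", "direct")),
            class = c("pr_curve", class(curve)))
}

#' @export
glance.pr_curve <- function(x, ...) {
  tibble(aupr = attr(x, "aupr"), prevalence = attr(x, "prevalence"),
         n_positive = attr(x, "n_positive"), n_pairs = attr(x, "n_pairs"),
         n_excluded = attr(x, "n_excluded"))
}

#' AUPR of a distance table against labels
#' @inheritParams precision_recall
#' @return a single number.
#' @export
aupr <- function(d, labels, include_sentinel = FALSE) {
  attr(precision_recall(d, labels, include_sentinel), "aupr")
}

#' AUPR under increasing measurement noise
#'
#' Adds seeded Gaussian noise (clip at 0, renormalize) to a clean peak
#' table at each noise level, recomputes all pairwise distances, and
#' scores them against the labels. The mean AUPR is expected to be
#' non-increasing in the noise level; this is reported, not asserted.
#'
#' @param table a clean (noiseless) `peak_tbl`.
#' @param labels pair labels ([related_pairs()]).
#' @param noise_sds numeric vector of noise standard deviations.
#' @param replicates replicates per level (default 10).
#' @param seed RNG seed.
#' @return tibble: `noise_sd`, `replicate`, `aupr`.
#' @export
noise_robustness <- function(table, labels, noise_sds = c(0, 0.005, 0.01, 0.02),
                             replicates = 10L, seed = 1L) {
  if (replicates < 1) abort("need >= 1 replicate", class = "midtrace_error")
  set.seed(seed)
  out <- list()
  for (sd in noise_sds) {
    for (r in seq_len(replicates)) {
      tab <- if (sd > 0) perturb_mids(table, sd) else table
      out[[length(out) + 1L]] <-
        tibble(noise_sd = sd, replicate = r,
               aupr = aupr(pairwise_mid_distances(tab), labels))
    }
  }
  dplyr::bind_rows(out)
}

#' Add Gaussian measurement noise to all MIDs
#'
#' Additive Gaussian noise on each MI fraction, clipped at 0 and
#' renormalized. Uses the current RNG state; seed externally for
#' reproducibility.
#'
#' @param table a `peak_tbl`.
#' @param noise_sd standard deviation.
#' @return a perturbed `peak_tbl`.
#' @export
perturb_mids <- function(table, noise_sd) {
  table$mids <- lapply(table$mids, function(m) {
    lapply(m, function(x) {
      x <- pmax(x + rnorm(length(x), sd = noise_sd), 0)
      if (sum(x) <= 0) x <- mid_unlabeled(length(x) - 1L) else x <- x / sum(x)
      x
    })
  })
  peak_table(as_tibble(table), experiments = experiments(table))
}

#' AUPR under random metabolite dropout
#'
#' For each keep fraction and replicate, a random peak subset is drawn,
#' pairwise distances are recomputed *within the subset* (so the
#' missing-convolutant rule binds harder) and scored against the labels
#' restricted to the subset. Replicates whose subset has no positive pair
#' are skipped and counted.
#'
#' @param table a `peak_tbl`.
#' @param labels pair labels.
#' @param keep_fractions fractions of peaks to keep, each in (0, 1].
#' @param replicates replicates per fraction.
#' @param seed RNG seed.
#' @return tibble: `keep_fraction`, `replicate`, `n_peaks`, `aupr`
#'   (`NA` for skipped replicates).
#' @export
dropout_robustness <- function(table, labels, keep_fractions = c(1, 0.8, 0.5),
                               replicates = 10L, seed = 1L) {
  if (any(keep_fractions <= 0 | keep_fractions > 1)) {
    abort("keep fractions must lie in (0, 1]", class = "midtrace_error")
  }
  set.seed(seed)
  out <- list()
  for (kf in keep_fractions) {
    for (r in seq_len(replicates)) {
      n_keep <- max(2L, round(kf * nrow(table)))
      ids <- sort(sample(table$peak_id, n_keep))
      sub <- subset_peaks(table, peak_ids = ids)
      d <- pairwise_mid_distances(sub)
      val <- tryCatch(aupr(d, labels), midtrace_error = function(e) NA_real_)
      out[[length(out) + 1L]] <- tibble(keep_fraction = kf, replicate = r,
                                        n_peaks = n_keep, aupr = val)
    }
  }
  dplyr::bind_rows(out)
}

#' Discoverability of metabolites by neighbor search
#'
#' A metabolite is *discoverable* when at least `min_fraction` of its
#' truly related partners appear among its `k` nearest neighbors by MID
#' distance. Metabolites with no true partner are excluded from the
#' denominator.
#'
#' @param d a `mid_dist` tibble.
#' @param labels pair labels.
#' @param k neighborhood size (default 20).
#' @param min_fraction fraction of partners that must be recovered
#'   (default 0.5).
#' @return a list: `per_metabolite` tibble (`peak_id`, `n_partners`,
#'   `n_recovered`, `discoverable`) and `fraction_discoverable`.
#' @export
discoverability <- function(d, labels, k = 20L, min_fraction = 0.5) {
  if (k < 1) abort("k must be >= 1", class = "midtrace_error")
  pos <- labels[labels$related, , drop = FALSE]
  ids <- attr(d, "peak_ids") %||% unique(c(d$peak_a, d$peak_b))
  partners <- split(c(pos$peak_b, pos$peak_a), c(pos$peak_a, pos$peak_b))
  rows <- purrr::map_dfr(ids, function(id) {
    p <- partners[[id]]
    if (is.null(p) || length(p) == 0) return(NULL)
    nn <- nearest_neighbors(d, id, k)$peak_id
    rec <- sum(p %in% nn)
    tibble(peak_id = id, n_partners = length(p), n_recovered = rec,
           discoverable = rec >= min_fraction * length(p))
  })
  list(per_metabolite = rows,
       fraction_discoverable = mean(rows$discoverable))
}

#' Neighbor ranks of true related partners
#'
#' For every metabolite with at least one truly related partner, the
#' ranks of those partners in its distance-sorted neighbor list, with a
#' seeded random-ranking baseline for comparison.
#'
#' @param d a `mid_dist` tibble.
#' @param labels pair labels ([related_pairs()]).
#' @param seed seed for the random baseline.
#' @return a list: `ranks` (tibble `peak_id`, `partner`, `rank`,
#'   `random_rank`), `median_rank` and `median_random_rank`.
#' @export
rank_report <- function(d, labels, seed = 1L) {
  pos <- labels[labels$related, , drop = FALSE]
  ids <- attr(d, "peak_ids") %||% unique(c(d$peak_a, d$peak_b))
  partners <- split(c(pos$peak_b, pos$peak_a), c(pos$peak_a, pos$peak_b))
  set.seed(seed)
  rows <- purrr::map_dfr(ids, function(id) {
    p <- partners[[id]]
    if (is.null(p) || length(p) == 0) return(NULL)
    nn <- nearest_neighbors(d, id, k = length(ids))
    shuffled <- sample(nn$peak_id)
    tibble(peak_id = id, partner = sort(p),
           rank = nn$rank[match(sort(p), nn$peak_id)],
           random_rank = match(sort(p), shuffled))
  })
  list(ranks = rows,
       median_rank = stats::median(rows$rank, na.rm = TRUE),
       median_random_rank = stats::median(rows$random_rank, na.rm = TRUE))
}

#' Greedy tracer-subset selection
#'
#' Starts from the single experiment with the best AUPR and repeatedly
#' adds the experiment that maximizes the AUPR of distances recomputed
#' from scratch on the growing experiment subset; ties broken by
#' experiment name.
#'
#' @param table a `peak_tbl` with at least two experiments.
#' @param labels pair labels.
#' @return tibble: `step`, `experiment` (added at this step),
#'   `cumulative_aupr`.
#' @export
greedy_tracer_selection <- function(table, labels) {
  exps <- experiments(table)
  if (length(exps) < 2) abort("need at least two experiments",
                              class = "midtrace_error")
  chosen <- character()
  out <- list()
  while (length(chosen) < length(exps)) {
    cand <- sort(setdiff(exps, chosen))
    scores <- vapply(cand, function(e) {
      aupr(pairwise_mid_distances(table, use_experiments = c(chosen, e)), labels)
    }, numeric(1))
    best <- cand[which.max(scores)]  # which.max takes the first (lowest name) tie
    chosen <- c(chosen, best)
    out[[length(out) + 1L]] <- tibble(step = length(chosen), experiment = best,
                                      cumulative_aupr = max(scores))
  }
  dplyr::bind_rows(out)
}
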