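#' Peak and isotopomer filters
#'
#' Two filters turn raw MID tables into analysis-ready ones, applied in a
#' fixed order: (1) the *enrichment filter* removes peaks that never reach
#' a minimum 13C enrichment in any labeled experiment (unlabeled
#' contaminants and medium components); (2) the *false-isotopomer filter*
#' zeroes mass isotopomers that are implausibly high across many
#' experiments, which indicates a colliding foreign peak rather than real
#' labeling. Both decisions are made on natural-abundance-corrected MIDs;
#' the zeroing is applied to the stored uncorrected fractions (the data
#' distances are computed on), followed by renormalization.
#'
#' @name filters
NULL

new_filter_report <- function(stage, n_in, n_out, removed = NULL, zeroed = NULL) {
  structure(list(
    stages = tibble(stage = stage, n_in = n_in, n_out = n_out),
    removed = removed %||% tibble(peak_id = character(), reason = character()),
    zeroed = zeroed %||% tibble(peak_id = character(), mi = integer())
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("%s: %d -> %d peaks\n", x$stages$stage[i], x$stages$n_in[i],
                x$stages$n_out[i]))
  }
  if (nrow(x$zeroed) > 0) cat(sprintf("%d (peak, MI) entries zeroed\n",
                                      nrow(x$zeroed)))
  invisible(x)
}

combine_reports <- function(a, b) {
  structure(list(stages = dplyr::bind_rows(a$stages, b$stages),
                 removed = dplyr::bind_rows(a$removed, b$removed),
                 zeroed = dplyr::bind_rows(a$zeroed, b$zeroed)),
            class = "filter_report")
}

#' Write a filter report as JSON
#' @param report a `filter_report`.
#' @param path file path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), as.data.frame), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Enrichment filter
#'
#' Retains peaks reaching at least `threshold` 13C enrichment (computed on
#' natural-abundance-corrected MIDs) in at least one labeled experiment;
#' the boundary is inclusive. Unlabeled-control experiments are excluded
#' from the maximum. Peaks with no MID in any labeled experiment are
#' removed and logged distinctly.
#'
#' @param table a `peak_tbl` (uncorrected).
#' @param threshold minimum enrichment (default 0.10).
#' @param unlabeled_experiments experiment ids to treat as unlabeled
#'   controls (default none).
#' @param p13 natural 13C abundance used for the correction.
#' @return a list with elements `table` (filtered `peak_tbl`) and
#'   `report` (a `filter_report`).
#' @export
enrichment_filter <- function(table, threshold = 0.10,
                              unlabeled_experiments = character(),
                              p13 = 0.0107) {
  labeled <- setdiff(experiments(table), unlabeled_experiments)
  keep <- logical(nrow(table))
  reason <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    m <- table$mids[[i]][names(table$mids[[i]]) %in% labeled]
    if (length(m) == 0) { reason[i] <- "no MID in any labeled experiment"; next }
    enr <- vapply(m, function(x) {
      mid_enrichment(as.numeric(correct_natural_abundance(x, p13)))
    }, numeric(1))
    if (max(enr) >= threshold) keep[i] <- TRUE
    else reason[i] <- sprintf("max enrichment %.4f < %.4f", max(enr), threshold)
  }
  removed <- tibble(peak_id = table$peak_id[!keep], reason = reason[!keep])
  out <- subset_peaks(table, peak_ids = table$peak_id[keep])
  list(table = out,
       report = new_filter_report("enrichment_filter", nrow(table), nrow(out),
                                  removed = removed))
}

#' False-isotopomer filter
#'
#' For each peak and each mass isotopomer index `i >= 1`, if the
#' natural-abundance-corrected fraction exceeds `mi_threshold` in strictly
#' more than `experiment_count` experiments, that isotopomer is zeroed in
#' all experiments (on the stored uncorrected fractions) and the MIDs
#' renormalized. The base isotopomer M+0 is never zeroed. The rule is
#' applied to a fixed point within one call, so the filter is idempotent.
#' By default all experiments present (including any unlabeled controls)
#' enter the count; restrict with `count_experiments`.
#'
#' @param table a `peak_tbl` (uncorrected).
#' @param mi_threshold corrected-fraction threshold (default 0.03,
#'   strict `>`).
#' @param experiment_count count threshold (default 10, strict `>`).
#' @param count_experiments experiments whose values enter the count
#'   (default: all).
#' @param p13 natural 13C abundance.
#' @return list of `table` and `report`; the report's `zeroed` tibble
#'   records each zeroed (peak, MI index).
#' @export
false_isotopomer_filter <- function(table, mi_threshold = 0.03,
                                    experiment_count = 10L,
                                    count_experiments = NULL,
                                    p13 = 0.0107) {
  counted <- count_experiments %||% experiments(table)
  zeroed <- list()
  dropped <- list()
  for (i in seq_len(nrow(table))) {
    n <- table$n_carbons[i]
    if (n < 1L) next
    repeat {
      m <- table$mids[[i]]
      if (length(m) == 0) break
      corr <- lapply(m, function(x) as.numeric(correct_natural_abundance(x, p13)))
      hit <- integer(0)
      for (mi in seq_len(n)) {
        cnt <- sum(vapply(corr[names(corr) %in% counted],
                          function(x) x[mi + 1L] > mi_threshold, logical(1)))
        if (cnt > experiment_count) hit <- c(hit, mi)
      }
      already <- vapply(hit, function(mi) {
        all(vapply(m, function(x) x[mi + 1L] == 0, logical(1)))
      }, logical(1))
      hit <- hit[!already]
      if (length(hit) == 0) break
      zeroed[[length(zeroed) + 1L]] <- tibble(peak_id = table$peak_id[i], mi = hit)
      for (e in names(m)) {
        x <- m[[e]]
        x[hit + 1L] <- 0
        if (sum(x) <= 0) {
          dropped[[length(dropped) + 1L]] <-
            tibble(peak_id = table$peak_id[i],
                   reason = sprintf("experiment %s emptied by MI zeroing", e))
          m[[e]] <- NULL
        } else m[[e]] <- x / sum(x)
      }
      table$mids[[i]] <- m
    }
  }
  out <- peak_table(as_tibble(table), experiments = experiments(table))
  rep <- new_filter_report("false_isotopomer_filter", nrow(table), nrow(out),
                           removed = dplyr::bind_rows(dropped),
                           zeroed = dplyr::bind_rows(zeroed))
  list(table = out, report = rep)
}

#' Standard preprocessing pipeline
#'
#' Applies the enrichment filter then the false-isotopomer filter (fixed
#' order) and merges the reports.
#'
#' @inheritParams enrichment_filter
#' @inheritParams false_isotopomer_filter
#' @return list of `table` and `report`.
#' @export
preprocess_peaks <- function(table, threshold = 0.10,
                             unlabeled_experiments = character(),
                             mi_threshold = 0.03, experiment_count = 10L,
                             count_experiments = NULL, p13 = 0.0107) {
  s1 <- enrichment_filter(table, threshold = threshold,
                          unlabeled_experiments = unlabeled_experiments,
                          p13 = p13)
  s2 <- false_isotopomer_filter(s1$table, mi_threshold = mi_threshold,
                                experiment_count = experiment_count,
                                count_experiments = count_experiments,
                                p13 = p13)
  list(table = s2$table, report = combine_reports(s1$report, s2$report))
}

# Minimal union-find for single-linkage grouping.
.uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

#' Group coeluting artefact peaks
#'
#' In-source fragments and adducts coelute with their parent ion and show
#' the same labeling pattern. Peaks within `rt_tolerance` seconds of each
#' other *and* with multi-experiment MID distance below `d_cutoff` are
#' grouped by single linkage; coeluting peaks with dissimilar MIDs remain
#' separate (distinct labeling rules out a shared source). Each group
#' reports a representative: largest carbon count, then lowest peak id.
#'
#' @param table a `peak_tbl` with retention times (`rt_seconds`).
#' @param rt_tolerance coelution window in seconds (default 5).
#' @param d_cutoff MID-distance cutoff for "same labeling" (default 0.3).
#' @param distances optional precomputed `mid_dist` for `table`.
#' @return a list: `groups` (tibble `peak_id`, `group`, `representative`)
#'   and `excluded` (peaks without retention time).
#' @export
group_coeluting_artefacts <- function(table, rt_tolerance = 5, d_cutoff = 0.3,
                                      distances = NULL) {
  if (!"rt_seconds" %in% names(table)) {
    abort("table has no rt_seconds column", class = "midtrace_error")
  }
  has_rt <- !is.na(table$rt_seconds)
  excluded <- tibble(peak_id = table$peak_id[!has_rt],
                     reason = "missing retention time")
  sub <- subset_peaks(table, peak_ids = table$peak_id[has_rt])
  if (is.null(distances)) distances <- pairwise_mid_distances(sub)
  ids <- sub$peak_id
  parent <- seq_along(ids)
  rt <- setNames(sub$rt_seconds, ids)
  ok <- distances$status %in% c("ok", "direct") &
    !is.na(distances$distance) & distances$distance < d_cutoff
  for (r in which(ok)) {
    a <- match(distances$peak_a[r], ids); b <- match(distances$peak_b[r], ids)
    if (is.na(a) || is.na(b)) next
    if (abs(rt[a] - rt[b]) <= rt_tolerance) {
      ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
      parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_along(ids), function(i) .uf_find(parent, i), integer(1))
  groups <- tibble(peak_id = ids, n_carbons = sub$n_carbons, root = root) |>
    dplyr::group_by(.data$root) |>
    dplyr::mutate(representative = .data$peak_id[order(-.data$n_carbons,
                                                       .data$peak_id)][1]) |>
    dplyr::ungroup()
  groups$group <- match(groups$root, unique(groups$root))
  list(groups = groups[, c("peak_id", "group", "representative")],
       excluded = excluded)
}
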