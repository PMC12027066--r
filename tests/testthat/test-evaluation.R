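mk_labeled_dist <- function(distance, related, ids = NULL) {
  n <- length(distance)
  ids <- ids %||% sprintf("m%02d", seq_len(n + 1))
  d <- tibble::tibble(peak_a = ids[1], peak_b = ids[-1],
                      distance = distance, best_convolutant = "direct",
                      n_experiments = 1L, status = "direct")
  labels <- tibble::tibble(peak_a = d$peak_a, peak_b = d$peak_b,
                           related = related)
  list(d = structure(d, peak_ids = ids,
                     class = c("mid_dist", class(d))),
       labels = labels)
}

test_that("a perfect ranking has AUPR 1 and a curve reaching (1, 1)", {
  x <- mk_labeled_dist(distance = c(0.1, 0.2, 0.3, 1, 2, 3),
                       related = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  pr <- precision_recall(x$d, x$labels)
  expect_equal(attr(pr, "aupr"), 1)
  expect_equal(max(pr$recall), 1)
  expect_true(all(pr$precision[pr$recall < 1] == 1))
})

test_that("the curve matches hand-computed confusion counts", {
  x <- mk_labeled_dist(distance = c(0.1, 0.2, 0.3, 0.4),
                       related = c(TRUE, FALSE, TRUE, FALSE))
  pr <- precision_recall(x$d, x$labels)
  expect_equal(pr$precision, c(1, 1/2, 2/3, 1/2))
  expect_equal(pr$recall, c(0.5, 0.5, 1, 1))
  o <- oracle_pr(x$d$distance, x$labels$related)
  expect_equal(attr(pr, "aupr"), o$aupr)
})

test_that("tied distances are swept as one threshold", {
  x <- mk_labeled_dist(distance = c(0.1, 0.1, 0.2, 0.2),
                       related = c(TRUE, FALSE, TRUE, FALSE))
  pr <- precision_recall(x$d, x$labels)
  expect_equal(pr$threshold, c(0.1, 0.2))
  expect_equal(pr$precision, c(0.5, 0.5))
  o <- oracle_pr(x$d$distance, x$labels$related)
  expect_equal(attr(pr, "aupr"), o$aupr)
})

test_that("random rankings score near prevalence and match the oracle", {
  set.seed(17)
  n <- 200
  related <- runif(n) < 0.2
  prev <- mean(related)
  auprs <- replicate(100, {
    x <- mk_labeled_dist(distance = runif(n), related = related)
    a <- aupr(x$d, x$labels)
    o <- oracle_pr(x$d$distance, x$labels$related)$aupr
    expect_equal(a, o)
    a
  })
  se <- sd(auprs) / sqrt(length(auprs))
  expect_lt(abs(mean(auprs) - prev), 3 * se + 0.02)
})

test_that("sentinel pairs are excluded from the sweep unless requested", {
  x <- mk_labeled_dist(distance = c(0.1, 0.5, 0.5),
                       related = c(TRUE, FALSE, TRUE))
  x$d$status[2:3] <- "missing_convolutant"
  pr <- precision_recall(x$d, x$labels)
  expect_equal(attr(pr, "n_pairs"), 1L)
  expect_equal(attr(pr, "n_excluded"), 2L)
  pr2 <- precision_recall(x$d, x$labels, include_sentinel = TRUE)
  expect_equal(attr(pr2, "n_pairs"), 3L)
  expect_error(precision_recall(x$d[2, ], x$labels[2, ]),
               class = "midtrace_error")
})

test_that("discoverability follows the top-k rule with exact fractions", {
  # build a table where m1 has partners at controlled ranks
  set.seed(23)
  fx <- eval_fixture()
  d <- pairwise_mid_distances(fx$table)
  disc <- discoverability(d, fx$labels, k = 20)
  # brute-force check of every flag
  pos <- fx$labels[fx$labels$related, ]
  for (r in seq_len(nrow(disc$per_metabolite))) {
    id <- disc$per_metabolite$peak_id[r]
    partners <- c(pos$peak_b[pos$peak_a == id], pos$peak_a[pos$peak_b == id])
    nn <- nearest_neighbors(d, id, 20)$peak_id
    expect_equal(disc$per_metabolite$discoverable[r],
                 sum(partners %in% nn) >= 0.5 * length(partners), info = id)
  }
  # a metabolite recovering 1 of 4 partners in top k is not discoverable
  x <- mk_labeled_dist(distance = c(1, 2, 3, 4, 5),
                       related = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  disc2 <- discoverability(x$d, x$labels, k = 1)
  expect_false(disc2$per_metabolite$discoverable[
    disc2$per_metabolite$peak_id == x$d$peak_a[1]])
})

test_that("noise robustness is reproducible and exact at zero noise", {
  fx <- eval_fixture()
  sub <- subset_peaks(fx$table,
                      peak_ids = c("S1", "A1", "A2", "A3", "S2", "B1", "B2"))
  nr1 <- noise_robustness(sub, fx$labels, noise_sds = c(0, 0.02),
                          replicates = 3, seed = 5)
  nr2 <- noise_robustness(sub, fx$labels, noise_sds = c(0, 0.02),
                          replicates = 3, seed = 5)
  expect_identical(nr1, nr2)
  zero <- nr1$aupr[nr1$noise_sd == 0]
  expect_true(all(zero == zero[1]))
})

test_that("dropout keeps the full-data AUPR at keep = 1 and is reproducible", {
  fx <- eval_fixture()
  full <- aupr(pairwise_mid_distances(fx$table), fx$labels)
  dr <- dropout_robustness(fx$table, fx$labels, keep_fractions = c(1, 0.6),
                           replicates = 2, seed = 3)
  expect_true(all(dr$aupr[dr$keep_fraction == 1] == full))
  dr2 <- dropout_robustness(fx$table, fx$labels, keep_fractions = c(1, 0.6),
                            replicates = 2, seed = 3)
  expect_identical(dr, dr2)
})

test_that("greedy tracer selection matches exhaustive search on a 3-tracer toy", {
  fx <- eval_fixture()
  tab <- subset_peaks(fx$table, keep_experiments = c("S1", "S2", "S3"))
  greedy <- greedy_tracer_selection(tab, fx$labels)
  expect_equal(nrow(greedy), 3L)
  # exhaustive first step
  singles <- vapply(c("S1", "S2", "S3"), function(e) {
    aupr(pairwise_mid_distances(tab, use_experiments = e), fx$labels)
  }, numeric(1))
  expect_equal(greedy$experiment[1], names(singles)[which.max(singles)])
  expect_equal(greedy$cumulative_aupr[1], max(singles))
  # exhaustive second step given the first
  rest <- setdiff(c("S1", "S2", "S3"), greedy$experiment[1])
  pairs <- vapply(rest, function(e) {
    aupr(pairwise_mid_distances(
      tab, use_experiments = c(greedy$experiment[1], e)), fx$labels)
  }, numeric(1))
  expect_equal(greedy$experiment[2], names(pairs)[which.max(pairs)])
  # endpoint identity: all experiments = full-table AUPR
  expect_equal(greedy$cumulative_aupr[3],
               aupr(pairwise_mid_distances(tab), fx$labels))
})

test_that("rank report places true partners near the top of neighbor lists", {
  fx <- eval_fixture()
  d <- pairwise_mid_distances(fx$table)
  rr <- rank_report(d, fx$labels, seed = 2)
  # brute check for one metabolite: ranks match the sorted neighbor list
  nn <- nearest_neighbors(d, "A2", k = nrow(fx$table))
  pos <- fx$labels[fx$labels$related, ]
  partners <- sort(c(pos$peak_b[pos$peak_a == "A2"],
                     pos$peak_a[pos$peak_b == "A2"]))
  sub <- rr$ranks[rr$ranks$peak_id == "A2", ]
  expect_equal(sub$partner, partners)
  expect_equal(sub$rank, nn$rank[match(partners, nn$peak_id)])
  # true partners rank far better than the random baseline
  expect_lt(rr$median_rank, rr$median_random_rank)
  expect_identical(rank_report(d, fx$labels, seed = 2)$ranks, rr$ranks)
})

test_that("duplicated tracers add nothing to the greedy curve", {
  fx <- eval_fixture()
  tab1 <- subset_peaks(fx$table, keep_experiments = "S1")
  peaks <- tibble::as_tibble(tab1)
  peaks$mids <- lapply(peaks$mids, function(m) {
    out <- list()
    if (!is.null(m$S1)) out <- list(S1 = m$S1, S1copy = m$S1)
    out
  })
  tab2 <- peak_table(peaks, experiments = c("S1", "S1copy"))
  greedy <- greedy_tracer_selection(tab2, fx$labels)
  expect_equal(greedy$cumulative_aupr[2], greedy$cumulative_aupr[1])
})
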