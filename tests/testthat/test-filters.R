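# p13 = 0 makes corrected == raw fractions, so filter boundaries can be
# probed directly.

mk_table <- function(rows, exps) {
  peak_table(dplyr::bind_rows(rows), experiments = exps)
}

test_that("enrichment filter keeps the inclusive boundary and drops unlabeled peaks", {
  exps <- c("glc", "gln", "control")
  rows <- list(
    # enrichment exactly 0.10 in one labeled experiment -> retained
    tibble::tibble(peak_id = "boundary", n_carbons = 1L,
                   mids = list(list(glc = c(0.90, 0.10), gln = c(1, 0)))),
    # just below -> removed
    tibble::tibble(peak_id = "below", n_carbons = 1L,
                   mids = list(list(glc = c(0.901, 0.099)))),
    # labeled only in the control -> removed (control excluded from max)
    tibble::tibble(peak_id = "ctl_only", n_carbons = 1L,
                   mids = list(list(control = c(0.5, 0.5)))),
    # fully unlabeled everywhere -> removed
    tibble::tibble(peak_id = "unlabeled", n_carbons = 2L,
                   mids = list(list(glc = c(1, 0, 0), gln = c(1, 0, 0)))))
  res <- enrichment_filter(mk_table(rows, exps), threshold = 0.10,
                           unlabeled_experiments = "control", p13 = 0)
  expect_equal(res$table$peak_id, "boundary")
  expect_equal(res$report$stages$n_in, 4L)
  expect_equal(res$report$stages$n_out, 1L)
  expect_match(res$report$removed$reason[res$report$removed$peak_id == "ctl_only"],
               "no MID in any labeled experiment")
})

test_that("enrichment uses corrected MIDs", {
  # raw enrichment just above threshold purely from natural 13C
  p13 <- 0.05
  meas <- apply_natural_abundance(c(1, 0, 0, 0), p13)  # ~0.05 enrichment raw
  tab <- mk_table(list(tibble::tibble(peak_id = "nat", n_carbons = 3L,
                                      mids = list(list(glc = meas)))), "glc")
  res <- enrichment_filter(tab, threshold = 0.04, p13 = p13)
  expect_equal(nrow(res$table), 0L)  # corrected enrichment is 0
})

test_that("false-isotopomer filter zeroes strictly above both thresholds", {
  n_exp <- 21L
  exps <- sprintf("e%02d", seq_len(n_exp))
  mk_peak <- function(id, hot_value, n_hot) {
    mids <- setNames(lapply(seq_len(n_exp), function(i) {
      m1 <- if (i <= n_hot) hot_value else 0.001
      mid_normalize(c(1 - m1 - 0.001, m1, 0.001))
    }), exps)
    tibble::tibble(peak_id = id, n_carbons = 2L, mids = list(mids))
  }
  tab <- mk_table(list(mk_peak("zeroed", 0.05, 12L),   # > 0.03 in 12 > 10 exps
                       mk_peak("kept10", 0.05, 10L),   # exactly 10 -> kept
                       mk_peak("low", 0.02, 21L)), exps)  # below 0.03 -> kept
  res <- false_isotopomer_filter(tab, mi_threshold = 0.03,
                                 experiment_count = 10L, p13 = 0)
  z <- res$report$zeroed
  expect_true(all(z$peak_id == "zeroed"))
  expect_equal(sort(unique(z$mi)), 1L)
  m <- get_mid(res$table, "zeroed", "e01")
  expect_equal(m[2], 0)
  expect_equal(sum(m), 1)
  expect_equal(get_mid(res$table, "kept10", "e01"),
               get_mid(tab, "kept10", "e01"))
  expect_equal(get_mid(res$table, "low", "e01"), get_mid(tab, "low", "e01"))
  # M+0 is never zeroed even when high everywhere
  expect_false(any(z$mi == 0))
})

test_that("both filters are idempotent", {
  tab <- random_peak_table(10, n_exps = 12, sizes = 2:3, seed = 13)
  r1 <- enrichment_filter(tab, p13 = 0)
  r2 <- enrichment_filter(r1$table, p13 = 0)
  expect_equal(tibble::as_tibble(r2$table), tibble::as_tibble(r1$table))
  f1 <- false_isotopomer_filter(tab, p13 = 0)
  f2 <- false_isotopomer_filter(f1$table, p13 = 0)
  expect_equal(tibble::as_tibble(f2$table), tibble::as_tibble(f1$table))
  expect_equal(nrow(f2$report$zeroed), 0L)
})

test_that("the pipeline applies enrichment then false-isotopomer filtering", {
  tab <- random_peak_table(8, n_exps = 12, sizes = 2:3, seed = 14)
  res <- preprocess_peaks(tab, p13 = 0)
  expect_equal(res$report$stages$stage,
               c("enrichment_filter", "false_isotopomer_filter"))
  expect_equal(res$report$stages$n_in[2], res$report$stages$n_out[1])
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(res$report, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "\n")))
})

test_that("coelution grouping joins similar MIDs and separates distinct ones", {
  exps <- c("e1", "e2")
  m_a <- list(e1 = c(0.5, 0.5), e2 = c(0.2, 0.8))
  m_orth <- list(e1 = c(1, 0), e2 = c(1, 0))
  rows <- list(
    tibble::tibble(peak_id = "parent", n_carbons = 1L, mids = list(m_a),
                   rt_seconds = 100),
    tibble::tibble(peak_id = "fragment", n_carbons = 1L, mids = list(m_a),
                   rt_seconds = 100),
    tibble::tibble(peak_id = "distinct", n_carbons = 1L, mids = list(m_orth),
                   rt_seconds = 100),
    tibble::tibble(peak_id = "far", n_carbons = 1L, mids = list(m_a),
                   rt_seconds = 300),
    tibble::tibble(peak_id = "no_rt", n_carbons = 1L, mids = list(m_a),
                   rt_seconds = NA_real_))
  tab <- peak_table(dplyr::bind_rows(rows), experiments = exps)
  res <- group_coeluting_artefacts(tab, rt_tolerance = 5, d_cutoff = 0.3)
  g <- setNames(res$groups$group, res$groups$peak_id)
  expect_equal(g[["parent"]], g[["fragment"]])
  expect_false(g[["parent"]] == g[["distinct"]])
  expect_false(g[["parent"]] == g[["far"]])
  expect_equal(res$excluded$peak_id, "no_rt")
  rep_of <- setNames(res$groups$representative, res$groups$peak_id)
  expect_equal(rep_of[["parent"]], "fragment")  # tie on carbons -> lowest id
})

test_that("grouping equals a brute-force single-linkage clustering", {
  tab <- random_peak_table(12, n_exps = 2, sizes = 2, seed = 15)
  tab$rt_seconds <- c(rep(100, 4), rep(150, 4), rep(400, 4))
  tab <- peak_table(tibble::as_tibble(tab), experiments = experiments(tab))
  d <- pairwise_mid_distances(tab)
  res <- group_coeluting_artefacts(tab, rt_tolerance = 60, d_cutoff = 0.4,
                                   distances = d)
  # brute force: adjacency + transitive closure
  ids <- tab$peak_id
  adj <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  M <- dist_matrix(d)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i != j && !is.na(M[i, j]) && M[i, j] < 0.4 &&
        abs(tab$rt_seconds[i] - tab$rt_seconds[j]) <= 60) adj[i, j] <- TRUE
  }
  diag(adj) <- TRUE
  for (k in seq_along(ids)) adj <- adj | (adj %*% adj > 0)
  comp <- apply(adj, 1, function(r) min(which(r)))
  expected_groups <- as.integer(factor(comp, levels = unique(comp)))
  got <- res$groups$group[match(ids, res$groups$peak_id)]
  expect_equal(as.integer(factor(got, levels = unique(got))), expected_groups)
})
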