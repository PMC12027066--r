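# Shared in-code fixtures for the test suite.

# Random peak table: random-MID peaks across experiments, with optional
# per-(peak, experiment) dropout.
random_peak_table <- function(n_peaks, n_exps = 3L, sizes = 1:4,
                              missing_prob = 0, seed = 1L) {
  set.seed(seed)
  exps <- sprintf("exp%d", seq_len(n_exps))
  peaks <- purrr::map_dfr(seq_len(n_peaks), function(i) {
    n <- sample(sizes, 1L)
    mids <- list()
    for (e in exps) {
      if (runif(1) < missing_prob) next
      mids[[e]] <- mid_normalize(runif(n + 1L))
    }
    tibble::tibble(peak_id = sprintf("p%02d", i), n_carbons = n,
                   mids = list(mids))
  })
  peak_table(peaks, experiments = exps)
}

# Table with a planted exact-convolution triple: B = conv(A, C) in every
# experiment, plus unrelated filler peaks.
planted_triple_table <- function(n_exps = 3L, n_filler = 4L, seed = 2L) {
  set.seed(seed)
  exps <- sprintf("exp%d", seq_len(n_exps))
  make_mids <- function(n) {
    setNames(lapply(exps, function(e) mid_normalize(runif(n + 1L))), exps)
  }
  a <- make_mids(2L)
  c_ <- make_mids(1L)
  b <- setNames(lapply(exps, function(e) mid_convolve(a[[e]], c_[[e]])), exps)
  rows <- list(
    tibble::tibble(peak_id = "A", n_carbons = 2L, mids = list(a)),
    tibble::tibble(peak_id = "B", n_carbons = 3L, mids = list(b)),
    tibble::tibble(peak_id = "C", n_carbons = 1L, mids = list(c_)))
  for (i in seq_len(n_filler)) {
    n <- sample(1:3, 1L)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(peak_id = sprintf("f%d", i), n_carbons = n,
                     mids = list(make_mids(n)))
  }
  peak_table(dplyr::bind_rows(rows), experiments = exps)
}

# Small cached evaluation fixture shared across expensive tests.
eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_peak_table("eval_panel", seed = 1L)
    cache
  }
})
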