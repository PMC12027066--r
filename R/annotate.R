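#' Candidate-compound annotation by m/z, adducts and MID neighbors
#'
#' Unknown peaks are matched against a candidate-compound table (id,
#' name, formula, monoisotopic neutral mass, optional structure-class
#' tags) by comparing the observed m/z with theoretical adduct m/z values
#' within a ppm tolerance. Candidates are then screened for consistency
#' with the observed 13C labeling (a peak showing M+6 labeling cannot be
#' a 5-carbon compound) and scored by structure-tag overlap with the
#' peak's nearest previously known neighbors in MID-distance space.
#'
#' @name annotate
NULL

# Monoisotopic atomic masses (Da) of elements accepted in formulas.
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Se = 79.9165213, Fe = 55.9349375,
  Mg = 23.9850417, Ca = 39.96259098
)

PROTON_MASS <- 1.007276466

#' Default adduct set
#'
#' The five adducts considered by default: M+H, M-H, M+NH4, M+H-H2O and
#' M-H-H2O (singly charged). `delta` is the shift added to the neutral
#' monoisotopic mass to obtain the ion m/z.
#'
#' @return tibble: `adduct`, `delta` (Da), `polarity` (`"+"`/`"-"`).
#' @export
default_adducts <- function() {
  nh4 <- 18.033823
  h2o <- 18.010565
  tibble(adduct = c("M+H", "M-H", "M+NH4", "M+H-H2O", "M-H-H2O"),
         delta = c(PROTON_MASS, -PROTON_MASS, nh4,
                   PROTON_MASS - h2o, -PROTON_MASS - h2o),
         polarity = c("+", "-", "+", "+", "-"))
}

#' Parse an elemental formula
#'
#' @param formula e.g. `"C6H12O6"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    abort("empty formula", class = "midtrace_error")
  }
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort(paste0("cannot parse formula: ", formula), class = "midtrace_error")
  }
  el <- sub("\\d+$", "", parts)
  cnt <- as.integer(ifelse(grepl("\\d+$", parts), sub("^[A-Za-z]+", "", parts), "1"))
  tot <- tapply(cnt, el, sum)[unique(el)]
  setNames(as.integer(tot), names(tot))
}

#' Monoisotopic neutral mass of a formula
#'
#' @inheritParams parse_formula
#' @return mass in Da.
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    abort(paste0("unknown elements: ", paste(unknown, collapse = ", ")),
          class = "midtrace_error")
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

formula_carbons <- function(formula) {
  counts <- parse_formula(formula)
  as.integer(counts["C"] %||% 0L)
}

#' Read / write a candidate-compound table
#'
#' TSV columns: `compound_id`, `name`, `formula`, `neutral_mass` (Da;
#' computed from the formula when absent — an explicit mass wins), `tags`
#' (structure-class tags separated by `;`). A synthetic table emulating a
#' compound-database extract can be generated with
#' [make_compound_table()].
#'
#' @param path file path.
#' @return a tibble with a `tags` list-column and validated
#'   `neutral_mass`.
#' @export
read_compound_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  if ("neutral_mass" %in% names(df)) df$neutral_mass <- as.numeric(df$neutral_mass)
  as_compound_table(df)
}

#' @rdname read_compound_table
#' @param compounds a data frame of compounds.
#' @export
as_compound_table <- function(compounds) {
  df <- as_tibble(compounds)
  if (!"compound_id" %in% names(df)) abort("compound_id column required",
                                           class = "midtrace_error")
  if (!"neutral_mass" %in% names(df)) df$neutral_mass <- NA_real_
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  need <- is.na(df$neutral_mass)
  df$neutral_mass[need] <- vapply(df$formula[need], formula_mass, numeric(1))
  both <- !is.na(df$formula) & !need
  bad <- both & abs(df$neutral_mass -
                      vapply(df$formula, function(f) {
                        if (is.na(f)) NA_real_ else formula_mass(f)
                      }, numeric(1))) > 1e-4
  if (any(bad, na.rm = TRUE)) {
    abort(paste0("neutral_mass inconsistent with formula for: ",
                 paste(df$compound_id[which(bad)], collapse = ", ")),
          class = "midtrace_error")
  }
  if (!"tags" %in% names(df)) df$tags <- ""
  if (!is.list(df$tags)) {
    df$tags <- lapply(df$tags, function(t) {
      if (is.na(t) || !nzchar(t)) character() else strsplit(t, ";", fixed = TRUE)[[1]]
    })
  }
  df
}

#' @rdname read_compound_table
#' @param compounds a compound table.
#' @export
write_compound_table <- function(compounds, path) {
  df <- compounds
  df$tags <- vapply(df$tags, paste, character(1), collapse = ";")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Match a peak m/z against candidate compounds
#'
#' A candidate matches when the theoretical adduct m/z (neutral mass +
#' adduct delta) is within `tolerance_ppm` of the observed m/z
#' (symmetric: `|obs - theo| / theo * 1e6 <= tolerance_ppm`) for an
#' adduct of the peak's polarity. When `n_carbons` is given, candidates
#' whose formula carbon count differs from it are excluded (the MID
#' length defines the peak's carbon count).
#'
#' @param mz observed m/z (> 0).
#' @param polarity `"+"` or `"-"`.
#' @param compounds a compound table ([as_compound_table()]).
#' @param adducts adduct tibble (default [default_adducts()]).
#' @param tolerance_ppm mass tolerance (default 10).
#' @param n_carbons peak carbon count, or `NA` to skip the check.
#' @return tibble of candidates: `compound_id`, `name`, `formula`,
#'   `adduct`, `theo_mz`, `ppm_error`, `carbon_consistent`, sorted by
#'   absolute ppm error then compound id.
#' @export
match_mz <- function(mz, polarity, compounds, adducts = default_adducts(),
                     tolerance_ppm = 10, n_carbons = NA) {
  if (!is.numeric(mz) || mz <= 0) abort("mz must be > 0", class = "midtrace_error")
  if (!polarity %in% c("+", "-")) abort("polarity must be '+' or '-'",
                                        class = "midtrace_error")
  ad <- adducts[adducts$polarity == polarity, , drop = FALSE]
  grid <- tidyr::crossing(compounds, ad)
  grid$theo_mz <- grid$neutral_mass + grid$delta
  grid$ppm_error <- (mz - grid$theo_mz) / grid$theo_mz * 1e6
  hit <- abs(grid$ppm_error) <= tolerance_ppm
  res <- grid[hit, , drop = FALSE]
  if (!is.na(n_carbons) && nrow(res) > 0) {
    nc <- vapply(res$formula, function(f) {
      if (is.na(f)) NA_integer_ else formula_carbons(f)
    }, integer(1))
    res$carbon_consistent <- !is.na(nc) & nc == n_carbons
    res <- res[res$carbon_consistent, , drop = FALSE]
  } else if (nrow(res) > 0) res$carbon_consistent <- NA
  res <- res[order(abs(res$ppm_error), res$compound_id), , drop = FALSE]
  cols <- c("compound_id", "name", "formula", "adduct", "theo_mz", "ppm_error",
            "carbon_consistent", "tags")
  res[, intersect(cols, names(res)), drop = FALSE]
}

#' Maximum observed labeled-carbon count per experiment
#'
#' The largest MI index whose natural-abundance-corrected fraction
#' exceeds `floor` in each experiment; used to reject candidates whose
#' formula cannot accommodate the observed labeling.
#'
#' @param table a `peak_tbl`.
#' @param peak_id the peak.
#' @param floor fraction floor (default 0.01).
#' @param p13 natural 13C abundance.
#' @return named integer vector over experiments with data.
#' @export
max_labeled_carbons <- function(table, peak_id, floor = 0.01, p13 = 0.0107) {
  i <- match(peak_id, table$peak_id)
  if (is.na(i)) abort(paste0("unknown peak id: ", peak_id), class = "midtrace_error")
  m <- table$mids[[i]]
  vapply(m, function(x) {
    cx <- as.numeric(correct_natural_abundance(x, p13))
    idx <- which(cx > floor) - 1L
    if (length(idx) == 0) 0L else max(idx)
  }, integer(1))
}

#' Score candidates by known-neighbor support
#'
#' Implements the neighbor-guided selection: (1) a candidate is rejected
#' outright if, in any experiment, the peak's maximum observed
#' labeled-carbon count exceeds the candidate's formula carbon count;
#' (2) surviving candidates receive a `neighbor_score`, the largest
#' structure-tag overlap between the candidate's tags and the tags of the
#' peak's `k` nearest previously known neighbors. Candidates scoring at
#' least `score_threshold` become the final call (best score, ties by
#' compound id); otherwise the peak is `"undetermined"` for human review.
#'
#' @param table a `peak_tbl` with `known` and `tags` columns.
#' @param peak_id the unknown peak.
#' @param candidates candidate tibble from [match_mz()].
#' @param d a `mid_dist` for `table`.
#' @param k number of known neighbors to consult (default 5).
#' @param score_threshold minimum tag-overlap score for a final call
#'   (default 1).
#' @param floor labeling-detection floor for the carbon-count check.
#' @param p13 natural 13C abundance.
#' @return a list: `candidates` (scored, ranked tibble with
#'   `labeling_consistent` and `neighbor_score`), `call` (compound id or
#'   `"undetermined"`), `known_neighbors`.
#' @export
neighbor_support <- function(table, peak_id, candidates, d, k = 5L,
                             score_threshold = 1, floor = 0.01, p13 = 0.0107) {
  if (!"known" %in% names(table)) abort("table has no 'known' column",
                                        class = "midtrace_error")
  maxlab <- max_labeled_carbons(table, peak_id, floor = floor, p13 = p13)
  nn <- nearest_neighbors(d, peak_id, k = nrow(table))
  known_ids <- table$peak_id[table$known %in% TRUE]
  nn_known <- head(nn[nn$peak_id %in% known_ids, , drop = FALSE], k)
  neighbor_tags <- lapply(nn_known$peak_id, function(id) {
    tg <- table$tags[[match(id, table$peak_id)]]
    tg %||% character()
  })
  cand <- candidates
  if (nrow(cand) == 0) {
    return(list(candidates = cand, call = "undetermined",
                known_neighbors = nn_known))
  }
  cand$labeling_consistent <- vapply(seq_len(nrow(cand)), function(i) {
    nc <- if (is.na(cand$formula[i])) NA_integer_ else formula_carbons(cand$formula[i])
    if (is.na(nc)) return(TRUE)
    all(maxlab <= nc)
  }, logical(1))
  scored <- lapply(seq_len(nrow(cand)), function(i) {
    ct <- if ("tags" %in% names(cand)) cand$tags[[i]] else character()
    if (length(neighbor_tags) == 0 || length(ct) == 0) {
      return(c(score = 0, rank = Inf))
    }
    ov <- vapply(neighbor_tags, function(nt) length(intersect(ct, nt)),
                 numeric(1))
    s <- max(ov)
    c(score = s, rank = if (s > 0) min(which(ov == s)) else Inf)
  })
  cand$neighbor_score <- vapply(scored, `[[`, numeric(1), "score")
  # equally scored candidates: the one backed by a nearer known neighbor wins
  cand$support_rank <- vapply(scored, `[[`, numeric(1), "rank")
  cand <- cand[cand$labeling_consistent, , drop = FALSE]
  cand <- cand[order(-cand$neighbor_score, cand$support_rank,
                     cand$compound_id), , drop = FALSE]
  call <- if (nrow(cand) > 0 && length(neighbor_tags) > 0 &&
              cand$neighbor_score[1] >= score_threshold) {
    cand$compound_id[1]
  } else "undetermined"
  list(candidates = cand, call = call, known_neighbors = nn_known)
}

#' Annotate all unknown peaks in a table
#'
#' Runs [match_mz()] and [neighbor_support()] for every peak not flagged
#' as known.
#'
#' @param table a `peak_tbl` with `mz`, `polarity`, `known`, `tags`.
#' @param compounds a compound table.
#' @param d optional precomputed `mid_dist` (computed if missing).
#' @param adducts adduct set.
#' @param tolerance_ppm mass tolerance.
#' @param k known-neighbor count.
#' @param score_threshold final-call threshold.
#' @return a tibble: `peak_id`, `n_candidates`, `call`, `best_score`.
#' @export
annotate_peaks <- function(table, compounds, d = NULL,
                           adducts = default_adducts(), tolerance_ppm = 10,
                           k = 5L, score_threshold = 1) {
  if (is.null(d)) d <- pairwise_mid_distances(table)
  unknown <- table$peak_id[!(table$known %in% TRUE)]
  purrr::map_dfr(unknown, function(id) {
    i <- match(id, table$peak_id)
    cand <- match_mz(table$mz[i], table$polarity[i], compounds,
                     adducts = adducts, tolerance_ppm = tolerance_ppm,
                     n_carbons = table$n_carbons[i])
    ns <- neighbor_support(table, id, cand, d, k = k,
                           score_threshold = score_threshold)
    tibble(peak_id = id, n_candidates = nrow(cand), call = ns$call,
           best_score = if (nrow(ns$candidates) > 0)
             ns$candidates$neighbor_score[1] else NA_real_)
  })
}
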