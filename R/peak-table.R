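#' Peak tables
#'
#' A peak table is the package's central container: a tibble with one row
#' per LCMS peak and a `mids` list-column holding, for each peak, a named
#' list mapping experiment (tracer) id to that peak's MID in the
#' experiment. A peak absent from an experiment simply has no entry in the
#' list. The ordered set of experiment ids lives in the `"experiments"`
#' attribute and is fixed for the lifetime of the table.
#'
#' Peak columns: `peak_id` (unique), `n_carbons`, and optional metadata
#' `formula`, `mz`, `rt_seconds`, `polarity` ("+"/"-"), `known` (logical
#' annotation status), `name`, `tags` (structure-class tags, a character
#' vector per peak).
#'
#' @name peak_table
NULL

peak_meta_cols <- c("formula", "mz", "rt_seconds", "polarity", "known", "name")

#' Build a peak table
#'
#' @param peaks a data frame with columns `peak_id`, `n_carbons`, a `mids`
#'   list-column (named list experiment -> MID vector), and optional
#'   metadata columns (`formula`, `mz`, `rt_seconds`, `polarity`, `known`,
#'   `name`, `tags`).
#' @param experiments ordered character vector of experiment ids; defaults
#'   to the union of experiment names found in `mids`, in order of first
#'   appearance.
#' @return a `peak_tbl` tibble.
#' @export
peak_table <- function(peaks, experiments = NULL) {
  peaks <- as_tibble(peaks)
  if (!all(c("peak_id", "n_carbons", "mids") %in% names(peaks))) {
    abort("peaks must have columns peak_id, n_carbons and a mids list-column",
          class = "midtrace_error")
  }
  peaks$peak_id <- as.character(peaks$peak_id)
  peaks$n_carbons <- as.integer(peaks$n_carbons)
  if (anyDuplicated(peaks$peak_id)) {
    abort("duplicate peak ids", class = "midtrace_error")
  }
  seen <- unique(unlist(lapply(peaks$mids, names), use.names = FALSE))
  if (is.null(experiments)) experiments <- seen else {
    experiments <- as.character(experiments)
    if (anyDuplicated(experiments)) abort("experiment ids must be unique",
                                          class = "midtrace_error")
    extra <- setdiff(seen, experiments)
    if (length(extra) > 0) {
      abort(paste0("mids reference unknown experiments: ",
                   paste(extra, collapse = ", ")), class = "midtrace_error")
    }
  }
  for (i in seq_len(nrow(peaks))) {
    m <- peaks$mids[[i]]
    if (is.null(m)) m <- list()
    for (e in names(m)) {
      if (is.null(m[[e]])) { m[[e]] <- NULL; next }
      validate_mid(m[[e]])
      if (length(m[[e]]) != peaks$n_carbons[i] + 1L) {
        abort(sprintf("peak %s: MID in experiment %s has length %d, expected %d",
                      peaks$peak_id[i], e, length(m[[e]]), peaks$n_carbons[i] + 1L),
              class = "midtrace_error")
      }
    }
    peaks$mids[[i]] <- m
  }
  structure(peaks,
            experiments = experiments,
            class = c("peak_tbl", class(peaks)))
}

#' @export
print.peak_tbl <- function(x, ...) {
  cat(sprintf("# A peak table: %d peaks x %d experiments (%s)\n",
              nrow(x), length(experiments(x)),
              paste(head(experiments(x), 5), collapse = ", ")))
  NextMethod()
}

#' Experiment ids of a peak table
#' @param table a `peak_tbl`.
#' @return character vector of experiment ids, in fixed order.
#' @export
experiments <- function(table) {
  attr(table, "experiments") %||% character()
}

#' Look up one MID
#' @param table a `peak_tbl`.
#' @param peak_id,experiment ids.
#' @return the MID vector, or `NULL` if absent.
#' @export
get_mid <- function(table, peak_id, experiment) {
  i <- match(peak_id, table$peak_id)
  if (is.na(i)) abort(paste0("unknown peak id: ", peak_id), class = "midtrace_error")
  table$mids[[i]][[experiment]]
}

#' Long (tidy) form of a peak table
#'
#' @param x a `peak_tbl`.
#' @param ... unused.
#' @return a tibble with one row per peak x experiment x mass isotopomer:
#'   `peak_id`, `experiment`, `n_carbons`, `mi` (0-based isotopomer index)
#'   and `fraction`.
#' @export
tidy.peak_tbl <- function(x, ...) {
  rows <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    m <- x$mids[[i]]
    if (length(m) == 0) return(NULL)
    purrr::map_dfr(names(m), function(e) {
      tibble(peak_id = x$peak_id[i], experiment = e,
             n_carbons = x$n_carbons[i],
             mi = seq_along(m[[e]]) - 1L, fraction = m[[e]])
    })
  })
  rows$experiment <- factor(rows$experiment, levels = experiments(x))
  rows
}

#' @export
glance.peak_tbl <- function(x, ...) {
  n_mids <- sum(lengths(x$mids))
  tibble(n_peaks = nrow(x), n_experiments = length(experiments(x)),
         n_mids = n_mids,
         completeness = n_mids / (nrow(x) * max(1L, length(experiments(x)))))
}

#' Read / write peak tables as TSV
#'
#' The on-disk format has one row per peak x experiment: columns
#' `peak_id`, `experiment`, `n_carbons`, optional metadata (`formula`,
#' `mz`, `rt_seconds`, `polarity`, `known`, `name`, `tags` with tags
#' separated by `;`), then `M0 ... Mk` fraction columns where `k` is the
#' largest carbon count in the table; the ragged tail is left empty.
#'
#' @param path file path.
#' @param experiments optional experiment ordering (default: order of
#'   first appearance in the file).
#' @return `read_mid_table()` returns a `peak_tbl`; `write_mid_table()`
#'   returns `path` invisibly.
#' @export
read_mid_table <- function(path, experiments = NULL) {
  # read everything as character and convert with base R: numeric parsing
  # is then correctly rounded, so write -> read -> write is byte-stable
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  for (cl in intersect(c("mz", "rt_seconds"), names(df))) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  if ("known" %in% names(df)) df$known <- as.logical(df$known)
  mi_cols <- grep("^M\\d+$", names(df), value = TRUE)
  for (cl in mi_cols) df[[cl]] <- as.numeric(df[[cl]])
  mi_cols <- mi_cols[order(as.integer(sub("^M", "", mi_cols)))]
  if (length(mi_cols) == 0) abort("no M0..Mn columns found", class = "midtrace_error")
  df$peak_id <- as.character(df$peak_id)
  ids <- unique(df$peak_id)
  if (is.null(experiments)) experiments <- unique(as.character(df$experiment))
  peaks <- purrr::map_dfr(ids, function(id) {
    sub <- df[df$peak_id == id, , drop = FALSE]
    n <- as.integer(sub$n_carbons[1])
    mids <- list()
    for (r in seq_len(nrow(sub))) {
      v <- as.numeric(sub[r, mi_cols[seq_len(n + 1L)]])
      mids[[as.character(sub$experiment[r])]] <- v
    }
    row <- tibble(peak_id = id, n_carbons = n, mids = list(mids))
    for (cl in peak_meta_cols) if (cl %in% names(sub)) row[[cl]] <- sub[[cl]][1]
    if ("tags" %in% names(sub)) {
      tg <- sub$tags[1]
      row$tags <- list(if (is.na(tg) || !nzchar(tg)) character() else
        strsplit(tg, ";", fixed = TRUE)[[1]])
    }
    row
  })
  peak_table(peaks, experiments = experiments)
}

#' @rdname read_mid_table
#' @param table a `peak_tbl`.
#' @export
write_mid_table <- function(table, path) {
  nmax <- max(table$n_carbons)
  mi_cols <- paste0("M", 0:nmax)
  rows <- purrr::map_dfr(seq_len(nrow(table)), function(i) {
    m <- table$mids[[i]]
    if (length(m) == 0) return(NULL)
    purrr::map_dfr(names(m), function(e) {
      v <- m[[e]]
      out <- tibble(peak_id = table$peak_id[i], experiment = e,
                    n_carbons = table$n_carbons[i])
      for (cl in peak_meta_cols) {
        if (cl %in% names(table)) out[[cl]] <- table[[cl]][i]
      }
      if ("tags" %in% names(table)) {
        out$tags <- paste(table$tags[[i]], collapse = ";")
      }
      mids_row <- setNames(as.list(rep(NA_real_, nmax + 1L)), mi_cols)
      mids_row[seq_along(v)] <- v
      dplyr::bind_cols(out, as_tibble(mids_row))
    })
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Restrict a peak table to a subset of peaks or experiments
#'
#' @param table a `peak_tbl`.
#' @param peak_ids,keep_experiments ids to keep (default: all).
#' @return a `peak_tbl`.
#' @export
subset_peaks <- function(table, peak_ids = NULL, keep_experiments = NULL) {
  if (!is.null(peak_ids)) {
    missing <- setdiff(peak_ids, table$peak_id)
    if (length(missing) > 0) {
      abort(paste0("unknown peak ids: ", paste(missing, collapse = ", ")),
            class = "midtrace_error")
    }
    table <- table[match(peak_ids, table$peak_id), , drop = FALSE]
  }
  exps <- experiments(table)
  if (!is.null(keep_experiments)) {
    exps <- exps[exps %in% keep_experiments]
    table$mids <- lapply(table$mids, function(m) m[names(m) %in% exps])
  }
  peak_table(as_tibble(table), experiments = exps)
}
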