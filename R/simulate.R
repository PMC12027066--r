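#' Labeling simulation on atom-mapped networks
#'
#' Given a network, a tracer configuration and the EMU system of the
#' target metabolites, the labeling state evolves as, for each EMU X of a
#' metabolite M with pool size p,
#' \deqn{dX/dt = \frac{1}{p}\Big(\sum_{in} v\, y_{src} - v_{out} X\Big)}
#' per mass isotopomer, where the inputs are source-EMU MIDs (convolved
#' for condensation reactions) and \eqn{v_{out}} is M's total consumption
#' flux. Substrate EMUs are fixed by the tracer. The steady state solves
#' the corresponding linear balance equations size block by size block.
#'
#' @name simulate_labeling
NULL

# Shared setup: EMU bookkeeping for a network + tracer.
.emu_context <- function(network, targets = NULL) {
  mets <- network$metabolites
  if (is.null(targets)) targets <- mets$id[!mets$is_substrate]
  sys <- decompose_emu(network, targets)
  cons <- consumption_flux(network)
  pools <- setNames(mets$pool_size, mets$id)
  ncarb <- setNames(mets$n_carbons, mets$id)
  list(sys = sys, cons = cons, pools = pools, ncarb = ncarb, targets = targets,
       mets = mets)
}

.substrate_emu_mids <- function(ctx, tracer) {
  emus <- ctx$sys$emus
  out <- list()
  for (i in which(emus$is_substrate)) {
    out[[emus$emu_id[i]]] <- substrate_emu_mid(emus$met[i], emus$atoms[[i]],
                                               ctx$ncarb[[emus$met[i]]], tracer)
  }
  out
}

#' Steady-state EMU simulation
#'
#' @param network an `atom_network`.
#' @param tracer a [tracer_config()] (or `NULL` for no labeling).
#' @param targets metabolite ids to report (default: all metabolites;
#'   substrates report their fixed tracer MIDs).
#' @return a named list mapping metabolite id to its steady-state MID.
#' @export
simulate_steady_state <- function(network, tracer = NULL, targets = NULL) {
  mets <- network$metabolites
  if (is.null(targets)) targets <- mets$id
  inner <- setdiff(targets, mets$id[mets$is_substrate])
  ctx <- .emu_context(network, if (length(inner) > 0) inner else NULL)
  X <- .substrate_emu_mids(ctx, tracer)
  emus <- ctx$sys$emus
  if (length(inner) > 0) {
    for (s in as.integer(names(ctx$sys$blocks))) {
      blk <- ctx$sys$blocks[[as.character(s)]]
      unk <- blk[!emus$is_substrate[match(blk, emus$emu_id)]]
      if (length(unk) == 0) next
      A <- matrix(0, length(unk), length(unk), dimnames = list(unk, unk))
      B <- matrix(0, length(unk), s + 1L)
      for (i in seq_along(unk)) {
        A[i, i] <- -ctx$cons[[emus$met[match(unk[i], emus$emu_id)]]]
      }
      for (er in ctx$sys$reactions) {
        if (!(er$target %in% unk)) next
        if (length(er$sources) == 1L && er$sources %in% unk) {
          A[er$target, er$sources] <- A[er$target, er$sources] + er$flux
        } else {
          y <- mid_unlabeled(0)
          for (src in er$sources) {
            if (is.null(X[[src]])) {
              abort(sprintf("EMU %s required before it is solved", src),
                    class = "midtrace_error")
            }
            y <- mid_convolve(y, X[[src]])
          }
          B[match(er$target, unk), ] <- B[match(er$target, unk), ] + er$flux * y
        }
      }
      sol <- tryCatch(solve(A, -B), error = function(e) {
        abort(sprintf("singular EMU block (size %d) involving: %s", s,
                      paste(unique(emus$met[match(unk, emus$emu_id)]),
                            collapse = ", ")),
              class = "midtrace_error")
      })
      for (i in seq_along(unk)) X[[unk[i]]] <- pmax(sol[i, ], 0)
    }
  }
  out <- list()
  for (m in targets) {
    if (mets$is_substrate[match(m, mets$id)]) {
      out[[m]] <- substrate_emu_mid(m, seq_len(ctx$ncarb[[m]]), ctx$ncarb[[m]],
                                    tracer)
    } else {
      id <- paste0(m, "#", paste(seq_len(ctx$ncarb[[m]]), collapse = "."))
      out[[m]] <- as.numeric(X[[id]])
    }
  }
  out
}

#' Isotopically nonstationary EMU simulation
#'
#' Solves the labeling dynamics on a time grid, starting from fully
#' unlabeled internal pools, with substrate EMUs held at the tracer MID.
#' All EMU sizes are integrated as one stiff ODE system (larger sizes
#' never feed back into smaller ones, so this is equivalent to solving
#' block by block).
#'
#' @inheritParams simulate_steady_state
#' @param times numeric time grid (must start at 0); default
#'   [default_time_grid()].
#' @param rtol,atol solver tolerances.
#' @return a `mid_sim` object: list with `times` and `mids`, a named list
#'   mapping metabolite id to a `length(times) x (n+1)` matrix of MID time
#'   courses.
#' @export
simulate_nonstationary <- function(network, tracer = NULL, times = NULL,
                                   targets = NULL, rtol = 1e-8, atol = 1e-10) {
  mets <- network$metabolites
  if (is.null(targets)) targets <- mets$id
  if (any(mets$pool_size <= 0)) {
    abort("zero or negative pool size", class = "midtrace_error")
  }
  if (is.null(times)) times <- default_time_grid(network)
  if (times[1] != 0) abort("time grid must start at 0", class = "midtrace_error")
  inner <- setdiff(targets, mets$id[mets$is_substrate])
  ctx <- .emu_context(network, if (length(inner) > 0) inner else NULL)
  emus <- ctx$sys$emus
  fixed <- .substrate_emu_mids(ctx, tracer)
  unk <- emus$emu_id[!emus$is_substrate]
  sizes <- emus$size[match(unk, emus$emu_id)]
  offsets <- c(0L, cumsum(sizes + 1L))
  idx <- setNames(lapply(seq_along(unk), function(i) {
    (offsets[i] + 1L):offsets[i + 1L]
  }), unk)
  met_of <- setNames(emus$met[match(unk, emus$emu_id)], unk)
  rate_out <- vapply(unk, function(u) ctx$cons[[met_of[[u]]]] /
                       ctx$pools[[met_of[[u]]]], numeric(1))
  inv_pool <- vapply(unk, function(u) 1 / ctx$pools[[met_of[[u]]]], numeric(1))
  rxns <- Filter(function(er) er$target %in% unk, ctx$sys$reactions)

  y0 <- unlist(lapply(sizes, mid_unlabeled), use.names = FALSE)
  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    for (i in seq_along(unk)) dy[idx[[i]]] <- -rate_out[i] * y[idx[[i]]]
    for (er in rxns) {
      ti <- match(er$target, unk)
      src_mid <- mid_unlabeled(0)
      for (src in er$sources) {
        v <- if (!is.null(fixed[[src]])) fixed[[src]] else y[idx[[src]]]
        src_mid <- if (length(src_mid) == 1L && length(er$sources) == 1L) v
                   else mid_convolve_raw(src_mid, v)
      }
      dy[idx[[ti]]] <- dy[idx[[ti]]] + inv_pool[ti] * er$flux * src_mid
    }
    list(dy)
  }
  sol <- if (length(unk) > 0) {
    deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)
  } else cbind(time = times)
  mids <- list()
  for (m in targets) {
    n <- ctx$ncarb[[m]]
    if (mets$is_substrate[match(m, mets$id)]) {
      row <- substrate_emu_mid(m, seq_len(n), n, tracer)
      mids[[m]] <- matrix(rep(row, each = length(times)), nrow = length(times))
    } else {
      id <- paste0(m, "#", paste(seq_len(n), collapse = "."))
      mids[[m]] <- unname(sol[, idx[[id]] + 1L, drop = FALSE])
    }
  }
  structure(list(times = times, mids = mids), class = "mid_sim")
}

# Convolution without validation (solver states transiently drift off the
# simplex within tolerance; validation there would be both slow and wrong).
mid_convolve_raw <- function(a, c_) {
  na <- length(a); nc <- length(c_)
  out <- numeric(na + nc - 1L)
  for (i in seq_len(na)) {
    j <- i:(i + nc - 1L)
    out[j] <- out[j] + a[i] * c_
  }
  out
}

#' @export
print.mid_sim <- function(x, ...) {
  cat(sprintf("# A labeling simulation: %d metabolites on %d time points (t in [%g, %g])\n",
              length(x$mids), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Long (tidy) form of a simulation
#' @param x a `mid_sim`.
#' @param ... unused.
#' @return tibble: `metabolite`, `time`, `mi`, `fraction`.
#' @export
tidy.mid_sim <- function(x, ...) {
  purrr::map_dfr(names(x$mids), function(m) {
    M <- x$mids[[m]]
    tibble(metabolite = m,
           time = rep(x$times, ncol(M)),
           mi = rep(seq_len(ncol(M)) - 1L, each = nrow(M)),
           fraction = as.vector(M))
  })
}

#' Write a simulated time course as TSV
#'
#' Long format: `metabolite`, `experiment` (optional label), `time`,
#' `M0 ... Mk` fraction columns (ragged tail empty).
#'
#' @param sim a `mid_sim`.
#' @param path file path.
#' @param experiment optional experiment label column value.
#' @export
write_simulation <- function(sim, path, experiment = NA_character_) {
  nmax <- max(vapply(sim$mids, ncol, integer(1))) - 1L
  mi_cols <- paste0("M", 0:nmax)
  rows <- purrr::map_dfr(names(sim$mids), function(m) {
    M <- sim$mids[[m]]
    out <- tibble(metabolite = m, experiment = experiment, time = sim$times)
    pad <- matrix(NA_real_, nrow(M), nmax + 1L - ncol(M))
    mi <- as.data.frame(cbind(M, pad))
    names(mi) <- mi_cols
    dplyr::bind_cols(out, mi)
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Default log-spaced time grid for a network
#'
#' Spans from 0 to well past the slowest pool's turnover so that labeling
#' reaches steady state on the grid; 200 points, log-spaced.
#'
#' @param network an `atom_network`.
#' @param n number of grid points.
#' @param horizon multiple of the slowest turnover time to cover.
#' @return numeric vector of times starting at 0.
#' @export
default_time_grid <- function(network, n = 200L, horizon = 60) {
  mets <- network$metabolites
  cons <- consumption_flux(network)
  rates <- cons[mets$id[!mets$is_substrate]] /
    mets$pool_size[!mets$is_substrate]
  rates <- rates[rates > 0]
  if (length(rates) == 0) abort("no active internal metabolites",
                                class = "midtrace_error")
  tmax <- horizon / min(rates)
  c(0, 10^seq(log10(tmax * 1e-4), log10(tmax), length.out = n - 1L))
}

#' Detect the labeling steady-state time
#'
#' The earliest grid time at which the maximum MID change per unit time
#' drops below `tol`.
#'
#' @param sim a `mid_sim`.
#' @param tol rate tolerance (fraction per time unit).
#' @return list `t_ss` (time, `NA` if never reached) and `index`.
#' @export
steady_state_time <- function(sim, tol = 1e-6) {
  tt <- sim$times
  rate <- rep(0, length(tt))
  for (M in sim$mids) {
    d <- abs(M[-1L, , drop = FALSE] - M[-nrow(M), , drop = FALSE]) /
      diff(tt)
    rate[-1L] <- pmax(rate[-1L], apply(d, 1L, max))
  }
  j <- which(rate[-1L] < tol)
  if (length(j) == 0) return(list(t_ss = NA_real_, index = length(tt)))
  list(t_ss = tt[j[1] + 1L], index = j[1] + 1L)
}

#' Sample MIDs before steady state
#'
#' Returns the simulated MIDs at `fraction * t_ss` (nearest grid point),
#' where `t_ss` is the detected steady-state time. Labeling in batch
#' culture is usually incomplete, and sampling the transient regime is
#' what makes chain neighbors distinguishable at all.
#'
#' @param sim a `mid_sim`.
#' @param fraction in (0, 1]; 1 returns the steady-state MIDs.
#' @param tol steady-state detection tolerance.
#' @return named list metabolite -> MID, with attributes `time` and
#'   `t_ss`.
#' @export
sample_pre_steady_state <- function(sim, fraction = 0.5, tol = 1e-6) {
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]", class = "midtrace_error")
  }
  ss <- steady_state_time(sim, tol)
  if (is.na(ss$t_ss)) {
    warn("steady state not reached on the time grid; using the last time point")
    ss$t_ss <- max(sim$times)
  }
  target <- fraction * ss$t_ss
  j <- which.min(abs(sim$times - target))
  out <- lapply(sim$mids, function(M) {
    x <- pmax(M[j, ], 0)
    x / sum(x)
  })
  attr(out, "time") <- sim$times[j]
  attr(out, "t_ss") <- ss$t_ss
  out
}

#' Simulate a panel of parallel tracer experiments
#'
#' Runs one nonstationary simulation per tracer, samples each at
#' `fraction * t_ss`, optionally adds measurement noise (additive
#' Gaussian per MI fraction, clipped at 0, renormalized), and assembles a
#' peak table with one experiment per tracer (named after its substrate).
#'
#' @param network an `atom_network`.
#' @param tracers list of [tracer_config()]s with distinct substrates.
#' @param fraction_of_t_ss pre-steady-state sampling fraction (default
#'   0.5).
#' @param noise_sd Gaussian noise standard deviation on MI fractions
#'   (default 0).
#' @param seed RNG seed for the noise (required when `noise_sd > 0`).
#' @param times optional time grid.
#' @param targets metabolites to report (default all).
#' @param add_natural_abundance apply the forward natural-13C model to
#'   the simulated MIDs (default `FALSE`: simulated data are abstract,
#'   tracer-only).
#' @param p13 natural 13C abundance if `add_natural_abundance`.
#' @return a `peak_tbl` with one peak per metabolite.
#' @export
run_tracer_panel <- function(network, tracers, fraction_of_t_ss = 0.5,
                             noise_sd = 0, seed = NULL, times = NULL,
                             targets = NULL, add_natural_abundance = FALSE,
                             p13 = 0.0107) {
  subs <- vapply(tracers, `[[`, character(1), "substrate")
  if (anyDuplicated(subs)) abort("tracers must reference distinct substrates",
                                 class = "midtrace_error")
  if (noise_sd > 0 && is.null(seed)) {
    abort("a seed is required when noise_sd > 0", class = "midtrace_error")
  }
  mets <- network$metabolites
  if (is.null(targets)) targets <- mets$id
  if (is.null(times)) times <- default_time_grid(network)
  clean <- list()
  for (tr in tracers) {
    sim <- simulate_nonstationary(network, tr, times = times, targets = targets)
    clean[[tr$substrate]] <- sample_pre_steady_state(sim, fraction_of_t_ss)
  }
  if (!is.null(seed)) set.seed(seed)
  peaks <- purrr::map_dfr(targets, function(m) {
    mids <- list()
    for (e in subs) {
      x <- clean[[e]][[m]]
      if (add_natural_abundance) x <- apply_natural_abundance(x, p13)
      if (noise_sd > 0) {
        x <- pmax(x + rnorm(length(x), sd = noise_sd), 0)
        x <- x / sum(x)
      }
      mids[[e]] <- x
    }
    tibble(peak_id = m, n_carbons = mets$n_carbons[match(m, mets$id)],
           mids = list(mids))
  })
  peak_table(peaks, experiments = subs)
}
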