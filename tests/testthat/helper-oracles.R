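# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive results from first
# principles (exhaustive enumeration, naive loops) and share no code with
# the implementation paths they check.

# Convolution by explicit double sum over (i, j) pairs.
oracle_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (i in seq_len(length(a))) {
      j <- k - i + 1L
      if (j >= 1L && j <= length(b)) s <- s + a[i] * b[j]
    }
    out[k] <- s
  }
  out
}

# Exhaustive convolutant-search distance for one pair, naive loops.
oracle_pair_distance <- function(table, ia, ib, exps) {
  if (table$n_carbons[ia] > table$n_carbons[ib]) { t <- ia; ia <- ib; ib <- t }
  m <- table$n_carbons[ia]; n <- table$n_carbons[ib]
  ma <- table$mids[[ia]]; mb <- table$mids[[ib]]
  shared <- exps[exps %in% names(ma) & exps %in% names(mb)]
  if (length(shared) == 0) {
    return(list(distance = NA_real_, conv = NA_character_, status = "incomparable"))
  }
  if (m == n) {
    d <- 0
    for (e in shared) d <- d + sqrt(sum((ma[[e]] - mb[[e]])^2))
    return(list(distance = d, conv = "direct", status = "direct"))
  }
  cand <- which(table$n_carbons == n - m)
  cand <- cand[order(table$peak_id[cand])]
  best <- Inf; best_id <- NA_character_
  for (ic in cand) {
    mc <- table$mids[[ic]]
    e_ok <- exps[exps %in% names(ma) & exps %in% names(mb) & exps %in% names(mc)]
    if (length(e_ok) == 0) next
    d <- 0
    for (e in e_ok) {
      cv <- oracle_convolve(ma[[e]], mc[[e]])
      d <- d + sqrt(sum((cv - mb[[e]])^2))
    }
    if (d < best) { best <- d; best_id <- table$peak_id[ic] }
  }
  if (is.infinite(best)) {
    list(distance = NA_real_, conv = "none", status = "missing_convolutant")
  } else list(distance = best, conv = best_id, status = "ok")
}

# Full pairwise matrix via the naive per-pair search + global-max sentinel.
oracle_pairwise <- function(table, use_experiments = NULL) {
  exps <- experiments(table)
  if (!is.null(use_experiments)) exps <- exps[exps %in% use_experiments]
  np <- nrow(table)
  rows <- list()
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      r <- oracle_pair_distance(table, i, j, exps)
      # orient as the implementation does: A is the smaller-carbon peak,
      # ties (equal size) by peak id
      ia <- i; ib <- j
      if (table$n_carbons[ia] > table$n_carbons[ib] ||
          (table$n_carbons[ia] == table$n_carbons[ib] &&
           table$peak_id[ia] > table$peak_id[ib])) { ia <- j; ib <- i }
      rows[[length(rows) + 1L]] <-
        data.frame(peak_a = table$peak_id[ia], peak_b = table$peak_id[ib],
                   distance = r$distance, conv = r$conv, status = r$status,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  defined <- res$status %in% c("ok", "direct")
  sentinel <- if (any(defined)) max(res$distance[defined]) else NA_real_
  res$distance[res$status == "missing_convolutant"] <- sentinel
  # orient pairs so peak_a has the smaller carbon count (matching the
  # implementation's convention) for comparison purposes
  res[order(res$peak_a, res$peak_b), ]
}

# --- full positional-isotopomer simulation oracle -------------------------

# Pattern distribution of a substrate under a tracer (bit p-1 = position p).
oracle_substrate_patterns <- function(n, tracer_hit) {
  # tracer_hit: per-position probability of 13C for the labeled species,
  # plus overall labeled fraction
  probs <- numeric(2^n)
  for (pat in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(pat, 0:(n - 1)), 1L)
    p_lab <- prod(ifelse(bits == 1, tracer_hit$per_pos, 1 - tracer_hit$per_pos))
    p_unl <- if (all(bits == 0)) 1 else 0
    probs[pat + 1] <- tracer_hit$fraction * p_lab +
      (1 - tracer_hit$fraction) * p_unl
  }
  probs
}

.tracer_hit <- function(met, n, tracer) {
  if (is.null(tracer) || tracer$substrate != met) {
    return(list(per_pos = numeric(n), fraction = 1))
  }
  pos <- if (identical(tracer$positions, "U")) seq_len(n)
         else as.integer(tracer$positions)
  per_pos <- ifelse(seq_len(n) %in% pos, tracer$purity, 0)
  list(per_pos = per_pos, fraction = tracer$fraction)
}

# Product-instance pattern distribution from reactant pattern distributions.
oracle_product_dist <- function(r, prod_term, pattern_of) {
  np <- length(prod_term$atoms)
  # for each product position, which (reactant index, reactant position)?
  src <- lapply(seq_len(np), function(p) {
    for (qi in seq_along(r$reactants)) {
      qpos <- match(prod_term$atoms[p], r$reactants[[qi]]$atoms)
      if (!is.na(qpos)) return(c(qi, qpos))
    }
    stop("unmapped product atom")
  })
  # marginal distribution of used positions per reactant
  out <- numeric(2^np)
  for (pat in 0:(2^np - 1)) {
    bits <- bitwAnd(bitwShiftR(pat, 0:(np - 1)), 1L)
    p <- 1
    for (qi in seq_along(r$reactants)) {
      used <- which(vapply(src, function(s) s[1] == qi, logical(1)))
      if (length(used) == 0) next
      qn <- length(r$reactants[[qi]]$atoms)
      qdist <- pattern_of(r$reactants[[qi]]$met)
      # marginal probability that reactant positions src[used][2] have bits[used]
      marg <- 0
      for (qpat in 0:(2^qn - 1)) {
        qbits <- bitwAnd(bitwShiftR(qpat, 0:(qn - 1)), 1L)
        okk <- TRUE
        for (u in used) {
          if (qbits[src[[u]][2]] != bits[u]) { okk <- FALSE; break }
        }
        if (okk) marg <- marg + qdist[qpat + 1]
      }
      p <- p * marg
    }
    out[pat + 1] <- p
  }
  out
}

oracle_mid_from_patterns <- function(probs, n) {
  mid <- numeric(n + 1L)
  for (pat in 0:(2^n - 1)) {
    k <- sum(bitwAnd(bitwShiftR(pat, 0:(n - 1)), 1L))
    mid[k + 1L] <- mid[k + 1L] + probs[pat + 1L]
  }
  mid
}

# Transient positional-isotopomer ODE simulation (deSolve on the full
# 2^n state space of every internal metabolite).
oracle_isotopomer_sim <- function(network, tracer, times) {
  mets <- network$metabolites
  internal <- mets$id[!mets$is_substrate]
  ncarb <- setNames(mets$n_carbons, mets$id)
  pools <- setNames(mets$pool_size, mets$id)
  cons <- setNames(numeric(nrow(mets)), mets$id)
  for (r in network$reactions) {
    for (t in r$reactants) cons[t$met] <- cons[t$met] + r$flux
  }
  sub_dist <- lapply(setNames(mets$id[mets$is_substrate],
                              mets$id[mets$is_substrate]), function(m) {
    oracle_substrate_patterns(ncarb[[m]], .tracer_hit(m, ncarb[[m]], tracer))
  })
  offs <- c(0, cumsum(2^ncarb[internal]))
  idx <- setNames(lapply(seq_along(internal), function(i) {
    (offs[i] + 1):offs[i + 1]
  }), internal)
  y0 <- unlist(lapply(internal, function(m) {
    p <- numeric(2^ncarb[[m]]); p[1] <- 1; p
  }), use.names = FALSE)
  deriv <- function(t, y, parms) {
    pattern_of <- function(m) {
      if (!is.null(sub_dist[[m]])) sub_dist[[m]] else y[idx[[m]]]
    }
    dy <- numeric(length(y))
    for (i in seq_along(internal)) {
      m <- internal[i]
      dy[idx[[i]]] <- -cons[[m]] / pools[[m]] * y[idx[[i]]]
    }
    for (r in network$reactions) {
      for (p in r$products) {
        if (p$met %in% internal) {
          d <- oracle_product_dist(r, p, pattern_of)
          i <- match(p$met, internal)
          dy[idx[[i]]] <- dy[idx[[i]]] + r$flux / pools[[p$met]] * d
        }
      }
    }
    list(dy)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  mids <- list()
  for (m in mets$id) {
    if (m %in% internal) {
      n <- ncarb[[m]]
      mids[[m]] <- t(apply(sol[, idx[[m]] + 1L, drop = FALSE], 1L,
                           oracle_mid_from_patterns, n = n))
    } else {
      row <- oracle_mid_from_patterns(sub_dist[[m]], ncarb[[m]])
      mids[[m]] <- matrix(rep(row, each = length(times)), nrow = length(times))
    }
  }
  list(times = times, mids = mids)
}

# Steady state of the same positional-isotopomer system by fixed-point
# iteration of P_M = (sum of producing flux * source dist) / consumption.
oracle_isotopomer_ss <- function(network, tracer, tol = 1e-13, max_iter = 10000) {
  mets <- network$metabolites
  internal <- mets$id[!mets$is_substrate]
  ncarb <- setNames(mets$n_carbons, mets$id)
  cons <- setNames(numeric(nrow(mets)), mets$id)
  for (r in network$reactions) {
    for (t in r$reactants) cons[t$met] <- cons[t$met] + r$flux
  }
  sub_dist <- lapply(setNames(mets$id[mets$is_substrate],
                              mets$id[mets$is_substrate]), function(m) {
    oracle_substrate_patterns(ncarb[[m]], .tracer_hit(m, ncarb[[m]], tracer))
  })
  P <- lapply(setNames(internal, internal), function(m) {
    p <- numeric(2^ncarb[[m]]); p[1] <- 1; p
  })
  for (it in seq_len(max_iter)) {
    delta <- 0
    newP <- P
    pattern_of <- function(m) if (!is.null(sub_dist[[m]])) sub_dist[[m]] else P[[m]]
    acc <- lapply(P, function(p) numeric(length(p)))
    for (r in network$reactions) {
      for (p in r$products) {
        if (p$met %in% internal) {
          acc[[p$met]] <- acc[[p$met]] +
            r$flux * oracle_product_dist(r, p, pattern_of)
        }
      }
    }
    for (m in internal) {
      newP[[m]] <- acc[[m]] / cons[[m]]
      delta <- max(delta, max(abs(newP[[m]] - P[[m]])))
    }
    P <- newP
    if (delta < tol) break
  }
  mids <- lapply(setNames(mets$id, mets$id), function(m) {
    if (m %in% internal) oracle_mid_from_patterns(P[[m]], ncarb[[m]])
    else oracle_mid_from_patterns(sub_dist[[m]], ncarb[[m]])
  })
  mids
}

# Flux-weighted atom-fate enumeration: probability that each carbon atom
# of each metabolite derives from `source`, by fixed-point iteration.
oracle_carbon_contribution <- function(network, source, tol = 1e-13,
                                       max_iter = 10000) {
  mets <- network$metabolites
  ncarb <- setNames(mets$n_carbons, mets$id)
  cons <- setNames(numeric(nrow(mets)), mets$id)
  for (r in network$reactions) {
    for (t in r$reactants) cons[t$met] <- cons[t$met] + r$flux
  }
  fixed <- c(mets$id[mets$is_substrate], source)
  prob <- list()
  for (m in mets$id) {
    prob[[m]] <- if (m == source) rep(1, ncarb[[m]]) else numeric(ncarb[[m]])
  }
  internal <- setdiff(mets$id, fixed)
  for (it in seq_len(max_iter)) {
    acc <- lapply(setNames(mets$id, mets$id), function(m) numeric(ncarb[[m]]))
    for (r in network$reactions) {
      for (p in r$products) {
        if (!p$met %in% internal) next
        for (pp in seq_along(p$atoms)) {
          for (q in r$reactants) {
            qpos <- match(p$atoms[pp], q$atoms)
            if (!is.na(qpos)) {
              acc[[p$met]][pp] <- acc[[p$met]][pp] + r$flux * prob[[q$met]][qpos]
              break
            }
          }
        }
      }
    }
    delta <- 0
    for (m in internal) {
      new <- acc[[m]] / cons[[m]]
      delta <- max(delta, max(abs(new - prob[[m]])))
      prob[[m]] <- new
    }
    if (delta < tol) break
  }
  vapply(setNames(mets$id, mets$id), function(m) mean(prob[[m]]), numeric(1))
}

# Exhaustive precision-recall from confusion counts at every threshold.
oracle_pr <- function(distance, related) {
  ord <- order(distance)
  distance <- distance[ord]; related <- related[ord]
  thr <- unique(distance)
  P <- sum(related)
  pts <- t(vapply(thr, function(t) {
    pred <- distance <= t
    tp <- sum(pred & related)
    c(precision = tp / sum(pred), recall = tp / P)
  }, numeric(2)))
  r <- c(0, pts[, "recall"])
  p <- c(pts[1, "precision"], pts[, "precision"])
  list(points = pts, aupr = sum(diff(r) * (head(p, -1) + p[-1]) / 2))
}
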