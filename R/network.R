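#' Atom-mapped metabolic networks
#'
#' A network is read from a plain-text reaction file, one reaction per
#' line, in an atom-transition dialect:
#'
#' ```
#' id: met (atoms) + met (atoms) -> met (atoms) + met (atoms)
#' ```
#'
#' Atoms are lowercase letters, position-matched between the two sides:
#' `v1: acoa (ab) + oaa (cd) -> cit (abcd)` says carbons 1-2 of citrate
#' come from acetyl-CoA and 3-4 from oxaloacetate. Rules: each letter may
#' appear at most once per side of a reaction (a metabolite taking part
#' twice is written as two instances, each with its own atom string);
#' every product letter must appear among the reactant letters; reactant
#' letters missing from the products are lost carbons (e.g. CO2 released
#' without being tracked). An empty right-hand side (`id: met (abc) ->`)
#' is a sink. Reversible reactions are encoded as two opposing
#' irreversible reactions. All fluxes must be non-negative, and at every
#' non-substrate metabolite total producing flux must equal total
#' consuming flux (steady state). Substrates are metabolites never
#' produced by any reaction (or listed explicitly); their pools are
#' external and their labeling is set by the tracer.
#'
#' @name atom_network
NULL

.parse_side <- function(txt, rxn_id) {
  txt <- trimws(txt)
  if (txt == "") return(list())
  terms <- strsplit(txt, "+", fixed = TRUE)[[1]]
  lapply(terms, function(t) {
    t <- trimws(t)
    m <- regmatches(t, regexec("^(?:(\\d+(?:\\.\\d+)?)\\s+)?([A-Za-z0-9_.-]+)\\s*\\(([a-z]*)\\)$", t))[[1]]
    if (length(m) == 0) {
      abort(sprintf("reaction %s: cannot parse term '%s'", rxn_id, t),
            class = "midtrace_parse_error")
    }
    if (nzchar(m[2]) && as.numeric(m[2]) != 1) {
      abort(sprintf("reaction %s: coefficient %s unsupported; repeat the metabolite instance instead",
                    rxn_id, m[2]), class = "midtrace_parse_error")
    }
    list(met = m[3], atoms = strsplit(m[4], "")[[1]])
  })
}

#' Parse an atom-mapped network
#'
#' @param text character vector of reaction lines (or a single string
#'   with newlines). Blank lines and `#` comments are ignored.
#' @param fluxes named numeric vector of reaction fluxes (default: 1 for
#'   every reaction).
#' @param pool_sizes named numeric vector of metabolite pool sizes
#'   (default: 1 for every metabolite; only relative pool/flux ratios
#'   shape the labeling transients).
#' @param substrates optional character vector of substrate metabolite
#'   ids; defaults to all metabolites never produced by a reaction.
#' @param balance_tol relative tolerance on flux balance at non-substrate
#'   metabolites.
#' @return an `atom_network`: a list with a `metabolites` tibble (`id`,
#'   `n_carbons`, `is_substrate`, `pool_size`) and a `reactions` list.
#' @export
parse_network <- function(text, fluxes = NULL, pool_sizes = NULL,
                          substrates = NULL, balance_tol = 1e-9) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  reactions <- lapply(lines, function(ln) {
    hdr <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(hdr) == 0) {
      abort(sprintf("cannot parse reaction line '%s'", ln),
            class = "midtrace_parse_error")
    }
    id <- hdr[2]
    sides <- strsplit(hdr[3], "->", fixed = TRUE)[[1]]
    if (length(sides) < 1 || length(sides) > 2) {
      abort(sprintf("reaction %s: expected exactly one '->'", id),
            class = "midtrace_parse_error")
    }
    lhs <- .parse_side(sides[1], id)
    rhs <- if (length(sides) == 2) .parse_side(sides[2], id) else list()
    if (length(lhs) == 0) {
      abort(sprintf("reaction %s: empty reactant side", id),
            class = "midtrace_parse_error")
    }
    r_atoms <- unlist(lapply(lhs, `[[`, "atoms"), use.names = FALSE)
    p_atoms <- unlist(lapply(rhs, `[[`, "atoms"), use.names = FALSE)
    if (anyDuplicated(r_atoms) || anyDuplicated(p_atoms)) {
      abort(sprintf("reaction %s: duplicated atom letter within a side", id),
            class = "midtrace_parse_error")
    }
    orphan <- setdiff(p_atoms, r_atoms)
    if (length(orphan) > 0) {
      abort(sprintf("reaction %s: atom mismatch, product atoms (%s) not on reactant side",
                    id, paste(orphan, collapse = "")),
            class = "midtrace_parse_error")
    }
    list(id = id, flux = NA_real_, reactants = lhs, products = rhs)
  })
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) abort("duplicate reaction ids",
                                    class = "midtrace_parse_error")

  # carbon counts, consistent across occurrences
  counts <- list()
  for (r in reactions) {
    for (term in c(r$reactants, r$products)) {
      n <- length(term$atoms)
      if (!is.null(counts[[term$met]]) && counts[[term$met]] != n) {
        abort(sprintf("metabolite %s: atom-count mismatch (%d vs %d) in reaction %s",
                      term$met, counts[[term$met]], n, r$id),
              class = "midtrace_parse_error")
      }
      counts[[term$met]] <- n
    }
  }
  mets <- sort(names(counts))

  if (is.null(fluxes)) fluxes <- setNames(rep(1, length(reactions)), rxn_ids)
  missing_flux <- setdiff(rxn_ids, names(fluxes))
  if (length(missing_flux) > 0) {
    abort(paste0("missing fluxes for: ", paste(missing_flux, collapse = ", ")),
          class = "midtrace_error")
  }
  if (any(fluxes < 0)) abort("fluxes must be non-negative", class = "midtrace_error")
  dangling <- setdiff(names(fluxes), rxn_ids)
  if (length(dangling) > 0) {
    abort(paste0("fluxes for unknown reactions: ", paste(dangling, collapse = ", ")),
          class = "midtrace_error")
  }
  for (i in seq_along(reactions)) reactions[[i]]$flux <- unname(fluxes[[rxn_ids[i]]])

  produced <- unique(unlist(lapply(reactions, function(r) {
    vapply(r$products, `[[`, character(1), "met")
  }), use.names = FALSE))
  if (is.null(substrates)) substrates <- setdiff(mets, produced)
  bad_sub <- setdiff(substrates, mets)
  if (length(bad_sub) > 0) {
    abort(paste0("unknown substrate metabolites: ", paste(bad_sub, collapse = ", ")),
          class = "midtrace_error")
  }

  pools <- setNames(rep(1, length(mets)), mets)
  if (!is.null(pool_sizes)) {
    bad <- setdiff(names(pool_sizes), mets)
    if (length(bad) > 0) abort(paste0("pool sizes for unknown metabolites: ",
                                      paste(bad, collapse = ", ")),
                               class = "midtrace_error")
    pools[names(pool_sizes)] <- pool_sizes
  }

  net <- structure(list(
    metabolites = tibble(id = mets,
                         n_carbons = unname(vapply(mets, function(m) counts[[m]],
                                                   integer(1))),
                         is_substrate = mets %in% substrates,
                         pool_size = unname(pools[mets])),
    reactions = reactions
  ), class = "atom_network")

  bal <- flux_balance(net)
  bad <- bal[!bal$is_substrate & bal$residual_rel > balance_tol, , drop = FALSE]
  if (nrow(bad) > 0) {
    abort(paste0("flux imbalance at: ",
                 paste(sprintf("%s (%.3g)", bad$id, bad$residual), collapse = ", ")),
          class = "midtrace_error")
  }
  net
}

#' @export
print.atom_network <- function(x, ...) {
  cat(sprintf("# An atom-mapped network: %d metabolites, %d reactions, %d substrates\n",
              nrow(x$metabolites), length(x$reactions),
              sum(x$metabolites$is_substrate)))
  invisible(x)
}

#' Flux balance residuals per metabolite
#'
#' @param network an `atom_network`.
#' @return a tibble: `id`, `production`, `consumption`, `residual`,
#'   `residual_rel`, `is_substrate`.
#' @export
flux_balance <- function(network) {
  mets <- network$metabolites$id
  prod <- setNames(numeric(length(mets)), mets)
  cons <- prod
  for (r in network$reactions) {
    for (t in r$reactants) cons[t$met] <- cons[t$met] + r$flux
    for (t in r$products) prod[t$met] <- prod[t$met] + r$flux
  }
  scale <- pmax(prod, cons, 1e-300)
  tibble(id = mets, production = unname(prod), consumption = unname(cons),
         residual = unname(abs(prod - cons)),
         residual_rel = unname(abs(prod - cons) / scale),
         is_substrate = network$metabolites$is_substrate)
}

# Total consuming flux per metabolite (label dilution rate numerator).
consumption_flux <- function(network) {
  mets <- network$metabolites$id
  cons <- setNames(numeric(length(mets)), mets)
  for (r in network$reactions) {
    for (t in r$reactants) cons[t$met] <- cons[t$met] + r$flux
  }
  cons
}

#' Read a network from files
#'
#' @param path reaction file.
#' @param fluxes_path,pools_path optional two-column headerless TSVs
#'   (id, value).
#' @inheritParams parse_network
#' @return an `atom_network`.
#' @export
read_network <- function(path, fluxes_path = NULL, pools_path = NULL,
                         substrates = NULL) {
  read_two_col <- function(p) {
    df <- readr::read_tsv(p, col_names = c("id", "value"), col_types = "cc",
                          show_col_types = FALSE, progress = FALSE)
    setNames(as.numeric(df$value), df$id)
  }
  fluxes <- if (!is.null(fluxes_path)) read_two_col(fluxes_path)
  pools <- if (!is.null(pools_path)) read_two_col(pools_path)
  parse_network(readLines(path), fluxes = fluxes, pool_sizes = pools,
                substrates = substrates)
}

#' Write a network to files
#'
#' @param network an `atom_network`.
#' @param path reaction file to write.
#' @param fluxes_path,pools_path optional TSV paths for fluxes and pool
#'   sizes.
#' @export
write_network <- function(network, path, fluxes_path = NULL, pools_path = NULL) {
  fmt_side <- function(terms) {
    paste(vapply(terms, function(t) {
      sprintf("%s (%s)", t$met, paste(t$atoms, collapse = ""))
    }, character(1)), collapse = " + ")
  }
  lines <- vapply(network$reactions, function(r) {
    sprintf("%s: %s -> %s", r$id, fmt_side(r$reactants), fmt_side(r$products))
  }, character(1))
  writeLines(lines, path)
  if (!is.null(fluxes_path)) {
    readr::write_tsv(tibble(id = vapply(network$reactions, `[[`, character(1), "id"),
                            value = vapply(network$reactions, `[[`, numeric(1), "flux")),
                     fluxes_path, col_names = FALSE, progress = FALSE)
  }
  if (!is.null(pools_path)) {
    readr::write_tsv(tibble(id = network$metabolites$id,
                            value = network$metabolites$pool_size),
                     pools_path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}
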