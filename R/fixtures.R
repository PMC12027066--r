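#' Synthetic fixtures: toy networks and simulated MID tables
#'
#' Generators for small atom-mapped networks (linear chains, a branch
#' point, a condensation, a scrambling TCA-like cycle, random DAGs and a
#' 25-metabolite evaluation panel), and for peak tables simulated from
#' them with a panel of parallel tracers. Every generator is
#' deterministic given its arguments (and seed, where randomness is
#' involved), so fixtures regenerate bit-identically.
#'
#' Fixture fluxes are assigned constructively so that flux balance holds
#' exactly and every reaction is active at comparable magnitude (all
#' fluxes 1 or 2); random DAGs restrict every metabolite to a single
#' consuming reaction, which makes unit fluxes balanced by construction.
#'
#' @name fixtures
NULL

.atoms <- function(n, offset = 0) letters[(offset + 1):(offset + n)]
.atom_str <- function(n, offset = 0) paste(.atoms(n, offset), collapse = "")

#' Generate a toy atom-mapped network
#'
#' Templates:
#' * `linear_chain`: `n_mets` metabolites in a carbon-preserving chain
#'   `M1 -> M2 -> ...`, `M1` the substrate.
#' * `branched`: a chain that splits at one node into two branches.
#' * `condensation`: `A + B -> C` from two substrates.
#' * `toy_tca`: a 4-reaction scrambling cycle (11 total carbons) where a
#'   2-carbon substrate condenses onto a regenerated 2-carbon acceptor,
#'   with CO2 release.
#' * `random_dag`: seeded random acyclic assembly of conversions and
#'   condensations.
#' * `eval_panel`: the default evaluation fixture — 25 metabolites in
#'   five tracer-substrate chains (lengths 3-5, carbon counts 2-4) plus
#'   one condensation (`A2 + B1 -> F1 -> F2`).
#'
#' @param template template name.
#' @param n_mets,carbons chain length and carbon count (`linear_chain`).
#' @param n_substrates,max_carbons,p_condense,seed `random_dag` controls.
#' @return an `atom_network`.
#' @export
make_network <- function(template = c("linear_chain", "branched",
                                      "condensation", "toy_tca",
                                      "random_dag", "eval_panel"),
                         n_mets = 4L, carbons = 3L, n_substrates = 2L,
                         max_carbons = 3L, p_condense = 0.3, seed = 1L) {
  template <- match.arg(template)
  switch(template,
    linear_chain = {
      if (n_mets < 2) abort("linear_chain needs >= 2 metabolites",
                            class = "midtrace_error")
      ids <- sprintf("M%d", seq_len(n_mets))
      a <- .atom_str(carbons)
      lines <- c(
        sprintf("r%d: %s (%s) -> %s (%s)", seq_len(n_mets - 1L),
                ids[-n_mets], a, ids[-1L], a),
        sprintf("out: %s (%s) ->", ids[n_mets], a))
      parse_network(lines)
    },
    branched = {
      a <- .atom_str(carbons)
      lines <- c(
        sprintf("r1: S (%s) -> A (%s)", a, a),
        sprintf("r2: A (%s) -> B (%s)", a, a),
        sprintf("r3: A (%s) -> C (%s)", a, a),
        sprintf("outB: B (%s) ->", a),
        sprintf("outC: C (%s) ->", a))
      parse_network(lines, fluxes = c(r1 = 2, r2 = 1, r3 = 1, outB = 1, outC = 1))
    },
    condensation = {
      na <- max(1L, carbons %/% 2L); nb <- max(1L, carbons - na)
      lines <- c(
        sprintf("rc: A (%s) + B (%s) -> C (%s)",
                .atom_str(na), .atom_str(nb, na), .atom_str(na + nb)),
        sprintf("out: C (%s) ->", .atom_str(na + nb)))
      parse_network(lines)
    },
    toy_tca = {
      # atom routing chosen so every cycle carbon eventually derives from
      # the acetyl substrate (no conserved loop => well-posed steady state)
      lines <- c(
        "r1: ac (ab) + oa (cd) -> ct (abcd)",
        "r2: ct (abcd) -> su (ac) + co2 (b) + co2 (d)",
        "r3: su (ab) -> oa (ab)",
        "rout: co2 (a) ->")
      parse_network(lines, fluxes = c(r1 = 1, r2 = 1, r3 = 1, rout = 2))
    },
    random_dag = .random_dag(n_mets, n_substrates, max_carbons, p_condense, seed),
    eval_panel = .eval_panel_network()
  )
}

.random_dag <- function(n_mets, n_substrates, max_carbons, p_condense, seed) {
  if (n_mets <= n_substrates) abort("need more metabolites than substrates",
                                    class = "midtrace_error")
  set.seed(seed)
  ids <- sprintf("X%02d", seq_len(n_mets))
  carbons <- integer(n_mets)
  carbons[seq_len(n_substrates)] <- sample(seq_len(max_carbons), n_substrates,
                                           replace = TRUE)
  open <- seq_len(n_substrates)  # metabolites not yet consumed
  lines <- character()
  for (i in (n_substrates + 1L):n_mets) {
    condense <- length(open) >= 2L && stats::runif(1) < p_condense
    if (condense) {
      par <- sort(sample(open, 2L))
      n1 <- carbons[par[1]]; n2 <- carbons[par[2]]
      carbons[i] <- n1 + n2
      lines <- c(lines, sprintf("r%02d: %s (%s) + %s (%s) -> %s (%s)",
                                i, ids[par[1]], .atom_str(n1),
                                ids[par[2]], .atom_str(n2, n1),
                                ids[i], .atom_str(n1 + n2)))
      open <- c(setdiff(open, par), i)
    } else {
      par <- if (length(open) == 1L) open else sample(open, 1L)
      carbons[i] <- carbons[par]
      a <- .atom_str(carbons[par])
      lines <- c(lines, sprintf("r%02d: %s (%s) -> %s (%s)", i, ids[par], a,
                                ids[i], a))
      open <- c(setdiff(open, par), i)
    }
  }
  for (t in open) {
    lines <- c(lines, sprintf("out%02d: %s (%s) ->", t, ids[t],
                              .atom_str(carbons[t])))
  }
  parse_network(lines)
}

# 25 metabolites, six substrate chains (carbon counts 1-4) feeding one
# condensation (A3 + B2 -> F1 -> F2). Every metabolite has exactly one
# consuming reaction, so unit fluxes balance exactly and all pools turn
# over at the same rate. The 1-carbon chain (W, untraced) guarantees a
# convolutant exists for every carbon-count difference in the table.
.eval_panel_network <- function() {
  chain <- function(prefix, sub, n_carbons, n_steps) {
    a <- .atom_str(n_carbons)
    ids <- c(sub, sprintf("%s%d", prefix, seq_len(n_steps)))
    sprintf("%s%d: %s (%s) -> %s (%s)", tolower(prefix),
            seq_len(n_steps), ids[-length(ids)], a, ids[-1L], a)
  }
  lines <- c(
    chain("A", "S1", 3L, 3L),
    chain("B", "S2", 2L, 2L),
    chain("C", "S3", 4L, 4L),
    chain("D", "S4", 3L, 4L),
    chain("E", "S5", 2L, 3L),
    chain("W", "W0", 1L, 1L),
    "f1: A3 (abc) + B2 (de) -> F1 (abcde)",
    "f2: F1 (abcde) -> F2 (abcde)",
    "outC: C4 (abcd) ->",
    "outD: D4 (abc) ->",
    "outE: E3 (ab) ->",
    "outW: W1 (a) ->",
    "outF: F2 (abcde) ->")
  parse_network(lines)
}

#' Direct biosynthetic precursors of each metabolite
#'
#' @param network an `atom_network`.
#' @return named list: for each non-substrate metabolite, the reactant
#'   metabolites of the reactions producing it.
#' @export
direct_precursors <- function(network) {
  out <- list()
  for (r in network$reactions) {
    pres <- vapply(r$reactants, `[[`, character(1), "met")
    for (p in r$products) {
      out[[p$met]] <- sort(unique(c(out[[p$met]], pres)))
    }
  }
  out
}

#' Simulate a noisy MID peak table with ground truth
#'
#' Builds (or accepts) a network, simulates one nonstationary labeling
#' experiment per substrate (uniformly labeled tracer, purity 1), samples
#' each before steady state, optionally adds measurement noise and decoy
#' peaks (random MIDs, unrelated to everything), and attaches synthetic
#' peak metadata (formula `CnH2nOn`, [M+H]+ m/z, deterministic retention
#' times). Ground truth (`relatedness` matrix, positive-pair labels and
#' the direct-precursor map) is computed from the same network.
#'
#' @param template passed to [make_network()] (ignored when `network`
#'   given).
#' @param network optional prebuilt `atom_network`.
#' @param tracers optional list of [tracer_config()]; default one uniform
#'   tracer per network substrate.
#' @param fraction_of_t_ss pre-steady-state sampling fraction (default
#'   0.5).
#' @param noise_sd Gaussian MI noise (default 0).
#' @param n_decoys number of random-MID decoy peaks (default 0).
#' @param seed RNG seed for noise and decoys.
#' @param f_threshold relatedness threshold for positive labels.
#' @param known_ids peaks flagged as previously known (default: the
#'   substrates and each chain's first product for `eval_panel`, else the
#'   substrates).
#' @return a list: `table` (`peak_tbl`), `network`, `relatedness`,
#'   `labels`, `precursors`, `tracers`.
#' @export
make_peak_table <- function(template = "eval_panel", network = NULL,
                            tracers = NULL, fraction_of_t_ss = 0.5,
                            noise_sd = 0, n_decoys = 0L, seed = 1L,
                            f_threshold = 0.5, known_ids = NULL) {
  if (is.null(network)) network <- make_network(template, seed = seed)
  mets <- network$metabolites
  if (is.null(tracers)) {
    subs <- mets$id[mets$is_substrate]
    # the eval panel traces its five main substrates; the 1-carbon chain
    # stays unlabeled (not every nutrient is available as a tracer)
    traced <- intersect(c("S1", "S2", "S3", "S4", "S5"), subs)
    if (length(traced) == 0) traced <- subs
    tracers <- lapply(traced, tracer_config)
  }
  tab <- run_tracer_panel(network, tracers,
                          fraction_of_t_ss = fraction_of_t_ss,
                          noise_sd = noise_sd, seed = seed)
  # synthetic metadata, deterministic in peak order
  tab$formula <- sprintf("C%dH%dO%d", tab$n_carbons, 2L * tab$n_carbons,
                         tab$n_carbons)
  tab$mz <- unname(vapply(tab$formula, formula_mass, numeric(1))) + PROTON_MASS
  tab$rt_seconds <- 60 + 7 * seq_len(nrow(tab))
  tab$polarity <- "+"
  if (is.null(known_ids)) {
    known_ids <- mets$id[mets$is_substrate]
    first_products <- intersect(c("A1", "B1", "C1", "D1", "E1"), tab$peak_id)
    known_ids <- c(known_ids, first_products)
  }
  tab$known <- tab$peak_id %in% known_ids
  tab$name <- tab$peak_id
  tab$tags <- lapply(tab$peak_id, function(id) {
    if (grepl("^(S1|A)", id)) "chainA"
    else if (grepl("^(S2|B)", id)) "chainB"
    else if (grepl("^(S3|C)", id)) "chainC"
    else if (grepl("^(S4|D)", id)) "chainD"
    else if (grepl("^(S5|E)", id)) "chainE"
    else if (grepl("^F", id)) c("chainA", "chainB")
    else "misc"
  })
  f <- relatedness_matrix(network)
  labels <- related_pairs(f, threshold = f_threshold)
  if (n_decoys > 0) {
    set.seed(seed + 1L)
    exps <- experiments(tab)
    decoys <- purrr::map_dfr(seq_len(n_decoys), function(i) {
      n <- sample(2:4, 1L)
      mids <- setNames(lapply(exps, function(e) {
        mid_normalize(stats::runif(n + 1L))
      }), exps)
      tibble(peak_id = sprintf("decoy%02d", i), n_carbons = n,
             mids = list(mids),
             formula = sprintf("C%dH%dO%d", n, 2L * n, n),
             mz = formula_mass(sprintf("C%dH%dO%d", n, 2L * n, n)) + PROTON_MASS,
             rt_seconds = 400 + 7 * i, polarity = "+", known = FALSE,
             name = sprintf("decoy%02d", i), tags = list("decoy"))
    })
    tab <- peak_table(dplyr::bind_rows(as_tibble(tab), decoys),
                      experiments = exps)
    decoy_ids <- decoys$peak_id
    extra <- tidyr::crossing(peak_a = decoy_ids,
                             peak_b = c(mets$id, decoy_ids))
    extra <- extra[extra$peak_a != extra$peak_b, , drop = FALSE]
    swap <- extra$peak_a > extra$peak_b
    tmp <- extra$peak_a[swap]
    extra$peak_a[swap] <- extra$peak_b[swap]; extra$peak_b[swap] <- tmp
    extra <- dplyr::distinct(extra)
    extra$f <- 0; extra$related <- FALSE
    labels <- dplyr::bind_rows(labels, extra)
    labels <- labels[order(labels$peak_a, labels$peak_b), , drop = FALSE]
  }
  list(table = tab, network = network, relatedness = f, labels = labels,
       precursors = direct_precursors(network), tracers = tracers)
}

#' Generate a synthetic candidate-compound table for a peak table
#'
#' Emulates a compound-database extract: one candidate per peak (same
#' formula and tags, id `cmp_<peak>`), plus `n_decoys` decoy compounds
#' whose masses fall outside any peak's matching window.
#'
#' @param table a `peak_tbl` with `formula` and `tags`.
#' @param n_decoys decoy compounds to append.
#' @return a compound tibble ([as_compound_table()]).
#' @export
make_compound_table <- function(table, n_decoys = 5L) {
  cmp <- tibble(compound_id = paste0("cmp_", table$peak_id),
                name = paste0("compound of ", table$peak_id),
                formula = table$formula,
                neutral_mass = NA_real_,
                tags = if ("tags" %in% names(table)) table$tags
                       else replicate(nrow(table), character(), simplify = FALSE))
  if (n_decoys > 0) {
    dec <- tibble(compound_id = sprintf("dec_%02d", seq_len(n_decoys)),
                  name = sprintf("decoy compound %d", seq_len(n_decoys)),
                  formula = sprintf("C%dH%dN%dO%d", 5 + seq_len(n_decoys),
                                    8 + seq_len(n_decoys), 2L,
                                    2 + seq_len(n_decoys)),
                  neutral_mass = NA_real_,
                  tags = replicate(n_decoys, "decoy", simplify = FALSE))
    cmp <- dplyr::bind_rows(cmp, dec)
  }
  as_compound_table(cmp)
}

#' Write a complete demo workspace
#'
#' Emits everything needed to run the whole workflow from files: the
#' network (reactions, fluxes, pools), the simulated MID table, the
#' relatedness matrix, the positive-pair labels and a candidate-compound
#' table.
#'
#' @param dir output directory (created if needed).
#' @param template,noise_sd,n_decoys,seed passed to [make_peak_table()].
#' @return the fixture list from [make_peak_table()], invisibly.
#' @export
write_demo_workspace <- function(dir, template = "eval_panel", noise_sd = 0,
                                 n_decoys = 0L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_peak_table(template, noise_sd = noise_sd, n_decoys = n_decoys,
                        seed = seed)
  write_network(fx$network, file.path(dir, "network.txt"),
                fluxes_path = file.path(dir, "fluxes.tsv"),
                pools_path = file.path(dir, "pools.tsv"))
  write_mid_table(fx$table, file.path(dir, "mid_table.tsv"))
  write_relatedness(fx$relatedness, file.path(dir, "relatedness.tsv"))
  readr::write_tsv(fx$labels, file.path(dir, "labels.tsv"), progress = FALSE)
  write_compound_table(make_compound_table(fx$table),
                       file.path(dir, "compounds.tsv"))
  invisible(fx)
}
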