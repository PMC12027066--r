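#' Elementary metabolite unit (EMU) decomposition
#'
#' An EMU is a subset of a metabolite's carbon atoms whose labeling state
#' can be balanced independently of the rest of the molecule. Tracing the
#' full-carbon EMUs of the target metabolites backward through the atom
#' maps yields the minimal set of EMUs (and EMU reactions) needed to
#' simulate the targets' MIDs; EMU reactions whose source atoms come from
#' several reactant molecules are *convolution* reactions, with all
#' sources strictly smaller than the target. Grouping EMUs by size gives
#' a system solvable size block by size block.
#'
#' @param network an `atom_network`.
#' @param targets metabolite ids whose full MIDs are required.
#' @return an `emu_system`: list with `emus` (tibble `emu_id`, `met`,
#'   `size`, `atoms` list-column, `is_substrate`), `reactions` (list of
#'   `target`, `sources` (character vector of emu ids, length > 1 for
#'   convolutions), `flux`), and `blocks` (emu ids grouped by size,
#'   ascending).
#' @export
decompose_emu <- function(network, targets) {
  mets <- network$metabolites
  bad <- setdiff(targets, mets$id)
  if (length(bad) > 0) abort(paste0("unknown target metabolites: ",
                                    paste(bad, collapse = ", ")),
                             class = "midtrace_error")
  is_sub <- setNames(mets$is_substrate, mets$id)
  ncarb <- setNames(mets$n_carbons, mets$id)

  emu_id <- function(met, atoms) paste0(met, "#", paste(sort(atoms), collapse = "."))
  seen <- new.env(parent = emptyenv())
  emus <- list()
  queue <- list()
  push <- function(met, atoms) {
    id <- emu_id(met, atoms)
    if (is.null(seen[[id]])) {
      seen[[id]] <- TRUE
      e <- list(emu_id = id, met = met, atoms = sort(atoms))
      emus[[length(emus) + 1L]] <<- e
      if (!is_sub[[met]]) queue[[length(queue) + 1L]] <<- e
    }
    id
  }
  for (m in targets) push(m, seq_len(ncarb[[m]]))

  emu_reactions <- list()
  while (length(queue) > 0) {
    e <- queue[[1L]]; queue <- queue[-1L]
    for (r in network$reactions) {
      for (p in r$products) {
        if (p$met != e$met) next
        letters_needed <- p$atoms[e$atoms]
        # split needed letters across reactant instances
        srcs <- list()
        for (q in r$reactants) {
          posq <- which(q$atoms %in% letters_needed)
          if (length(posq) > 0) srcs[[length(srcs) + 1L]] <- list(met = q$met,
                                                                 atoms = posq)
        }
        got <- sum(vapply(srcs, function(s) length(s$atoms), integer(1)))
        if (got != length(letters_needed)) {
          abort(sprintf("reaction %s: product atoms of %s not all mapped",
                        r$id, e$met), class = "midtrace_error")
        }
        src_ids <- vapply(srcs, function(s) push(s$met, s$atoms), character(1))
        emu_reactions[[length(emu_reactions) + 1L]] <-
          list(target = e$emu_id, sources = sort(src_ids), flux = r$flux,
               reaction_id = r$id)
      }
    }
  }

  emu_tbl <- purrr::map_dfr(emus, function(e) {
    tibble(emu_id = e$emu_id, met = e$met, size = length(e$atoms),
           atoms = list(e$atoms), is_substrate = unname(is_sub[e$met]))
  })
  emu_tbl <- emu_tbl[order(emu_tbl$size, emu_tbl$emu_id), , drop = FALSE]
  blocks <- split(emu_tbl$emu_id, emu_tbl$size)
  structure(list(emus = emu_tbl, reactions = emu_reactions, blocks = blocks,
                 targets = targets),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat(sprintf("# An EMU system: %d EMUs (sizes %s), %d EMU reactions\n",
              nrow(x$emus), paste(names(x$blocks), collapse = ", "),
              length(x$reactions)))
  invisible(x)
}

#' Tracer experiment configuration
#'
#' @param substrate substrate metabolite id.
#' @param positions `"U"` for uniform labeling, or an integer vector of
#'   labeled carbon positions.
#' @param fraction fraction of the substrate pool entering the system
#'   that is the labeled species (default 1).
#' @param purity isotopic purity of each labeled position (default 1).
#' @return a `tracer_config` list.
#' @export
tracer_config <- function(substrate, positions = "U", fraction = 1, purity = 1) {
  if (fraction < 0 || fraction > 1 || purity < 0 || purity > 1) {
    abort("fraction and purity must lie in [0, 1]", class = "midtrace_error")
  }
  structure(list(substrate = substrate, positions = positions,
                 fraction = fraction, purity = purity),
            class = "tracer_config")
}

# MID of a substrate EMU (atom subset `atoms`, positions 1..n) under a tracer.
substrate_emu_mid <- function(met, atoms, n_carbons, tracer) {
  k <- length(atoms)
  if (is.null(tracer) || tracer$substrate != met) return(mid_unlabeled(k))
  labeled_pos <- if (identical(tracer$positions, "U")) seq_len(n_carbons)
                 else as.integer(tracer$positions)
  lab <- mid_unlabeled(0)
  for (a in atoms) {
    atom_mid <- if (a %in% labeled_pos) c(1 - tracer$purity, tracer$purity)
                else c(1, 0)
    lab <- mid_convolve(lab, atom_mid)
  }
  (1 - tracer$fraction) * mid_unlabeled(k) + tracer$fraction * lab
}
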