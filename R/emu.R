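# Elementary metabolite unit (EMU) decomposition.
#
# An EMU is a subset of a metabolite's carbon atoms. Tracing measured
# fragments backward through the atom maps yields the minimal set of EMUs
# whose steady-state MIDs must be known, organised into size blocks whose
# balances are linear given all smaller sizes. Rotationally symmetric
# species are scrambled at production: every producing term is duplicated
# under the mirrored orientation with half weight, which makes the whole
# pool 50/50 scrambled without touching consuming reactions.

.emu_key <- function(species, positions) {
  paste0(species, "[", paste(positions, collapse = ","), "]")
}

# Production terms for one EMU (species, positions) of a balanced species.
# Each term: list(k = expanded-reaction index, coef, parts = list of
# (species, positions)).
.emu_producers <- function(model, species, positions) {
  terms <- list()
  orientations <- if (species %in% model$symmetric) {
    n <- model$species[[species]]
    list(list(pos = positions, coef = 0.5),
         list(pos = sort(n + 1L - positions), coef = 0.5))
  } else {
    list(list(pos = positions, coef = 1))
  }
  for (k in seq_along(model$expanded)) {
    e <- model$expanded[[k]]
    for (p in e$products) {
      if (p$species != species) next
      for (o in orientations) {
        letters_needed <- p$atoms[o$pos]
        # locate each letter among the reactant entries
        parts <- list()
        for (ri in seq_along(e$reactants)) {
          ratoms <- e$reactants[[ri]]$atoms
          hit <- which(ratoms %in% letters_needed)
          if (length(hit)) {
            parts[[length(parts) + 1L]] <-
              list(species = e$reactants[[ri]]$species, positions = sort(hit))
          }
        }
        found <- sum(vapply(parts, function(pp) length(pp$positions), 0L))
        if (found != length(letters_needed)) {
          stop("atom map of reaction '", e$id, "' does not cover EMU ",
               .emu_key(species, positions), call. = FALSE)
        }
        terms[[length(terms) + 1L]] <- list(k = k, coef = o$coef, parts = parts)
      }
    }
  }
  terms
}

#' EMU decomposition of a network for a set of target fragments
#'
#' Traces each target fragment backward through the atom maps to build the
#' minimal EMU system needed to simulate its steady-state MID, grouped into
#' size blocks in ascending order.
#'
#' @param model A `network_model`.
#' @param targets List of targets, each a list/vector with `species` and
#'   1-based carbon `positions`, or a `fragment_table` (see
#'   [read_fragments()]), in which case the skeleton carbon subsets are used.
#' @return An `emu_system` with elements `emus` (per-EMU metadata),
#'   `blocks` (EMU keys per size) and `terms` (production terms).
#' @export
emu_decompose <- function(model, targets) {
  stopifnot(inherits(model, "network_model"))
  if (inherits(targets, "fragment_table")) {
    targets <- lapply(seq_len(nrow(targets)), function(i) {
      list(species = targets$species[i], positions = targets$carbons[[i]])
    })
  }
  inputs <- c(model$medium, model$unbalanced)
  emus <- list()
  terms <- list()
  queue <- list()
  push <- function(species, positions) {
    positions <- sort(unique(as.integer(positions)))
    if (!species %in% names(model$species)) {
      stop("unknown species in fragment: ", species, call. = FALSE)
    }
    if (any(positions < 1L) || any(positions > model$species[[species]])) {
      stop("fragment carbon index out of range for ", species, " (",
           model$species[[species]], " carbons)", call. = FALSE)
    }
    key <- .emu_key(species, positions)
    if (is.null(emus[[key]])) {
      emus[[key]] <<- list(species = species, positions = positions,
                           size = length(positions),
                           input = species %in% inputs)
      queue[[length(queue) + 1L]] <<- key
    }
    key
  }
  for (tg in targets) push(tg$species, tg$positions)
  while (length(queue)) {
    key <- queue[[1]]
    queue[[1]] <- NULL
    em <- emus[[key]]
    if (em$input) next
    tms <- .emu_producers(model, em$species, em$positions)
    if (!length(tms)) {
      stop("no producing reaction for EMU ", key,
           " (dead-end species?)", call. = FALSE)
    }
    for (i in seq_along(tms)) {
      tms[[i]]$parts <- lapply(tms[[i]]$parts, function(pp) {
        list(key = push(pp$species, pp$positions))
      })
    }
    terms[[key]] <- tms
  }
  sizes <- sort(unique(vapply(emus, `[[`, 0L, "size")))
  blocks <- lapply(sizes, function(s) {
    names(emus)[vapply(emus, function(e) e$size == s && !e$input, TRUE)]
  })
  names(blocks) <- as.character(sizes)
  blocks <- blocks[vapply(blocks, length, 0L) > 0L]
  structure(list(emus = emus, terms = terms, blocks = blocks),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  cat("EMU system:", length(x$emus), "EMUs (",
      sum(vapply(x$emus, `[[`, TRUE, "input")), "substrate )\n")
  for (s in names(x$blocks)) {
    cat("  size", s, ":", length(x$blocks[[s]]), "balanced EMUs\n")
  }
  invisible(x)
}

#' Define a tracer
#'
#' @param species Medium species carrying the label.
#' @param positions 1-based labeled carbon positions.
#' @param isotope `"13C"` (the EMU simulator is carbon-only; deuterated
#'   glucose cycling has its own estimator, see [cycling_rates()]).
#' @param enrichment Isotopic purity per labeled position.
#' @param fraction Fraction of the medium pool that is tracer.
#' @return A `tracer_spec`.
#' @export
tracer_spec <- function(species, positions, isotope = "13C",
                        enrichment = 0.99, fraction = 1.0) {
  isotope <- match.arg(isotope, c("13C", "2H"))
  stopifnot(enrichment >= 0, enrichment <= 1, fraction >= 0, fraction <= 1)
  structure(list(species = species, positions = as.integer(positions),
                 isotope = isotope, enrichment = enrichment,
                 fraction = fraction),
            class = "tracer_spec")
}

# MID of a substrate EMU under a tracer. Unlabeled positions carry natural
# 13C at `nat13c` (0 for an idealized simulation). Tracer fraction mixes at
# the molecule level.
.substrate_emu_mid <- function(model, species, positions, tracer, nat13c) {
  n <- length(positions)
  natural <- .conv_pow(c(1 - nat13c, nat13c), n)
  if (is.null(tracer) || tracer$species != species) return(natural)
  lab <- 1
  for (p in positions) {
    d <- if (p %in% tracer$positions) {
      c(1 - tracer$enrichment, tracer$enrichment)
    } else {
      c(1 - nat13c, nat13c)
    }
    lab <- .conv(lab, d)
  }
  tracer$fraction * lab + (1 - tracer$fraction) * natural
}

#' Simulate steady-state labeling of EMU targets
#'
#' Solves the EMU balance equations block-by-block (one linear system per
#' EMU size) for a flux vector and tracer, returning the carbon-skeleton
#' MIDs of all EMUs in the system.
#'
#' @param model A `network_model`.
#' @param emus An `emu_system` from [emu_decompose()].
#' @param net Named net flux vector (one entry per reaction).
#' @param exch Named exchange flux vector (reversible reactions; missing
#'   entries default to 0). Exchange fluxes must be nonnegative.
#' @param tracer A [tracer_spec()] with isotope `"13C"`, or `NULL` for an
#'   unlabeled experiment.
#' @param nat13c Natural 13C abundance applied to skeleton carbons not
#'   enriched by the tracer; set 0 for idealized textbook MIDs.
#' @param balance_tol Tolerance on the flux balance precondition.
#' @return Named list of MID vectors, keyed as `"Species[i,j,...]"`.
#' @export
simulate_labeling <- function(model, emus, net, exch = NULL, tracer = NULL,
                              nat13c = natural_13c(), balance_tol = 1e-6) {
  stopifnot(inherits(model, "network_model"), inherits(emus, "emu_system"))
  if (!is.null(tracer) && tracer$isotope != "13C") {
    stop("the EMU simulator handles 13C tracers only", call. = FALSE)
  }
  if (!flux_balanced(model, net, balance_tol)) {
    stop("net fluxes violate S v = 0 beyond tolerance", call. = FALSE)
  }
  if (!is.null(exch) && any(exch < -1e-12)) {
    stop("exchange fluxes must be nonnegative", call. = FALSE)
  }
  w <- .oneway_fluxes(model, net, exch)
  mids <- list()
  for (key in names(emus$emus)) {
    em <- emus$emus[[key]]
    if (em$input) {
      mids[[key]] <- .substrate_emu_mid(model, em$species, em$positions,
                                        tracer, nat13c)
    }
  }
  for (s in names(emus$blocks)) {
    all_keys <- emus$blocks[[s]]
    width <- as.integer(s) + 1L
    # pools with zero total production carry no label downstream (their
    # consumption flux is also zero at steady state); mark NA and drop
    totals <- vapply(all_keys, function(key) {
      sum(vapply(emus$terms[[key]], function(tm) w[tm$k] * tm$coef, 0))
    }, 0)
    for (key in all_keys[totals == 0]) mids[[key]] <- NA
    keys <- all_keys[totals > 0]
    n <- length(keys)
    if (n == 0L) next
    idx <- stats::setNames(seq_len(n), keys)
    A <- matrix(0, n, n)
    B <- matrix(0, n, width)
    for (i in seq_len(n)) {
      for (tm in emus$terms[[keys[i]]]) {
        wt <- w[tm$k] * tm$coef
        if (wt == 0) next
        A[i, i] <- A[i, i] - wt
        pk <- vapply(tm$parts, `[[`, "", "key")
        if (length(pk) == 1L && pk %in% keys) {
          A[i, idx[[pk]]] <- A[i, idx[[pk]]] + wt
        } else {
          y <- 1
          for (p in pk) {
            if (is.null(mids[[p]]) || anyNA(mids[[p]])) {
              stop("singular EMU block: zero-flux pool of species '",
                   emus$emus[[p]]$species, "' feeds ", keys[i], call. = FALSE)
            }
            y <- .conv(y, mids[[p]])
          }
          B[i, ] <- B[i, ] - wt * y
        }
      }
    }
    X <- tryCatch(solve(A, B), error = function(e) {
      stop("singular EMU block at size ", s, ": ", conditionMessage(e),
           call. = FALSE)
    })
    for (i in seq_len(n)) mids[[keys[i]]] <- X[i, ]
  }
  mids
}

#' Read a fragment-ion table
#'
#' Fragment tables declare the measured GC-MS fragment ions: the metabolite
#' species, the carbon subset retained in the ion, and the elemental formula
#' of the atoms added by derivatization (methyloxime-TBDMS for organic/amino
#' acids, di-O-isopropylidene propionate for glucose), which determine the
#' natural-abundance convolution in measurement space.
#'
#' @param table Path to a TSV with columns `fragment`, `species`, `carbons`
#'   (e.g. `"1-3"` or `"2,3"`), `derivative_formula`; or an equivalent
#'   `data.frame`.
#' @return A `fragment_table` data frame with a list column `carbons`.
#' @export
read_fragments <- function(table) {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               comment.char = "#")
  }
  need <- c("fragment", "species", "carbons", "derivative_formula")
  if (!all(need %in% names(table))) {
    stop("fragment table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$fragment)) {
    stop("duplicate fragment name", call. = FALSE)
  }
  parse_carbons <- function(x) {
    out <- integer(0)
    for (piece in strsplit(x, ",")[[1]]) {
      piece <- trimws(piece)
      if (grepl("-", piece)) {
        ab <- as.integer(strsplit(piece, "-")[[1]])
        out <- c(out, seq(ab[1], ab[2]))
      } else {
        out <- c(out, as.integer(piece))
      }
    }
    sort(unique(out))
  }
  table$carbons <- lapply(as.character(table$carbons), parse_carbons)
  class(table) <- c("fragment_table", "data.frame")
  table
}

#' Convert a skeleton MID to measurement space
#'
#' Convolves a carbon-skeleton MID with the natural-abundance distribution
#' of the derivative atoms, truncates to the reported mass window, and
#' renormalizes.
#'
#' @param skeleton Numeric skeleton MID (M+0 ... M+n).
#' @param derivative_formula Elemental formula of atoms added by
#'   derivatization (`""` for none).
#' @param window Number of mass channels beyond the skeleton carbon count
#'   kept in measurement space (default 2, typical GC-MS reporting).
#' @param warn_loss Warn if truncation discards more than this fraction of
#'   total abundance (default 0.001).
#' @return Renormalized MID of length `length(skeleton) + window`.
#' @export
fragment_mid <- function(skeleton, derivative_formula = "", window = 2L,
                         warn_loss = 0.001) {
  full <- .conv(skeleton, .natural_mid_cached(derivative_formula))
  keep <- min(length(full), length(skeleton) + window)
  out <- full[seq_len(keep)]
  lost <- sum(full) - sum(out)
  if (lost > warn_loss * sum(full)) {
    warning(sprintf("mass window truncates %.2f%% of fragment abundance",
                    100 * lost / sum(full)))
  }
  out / sum(out)
}

#' Simulate measured fragment MIDs for one tracer
#'
#' Convenience wrapper: EMU-simulates skeleton labeling and converts every
#' fragment in a fragment table to measurement space.
#'
#' @inheritParams simulate_labeling
#' @param fragments A `fragment_table`.
#' @param window Mass-window width beyond skeleton carbons (see
#'   [fragment_mid()]).
#' @return Named list of measurement-space MIDs, one per fragment.
#' @export
simulate_fragments <- function(model, emus, net, exch = NULL, tracer = NULL,
                               fragments, nat13c = natural_13c(),
                               window = 2L, warn_loss = Inf) {
  mids <- simulate_labeling(model, emus, net, exch, tracer, nat13c = nat13c)
  out <- list()
  for (i in seq_len(nrow(fragments))) {
    key <- .emu_key(fragments$species[i], fragments$carbons[[i]])
    if (is.null(mids[[key]])) {
      stop("fragment '", fragments$fragment[i], "' EMU ", key,
           " absent from EMU system", call. = FALSE)
    }
    if (anyNA(mids[[key]])) {
      stop("fragment '", fragments$fragment[i], "' sits on a zero-flux pool (",
           fragments$species[i], ")", call. = FALSE)
    }
    out[[fragments$fragment[i]]] <-
      fragment_mid(mids[[key]], fragments$derivative_formula[i],
                   window = window, warn_loss = warn_loss)
  }
  out
}
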