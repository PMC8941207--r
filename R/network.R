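# Atom-mapped reaction networks.
#
# A network is a set of reactions with letter-coded carbon maps, e.g.
#   CS: OAA (abcd) + AcCoA (ef) -> Cit (dcbfea)
# Species consumed from or excreted to the medium are declared through the
# reaction `role` (uptake / release); all other species are balanced
# intracellular pools. Rotationally symmetric skeletons (succinate,
# fumarate) are flagged so their label is scrambled 50/50 on production.

.parse_side <- function(txt, rid) {
  txt <- trimws(txt)
  if (txt == "") stop("reaction '", rid, "': empty reaction side", call. = FALSE)
  terms <- strsplit(txt, "\\+")[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]+\\s+)?([A-Za-z][A-Za-z0-9_.]*)\\s*\\(([A-Za-z]*)\\)$", tm))[[1]]
    if (length(m) == 0L) {
      stop("reaction '", rid, "': cannot parse term '", tm, "'", call. = FALSE)
    }
    coef <- trimws(m[2])
    if (coef != "" && coef != "1") {
      stop("reaction '", rid, "': stoichiometric coefficients other than 1 ",
           "are not supported; repeat the species with distinct atom letters",
           call. = FALSE)
    }
    out[[length(out) + 1L]] <- list(species = m[3],
                                    atoms = strsplit(m[4], "")[[1]])
  }
  out
}

.parse_reaction <- function(id, equation, reversible, role) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("reaction '", id, "': equation must contain exactly one '->'",
         call. = FALSE)
  }
  reactants <- .parse_side(sides[1], id)
  products <- .parse_side(sides[2], id)
  for (side in list(reactants, products)) {
    letters_side <- unlist(lapply(side, `[[`, "atoms"))
    if (anyDuplicated(letters_side)) {
      stop("reaction '", id, "': atom letter used twice on one side",
           call. = FALSE)
    }
  }
  rl <- sort(unlist(lapply(reactants, `[[`, "atoms")))
  pl <- sort(unlist(lapply(products, `[[`, "atoms")))
  if (!identical(rl, pl)) {
    stop("reaction '", id, "': unbalanced carbons (reactants '",
         paste(rl, collapse = ""), "' vs products '",
         paste(pl, collapse = ""), "')", call. = FALSE)
  }
  role <- match.arg(role, c("internal", "uptake", "release"))
  list(id = id, equation = equation, reversible = isTRUE(reversible),
       role = role, reactants = reactants, products = products)
}

#' Parse an atom-mapped reaction network
#'
#' Reads a tab-delimited reaction table with columns `id`, `equation`,
#' `reversible` and `role` into a validated `network_model`. The equation
#' grammar is `Species (letters) [+ ...] -> Species (letters) [+ ...]`;
#' the multiset of atom letters must balance across the arrow and each
#' letter may appear only once per side.
#'
#' Uptake and release reactions connect the intracellular pools to the
#' medium: the single species that does not occur in any internal reaction
#' is taken as the medium species and excluded from the balanced set.
#' Species listed in `unbalanced` (by default CO2, treated as an effectively
#' infinite bicarbonate-diluted pool at natural abundance) are neither
#' balanced nor traced further back.
#'
#' @param table Path to a TSV file, or a `data.frame` with the four columns.
#' @param symmetric Character vector of rotationally symmetric species whose
#'   labeling is scrambled 50/50 (default: any species named `Suc` or `Fum`,
#'   the succinate and fumarate pools).
#' @param unbalanced Species exempted from mass balance and treated as
#'   natural-abundance inputs (default `"CO2"`). Set
#'   `unbalanced = character(0)` to balance CO2 explicitly, in which case the
#'   network must contain a CO2 release reaction.
#' @return A `network_model` object.
#' @seealso [validate_network()], [emu_decompose()]
#' @export
read_network <- function(table, symmetric = NULL, unbalanced = "CO2") {
  if (is.character(table)) {
    table <- utils::read.delim(table, stringsAsFactors = FALSE,
                               comment.char = "#")
  }
  need <- c("id", "equation", "reversible", "role")
  if (!all(need %in% names(table))) {
    stop("reaction table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$id)) {
    stop("duplicate reaction id: ",
         paste(unique(table$id[duplicated(table$id)]), collapse = ", "),
         call. = FALSE)
  }
  rev_flag <- table$reversible
  if (is.character(rev_flag)) rev_flag <- tolower(trimws(rev_flag)) %in% c("true", "yes", "1", "r")
  reactions <- Map(.parse_reaction, table$id, table$equation,
                   as.logical(rev_flag), table$role)
  names(reactions) <- table$id

  # species census
  species <- list()
  for (r in reactions) {
    for (entry in c(r$reactants, r$products)) {
      n <- length(entry$atoms)
      if (!is.null(species[[entry$species]]) && species[[entry$species]] != n) {
        stop("species '", entry$species, "' used with inconsistent carbon ",
             "counts (", species[[entry$species]], " vs ", n, ")",
             call. = FALSE)
      }
      species[[entry$species]] <- n
    }
  }
  species <- unlist(species)

  # medium species: touched by uptake/release reactions but by no internal one
  internal_sp <- unique(unlist(lapply(reactions, function(r) {
    if (r$role == "internal") vapply(c(r$reactants, r$products), `[[`, "", "species")
  })))
  n_rxn_touching <- table(unlist(lapply(reactions, function(r) {
    unique(vapply(c(r$reactants, r$products), `[[`, "", "species"))
  })))
  medium <- character(0)
  for (r in reactions) {
    if (r$role %in% c("uptake", "release")) {
      sp <- vapply(c(r$reactants, r$products), `[[`, "", "species")
      med <- setdiff(sp, internal_sp)
      if (length(med) > 1L) {
        # species shared with other exchange reactions are pools, not medium
        med <- med[n_rxn_touching[med] == 1L]
      }
      if (length(med) != 1L) {
        stop("reaction '", r$id, "' (", r$role, ") must touch exactly one ",
             "medium species; found: ", paste(med, collapse = ", "),
             call. = FALSE)
      }
      medium <- union(medium, med)
    }
  }
  unbalanced <- intersect(unbalanced, names(species))
  balanced <- setdiff(names(species), c(medium, unbalanced))

  if (is.null(symmetric)) {
    symmetric <- intersect(c("Suc", "Fum", "succinate", "fumarate"),
                           names(species))
  } else {
    bad <- setdiff(symmetric, names(species))
    if (length(bad)) stop("symmetric species not in network: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }

  model <- structure(list(
    reactions = reactions,
    species = species,
    balanced = balanced,
    medium = medium,
    unbalanced = unbalanced,
    symmetric = symmetric,
    net_names = names(reactions),
    exch_names = names(reactions)[vapply(reactions, `[[`, TRUE, "reversible")]
  ), class = "network_model")
  model$S <- .stoichiometry(model)
  model$expanded <- .expand_reactions(model)
  model
}

# Net stoichiometric matrix over balanced species (rows) x reactions (cols).
.stoichiometry <- function(model) {
  S <- matrix(0, length(model$balanced), length(model$reactions),
              dimnames = list(model$balanced, names(model$reactions)))
  for (r in model$reactions) {
    for (entry in r$reactants) {
      if (entry$species %in% model$balanced) {
        S[entry$species, r$id] <- S[entry$species, r$id] - 1
      }
    }
    for (entry in r$products) {
      if (entry$species %in% model$balanced) {
        S[entry$species, r$id] <- S[entry$species, r$id] + 1
      }
    }
  }
  S
}

# One-way expansion: each reversible reaction becomes forward + backward
# (atom map mirrored). Element k carries (rxn id, direction).
.expand_reactions <- function(model) {
  out <- list()
  for (r in model$reactions) {
    out[[length(out) + 1L]] <- list(id = r$id, dir = "fwd",
                                    reactants = r$reactants,
                                    products = r$products)
    if (r$reversible) {
      out[[length(out) + 1L]] <- list(id = r$id, dir = "bwd",
                                      reactants = r$products,
                                      products = r$reactants)
    }
  }
  out
}

# Map (net, exch) named vectors to one-way fluxes over model$expanded.
# fwd = exch + max(net, 0); bwd = exch + max(-net, 0).
.oneway_fluxes <- function(model, net, exch = NULL) {
  if (is.null(exch)) exch <- stats::setNames(numeric(length(model$exch_names)),
                                             model$exch_names)
  missing_net <- setdiff(model$net_names, names(net))
  if (length(missing_net)) {
    stop("net fluxes missing for: ", paste(missing_net, collapse = ", "),
         call. = FALSE)
  }
  w <- numeric(length(model$expanded))
  for (k in seq_along(model$expanded)) {
    e <- model$expanded[[k]]
    v <- net[[e$id]]
    x <- if (e$id %in% names(exch)) exch[[e$id]] else 0
    w[k] <- if (e$dir == "fwd") x + max(v, 0) else x + max(-v, 0)
  }
  w
}

#' Null-space basis of a matrix
#'
#' Orthonormal basis of the right null space, via singular value
#' decomposition. The flux solution space of a network is the null space of
#' its balanced stoichiometric matrix.
#'
#' @param A Numeric matrix.
#' @param tol Singular values below `tol * max(sv)` count as zero.
#' @return Matrix whose columns span the null space (possibly 0 columns).
#' @export
null_space <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  rank <- sum(sv$d > tol * max(sv$d, 1e-300))
  if (rank == ncol(A)) {
    matrix(numeric(0), ncol(A), 0)
  } else {
    sv$v[, (rank + 1L):ncol(A), drop = FALSE]
  }
}

#' Structural validation report for a network
#'
#' Reports dead-end balanced species (missing a producer or a consumer),
#' the rank of the balanced stoichiometry, and the dimension of the flux
#' solution space (number of free fluxes). Report-only: no errors raised.
#'
#' @param model A `network_model`.
#' @return A list of class `network_validation` with elements
#'   `dead_ends`, `rank`, `n_fluxes`, `free_dim`, `n_exchange`.
#' @export
validate_network <- function(model) {
  stopifnot(inherits(model, "network_model"))
  produced <- consumed <- character(0)
  for (r in model$reactions) {
    consumed <- union(consumed, vapply(r$reactants, `[[`, "", "species"))
    produced <- union(produced, vapply(r$products, `[[`, "", "species"))
  }
  dead <- model$balanced[!(model$balanced %in% produced) |
                           !(model$balanced %in% consumed)]
  rk <- qr(model$S)$rank
  out <- list(dead_ends = dead,
              rank = rk,
              n_fluxes = length(model$net_names),
              free_dim = length(model$net_names) - rk,
              n_exchange = length(model$exch_names))
  class(out) <- "network_validation"
  out
}

#' @export
print.network_validation <- function(x, ...) {
  cat("Network validation\n")
  cat("  fluxes:", x$n_fluxes, "net +", x$n_exchange, "exchange\n")
  cat("  stoichiometric rank:", x$rank, " free net fluxes:", x$free_dim, "\n")
  if (length(x$dead_ends)) {
    cat("  dead-end species:", paste(x$dead_ends, collapse = ", "), "\n")
  } else {
    cat("  dead-end species: none\n")
  }
  invisible(x)
}

#' @export
print.network_model <- function(x, ...) {
  cat("Atom-mapped metabolic network\n")
  cat("  reactions:", length(x$reactions),
      sprintf("(%d reversible)", length(x$exch_names)), "\n")
  cat("  balanced species:", length(x$balanced), "\n")
  cat("  medium species:", paste(x$medium, collapse = ", "), "\n")
  if (length(x$unbalanced)) {
    cat("  unbalanced inputs:", paste(x$unbalanced, collapse = ", "), "\n")
  }
  if (length(x$symmetric)) {
    cat("  symmetric species:", paste(x$symmetric, collapse = ", "), "\n")
  }
  invisible(x)
}

# Named exchange-reaction map: medium species -> reaction id and sign
# (+1 release, -1 uptake) of the model-predicted extracellular rate.
.medium_rate_map <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (r$role == "uptake") {
      sp <- setdiff(vapply(c(r$reactants, r$products), `[[`, "", "species"),
                    model$balanced)
      sp <- intersect(sp, model$medium)
      out[[sp]] <- list(id = r$id, sign = -1)
    } else if (r$role == "release") {
      sp <- intersect(vapply(c(r$reactants, r$products), `[[`, "", "species"),
                      model$medium)
      out[[sp]] <- list(id = r$id, sign = +1)
    }
  }
  out
}

#' Check flux balance
#'
#' @param model A `network_model`.
#' @param net Named net flux vector.
#' @param tol Tolerance on `max(abs(S v))`.
#' @return `TRUE` or `FALSE`.
#' @export
flux_balanced <- function(model, net, tol = 1e-8) {
  v <- net[colnames(model$S)]
  max(abs(model$S %*% v)) <= tol
}
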