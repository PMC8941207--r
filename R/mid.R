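# Natural isotope abundances used for theoretical MIDs of derivatized
# fragments. Values are fractional abundances ordered by mass shift
# (+0, +1, +2, ...). Silicon matters because TBDMS derivatives carry
# one or two Si atoms whose +1/+2 isotopes are far from negligible.
.isotope_table <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.9222, 0.0468, 0.0310),
  P  = c(1.0),
  S  = c(0.9499, 0.0075, 0.0425)
)

#' Natural-abundance 13C fraction
#'
#' Fractional abundance of carbon-13 used when simulating skeleton carbons
#' that are not enriched by the tracer.
#' @return A single number (0.0107).
#' @export
natural_13c <- function() .isotope_table$C[2]

# Convolve two mass distributions (polynomial multiplication).
.conv <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# n-fold convolution power of a distribution.
.conv_pow <- function(a, n) {
  out <- 1
  p <- a
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .conv(out, p)
    p <- .conv(p, p)
    n <- n %/% 2L
  }
  out
}

#' Convolve two mass isotopomer distributions
#'
#' The MID of a molecule assembled from two independent moieties is the
#' convolution of the moiety MIDs.
#'
#' @param a,b Numeric vectors of fractional abundances (M+0, M+1, ...).
#' @return Numeric vector of length `length(a) + length(b) - 1`.
#' @export
mid_convolve <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  .conv(a, b)
}

#' Parse an elemental formula
#'
#' Parses strings such as `"C9H18NO2Si"` into named atom counts. Only
#' elements with tabulated isotope abundances (C, H, N, O, Si, P, S) are
#' accepted.
#'
#' @param formula A formula string; `""` denotes the empty formula.
#' @return Named integer vector of atom counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(length(formula) == 1L)
  if (is.na(formula)) formula <- ""
  formula <- gsub("\\s", "", as.character(formula))
  if (formula == "" || formula == "-") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- integer(0)
  for (p in pieces) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (n == "") 1L else as.integer(n)
    if (!el %in% names(.isotope_table)) {
      stop("unknown element '", el, "' in formula: ", formula, call. = FALSE)
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  if (any(counts < 0)) stop("negative atom count", call. = FALSE)
  counts
}

#' Theoretical natural-abundance MID of an elemental composition
#'
#' Computes the isotopologue distribution expected from naturally occurring
#' heavy isotopes by multinomial convolution across atoms. This is the
#' reference distribution against which unlabeled standards are compared
#' when assessing GC-MS measurement uncertainty, and the derivative
#' contribution convolved into simulated fragment MIDs.
#'
#' @param formula Elemental formula string (e.g. `"C6H12O6"`) or a named
#'   count vector as returned by [parse_formula()].
#' @param max_shift Truncate the returned distribution at this mass shift
#'   (default: full length).
#' @return Numeric vector of fractional abundances (M+0, M+1, ...), summing
#'   to 1 over the untruncated distribution.
#' @examples
#' natural_mid("C3")[2]  # ~ 3 * 0.0107 * 0.9893^2
#' @export
natural_mid <- function(formula, max_shift = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  out <- 1
  for (el in names(counts)) {
    if (counts[[el]] > 0L) {
      out <- .conv(out, .conv_pow(.isotope_table[[el]], counts[[el]]))
    }
  }
  if (length(out) == 1L) out <- c(1)
  if (!is.null(max_shift)) out <- out[seq_len(min(length(out), max_shift + 1L))]
  out
}

#' Root-mean-square deviation between two MIDs
#'
#' Used to quantify measurement uncertainty from unlabeled standards: the
#' RMSD between a measured MID and the theoretical natural-abundance MID.
#'
#' @param measured,reference Numeric vectors of equal length.
#' @return A single nonnegative number.
#' @export
mid_rmsd <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    stop("MID length mismatch: ", length(measured), " vs ", length(reference),
         call. = FALSE)
  }
  sqrt(mean((measured - reference)^2))
}

# Memoized natural MIDs for derivative formulas (hot path in fitting).
.nat_mid_cache <- new.env(parent = emptyenv())
.natural_mid_cached <- function(formula) {
  if (is.na(formula)) formula <- ""
  key <- paste0("f:", formula)
  hit <- .nat_mid_cache[[key]]
  if (is.null(hit)) {
    hit <- natural_mid(formula)
    assign(key, hit, envir = .nat_mid_cache)
  }
  hit
}

# Validate / renormalize an MID vector.
.check_mid <- function(x, tol = 1e-6, what = "MID") {
  if (any(x < -1e-9)) stop(what, " has negative entries", call. = FALSE)
  s <- sum(x)
  if (abs(s - 1) > tol) {
    stop(what, " sums to ", format(s), ", not 1", call. = FALSE)
  }
  x / s
}
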