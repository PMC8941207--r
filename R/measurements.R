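# Measurement sets for flux regression: fragment MIDs per tracer with
# standard errors, plus extracellular exchange rates (nmol/10^6 cells/h;
# negative = uptake, positive = excretion).

.new_measurement_set <- function(mids, rates) {
  stopifnot(all(c("fragment", "tracer", "mass", "value", "se") %in% names(mids)),
            all(c("metabolite", "value", "se") %in% names(rates)))
  if (any(mids$se <= 0) || any(rates$se <= 0)) {
    stop("every measurement standard error must be > 0", call. = FALSE)
  }
  key <- paste(mids$fragment, mids$tracer)
  for (k in unique(key)) {
    s <- sum(mids$value[key == k])
    if (abs(s - 1) > 1e-6) {
      stop("MID of ", k, " sums to ", format(s), ", not 1", call. = FALSE)
    }
  }
  structure(list(mids = mids, rates = rates), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("Measurement set\n")
  cat("  fragment MIDs:", length(unique(paste(x$mids$fragment, x$mids$tracer))),
      "(", length(unique(x$mids$fragment)), "fragments x",
      length(unique(x$mids$tracer)), "tracer(s) )\n")
  cat("  extracellular rates:", nrow(x$rates), "\n")
  invisible(x)
}

# Standard error of the mean across replicates.
.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Assemble a measurement set with the max(RMSD, SEM) error model
#'
#' Builds the weighted measurement set used by [fit_fluxes()]. The standard
#' error of each MID element is the larger of (a) the root-mean-square
#' deviation between unlabeled control samples and the theoretical
#' natural-abundance MID of the derivatized fragment, and (b) the standard
#' error of the mean across biological replicates. Rate standard errors are
#' replicate SEMs.
#'
#' @param mids Long data frame of replicate MID measurements with columns
#'   `fragment`, `tracer`, `replicate`, `mass`, `value`.
#' @param controls Long data frame of unlabeled control MIDs with columns
#'   `fragment`, `replicate`, `mass`, `value`, or `NULL` if unavailable.
#' @param rates Data frame of replicate rates with columns `metabolite`,
#'   `replicate`, `value` (nmol/10^6 cells/h, excretion positive).
#' @param fragments `fragment_table` used to compute theoretical natural
#'   MIDs for the controls.
#' @param window Mass-window width (must match the measured tables).
#' @param se_floor Lower bound applied to all standard errors (default
#'   1e-4) so that no channel gets infinite weight.
#' @return A `measurement_set`.
#' @export
assemble_errors <- function(mids, controls = NULL, rates, fragments,
                            window = 2L, se_floor = 1e-4) {
  have_reps <- length(unique(mids$replicate)) >= 2L
  if (is.null(controls) && !have_reps) {
    stop("need unlabeled controls or >= 2 replicates to set MID errors",
         call. = FALSE)
  }
  # control RMSD per fragment
  rmsd <- stats::setNames(rep(NA_real_, nrow(fragments)), fragments$fragment)
  if (!is.null(controls)) {
    for (i in seq_len(nrow(fragments))) {
      fr <- fragments$fragment[i]
      sub <- controls[controls$fragment == fr, , drop = FALSE]
      if (!nrow(sub)) next
      theo <- fragment_mid(natural_mid(paste0("C", length(fragments$carbons[[i]]))),
                           fragments$derivative_formula[i], window = window,
                           warn_loss = Inf)
      devs <- unlist(lapply(split(sub, sub$replicate), function(d) {
        d <- d[order(d$mass), ]
        d$value - theo[d$mass + 1L]
      }))
      rmsd[fr] <- sqrt(mean(devs^2))
    }
  }
  agg <- stats::aggregate(value ~ fragment + tracer + mass, mids, mean)
  sems <- stats::aggregate(value ~ fragment + tracer + mass, mids,
                           function(x) if (length(x) >= 2L) .sem(x) else NA_real_)
  agg$se <- pmax(sems$value, rmsd[agg$fragment], se_floor, na.rm = TRUE)
  # renormalize mean MIDs (noise may leave sums slightly off 1)
  key <- paste(agg$fragment, agg$tracer)
  for (k in unique(key)) {
    sel <- key == k
    agg$value[sel] <- agg$value[sel] / sum(agg$value[sel])
  }
  r_mean <- stats::aggregate(value ~ metabolite, rates, mean)
  r_sem <- stats::aggregate(value ~ metabolite, rates,
                            function(x) if (length(x) >= 2L) .sem(x) else NA_real_)
  if (anyNA(r_sem$value)) {
    stop("rate measurements need >= 2 replicates for SEM", call. = FALSE)
  }
  r_mean$se <- pmax(r_sem$value, se_floor)
  .new_measurement_set(agg[order(agg$tracer, agg$fragment, agg$mass), ],
                       r_mean)
}

#' Load a measurement set from delimited files
#'
#' Reads wide-format tables: the MID file has columns `fragment`, `tracer`,
#' `M0...Mn`, `SE0...SEn`; the rate file has `metabolite`, `rate`, `se`.
#' MIDs off 1 by less than `1e-6` are renormalized; larger deviations are
#' an error, as are duplicated fragment/tracer rows.
#'
#' @param mid_path,rate_path File paths (TSV).
#' @return A `measurement_set`.
#' @export
load_measurements <- function(mid_path, rate_path) {
  wide <- utils::read.delim(mid_path, stringsAsFactors = FALSE,
                            comment.char = "#")
  key <- paste(wide$fragment, wide$tracer, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated fragment/tracer row: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  mcols <- grep("^M[0-9]+$", names(wide), value = TRUE)
  scols <- grep("^SE[0-9]+$", names(wide), value = TRUE)
  if (!length(mcols) || length(mcols) != length(scols)) {
    stop("MID file needs matching M0..Mn and SE0..SEn columns", call. = FALSE)
  }
  mcols <- mcols[order(as.integer(sub("M", "", mcols)))]
  scols <- scols[order(as.integer(sub("SE", "", scols)))]
  rows <- list()
  for (i in seq_len(nrow(wide))) {
    vals <- as.numeric(wide[i, mcols])
    ses <- as.numeric(wide[i, scols])
    ok <- !is.na(vals)
    s <- sum(vals[ok])
    if (abs(s - 1) > 1e-6) {
      stop("MID of ", key[i], " sums to ", format(s), ", not 1",
           call. = FALSE)
    }
    rows[[i]] <- data.frame(fragment = wide$fragment[i],
                            tracer = wide$tracer[i],
                            mass = which(ok) - 1L,
                            value = vals[ok] / s, se = ses[ok])
  }
  mids <- do.call(rbind, rows)
  rt <- utils::read.delim(rate_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (!all(c("metabolite", "rate", "se") %in% names(rt))) {
    stop("rate file needs columns metabolite, rate, se", call. = FALSE)
  }
  rates <- data.frame(metabolite = rt$metabolite, value = rt$rate, se = rt$se)
  .new_measurement_set(mids, rates)
}

#' Write a measurement set to delimited files
#'
#' Inverse of [load_measurements()].
#' @param ms A `measurement_set`.
#' @param mid_path,rate_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_measurements <- function(ms, mid_path, rate_path) {
  maxm <- max(ms$mids$mass)
  key <- unique(ms$mids[c("fragment", "tracer")])
  out <- key
  for (m in 0:maxm) {
    out[[paste0("M", m)]] <- NA_real_
    out[[paste0("SE", m)]] <- NA_real_
  }
  for (i in seq_len(nrow(key))) {
    sub <- ms$mids[ms$mids$fragment == key$fragment[i] &
                     ms$mids$tracer == key$tracer[i], ]
    for (j in seq_len(nrow(sub))) {
      out[i, paste0("M", sub$mass[j])] <- sub$value[j]
      out[i, paste0("SE", sub$mass[j])] <- sub$se[j]
    }
  }
  utils::write.table(out, mid_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  rt <- data.frame(metabolite = ms$rates$metabolite, rate = ms$rates$value,
                   se = ms$rates$se)
  utils::write.table(rt, rate_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(mid_path, rate_path))
}
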