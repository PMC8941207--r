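# Futile glucose cycling from a [2H7]glucose medium-labeling experiment.
#
# Cells fed [1,2,3,4,5,6,6-2H7]glucose phosphorylate it via glucokinase;
# glucose-6-phosphate that re-emerges as glucose through glucose-6-
# phosphatase (G6PC2) has exchanged the C2 deuterium with water at the
# phosphoglucose-isomerase step and therefore appears in the medium as an
# M+6 species. The cycled fraction r(t) is the baseline-corrected M+6
# abundance of medium glucose; its production rate, normalized to the
# integrated viable cell density, estimates the G6P -> glucose release
# flux, and cycling_percent = 100 * V_release / V_total_uptake.

#' Assemble a glucose cycling experiment
#'
#' @param time Times (h), increasing, starting at 0.
#' @param mids Matrix (length(time) x 8) of medium glucose MIDs
#'   (M+0 ... M+7), each row summing to 1.
#' @param conc Total medium glucose concentrations (mM) at `time`.
#' @param cells Viable cell counts at `time`.
#' @param volume Medium volume (ml).
#' @param glucose_mM Condition label (nominal 5 or 11 mM).
#' @return A `cycling_experiment`.
#' @export
cycling_experiment <- function(time, mids, conc, cells, volume,
                               glucose_mM = conc[1]) {
  mids <- as.matrix(mids)
  stopifnot(nrow(mids) == length(time), ncol(mids) == 8L,
            length(conc) == length(time), length(cells) == length(time))
  if (is.unsorted(time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (length(time) < 2L) stop("need >= 2 time points", call. = FALSE)
  mids <- t(apply(mids, 1, .check_mid, tol = 1e-3, what = "glucose MID"))
  structure(list(time = time, mids = mids, conc = conc, cells = cells,
                 volume = volume, glucose_mM = glucose_mM),
            class = "cycling_experiment")
}

#' Cycled (recycled-glucose) fraction over time
#'
#' The abundance of the partially deuterated M+6 species, corrected for
#' its baseline at t = 0 (natural/impurity background). Warns when the
#' baseline itself exceeds 2%, indicating a contaminated tracer batch.
#'
#' @param experiment A `cycling_experiment`.
#' @return Data frame with `time` and cycled fraction `r`.
#' @export
cycled_fraction <- function(experiment) {
  stopifnot(inherits(experiment, "cycling_experiment"))
  m6 <- experiment$mids[, 7]
  if (m6[1] > 0.02) {
    warning(sprintf("M+6 baseline is %.3f (> 0.02): contaminated baseline?",
                    m6[1]))
  }
  data.frame(time = experiment$time, r = m6 - m6[1])
}

#' Glucose cycling and uptake rates
#'
#' Estimates, per 10^6 cells: the recycled-glucose release rate
#' `V_release` from the appearance rate of the M+6 species (corrected for
#' its re-uptake), the net glucose disappearance rate `V_net_uptake`, the
#' total phosphorylation rate `V_total_uptake = V_net + V_release`, and
#' `cycling_percent = 100 * V_release / V_total_uptake`.
#'
#' @param experiment A `cycling_experiment`.
#' @param growth Optional `growth_fit`; defaults to a fit of the
#'   experiment's own cell counts (or constant density with 2 points).
#' @param horizon Use time points up to this horizon (h, default 24).
#' @return A `cycling_rates` list with the four quantities (rates in
#'   nmol/10^6 cells/h) plus the cycled-fraction course.
#' @export
cycling_rates <- function(experiment, growth = NULL, horizon = 24) {
  stopifnot(inherits(experiment, "cycling_experiment"))
  keep <- experiment$time <= horizon + 1e-9
  tt <- experiment$time[keep]
  conc <- experiment$conc[keep]
  cells <- experiment$cells[keep]
  rfrac <- cycled_fraction(experiment)$r[keep]
  if (is.null(growth)) {
    growth <- if (length(tt) >= 3L) {
      fit_growth(tt, cells)
    } else {
      structure(list(x0 = cells[1], mu = 0,
                     integral = function(t1, t2) cells[1] * (t2 - t1)),
                class = "growth_fit")
    }
  }
  V <- experiment$volume
  nX <- growth$integral(tt[1], tt[length(tt)]) / 1e6   # 10^6 cell-hours
  if (nX <= 0) stop("integrated cell density is zero", call. = FALSE)

  amount <- conc * V * 1000                       # nmol of glucose
  a6 <- amount * rfrac                            # nmol of recycled species
  # net uptake from total glucose disappearance
  v_net <- -(amount[length(tt)] - amount[1]) / nX
  # release rate from M+6 appearance, iteratively corrected for the
  # re-uptake of already-recycled glucose (second-order at small r)
  xgrid <- vapply(tt, function(t2) growth$integral(tt[1], t2), 0) / 1e6
  int_xr <- sum(diff(xgrid) *
                  (utils::head(rfrac, -1) + utils::tail(rfrac, -1)) / 2)
  v_rel <- (a6[length(tt)] - a6[1]) / nX
  for (i in 1:5) {
    v_tot <- v_net + v_rel
    v_rel <- ((a6[length(tt)] - a6[1]) + v_tot * int_xr * 1) / nX
  }
  v_tot <- v_net + v_rel
  if (v_tot <= 0) {
    stop("total glucose uptake is nonpositive (net glucose production); ",
         "report V_release alone", call. = FALSE)
  }
  structure(list(V_release = v_rel, V_net_uptake = v_net,
                 V_total_uptake = v_tot,
                 cycling_percent = 100 * v_rel / v_tot,
                 cycled = data.frame(time = tt, r = rfrac),
                 horizon = horizon),
            class = "cycling_rates")
}

#' @export
print.cycling_rates <- function(x, ...) {
  cat(sprintf("Glucose cycling over %g h:\n", x$horizon))
  cat(sprintf("  V_release       %8.3f nmol/10^6 cells/h\n", x$V_release))
  cat(sprintf("  V_net_uptake    %8.3f nmol/10^6 cells/h\n", x$V_net_uptake))
  cat(sprintf("  V_total_uptake  %8.3f nmol/10^6 cells/h\n", x$V_total_uptake))
  cat(sprintf("  cycling         %8.2f %%\n", x$cycling_percent))
  invisible(x)
}

#' Simulate a [2H7]glucose cycling experiment
#'
#' Forward model: cells take up medium glucose (all mass species
#' proportionally) at a total per-cell rate `v_total`, and release a
#' fraction `cycling_percent/100` of it back as the M+6 species. Medium
#' amounts evolve by fine-step Euler integration under exponential growth;
#' measured MIDs optionally receive truncated-Gaussian noise and are
#' renormalized.
#'
#' @param cycling_percent Ground-truth cycling percentage (0-100).
#' @param v_total Total glucose phosphorylation rate (nmol/10^6 cells/h).
#' @param glucose_mM Initial medium glucose (mM).
#' @param time Sampling times (h).
#' @param x0,mu Initial cell count and growth rate (1/h).
#' @param volume Medium volume (ml).
#' @param purity Per-position deuterium enrichment of the tracer; the
#'   initial medium MID is binomial across the 7 labeled positions.
#' @param mid_sd MID measurement noise (per channel, truncated at 0, then
#'   renormalized); 0 for noise-free.
#' @param seed Optional seed applied when `mid_sd > 0`.
#' @return A `cycling_experiment`.
#' @export
simulate_cycling <- function(cycling_percent, v_total, glucose_mM = 5,
                             time = c(0, 6, 12, 18, 24), x0 = 8e6,
                             mu = 0.01, volume = 6, purity = 0.998,
                             mid_sd = 0, seed = NULL) {
  stopifnot(cycling_percent >= 0, cycling_percent < 100, v_total > 0)
  if (!is.null(seed)) set.seed(seed)
  mid0 <- .conv_pow(c(1 - purity, purity), 7)   # M+0..M+7 of the tracer
  amounts <- glucose_mM * volume * 1000 * mid0  # nmol per mass species
  v_rel_frac <- cycling_percent / 100
  dt <- 0.005
  tmax <- max(time)
  out_mid <- matrix(NA_real_, length(time), 8)
  out_conc <- numeric(length(time))
  record <- function(i) {
    tot <- sum(amounts)
    out_mid[i, ] <<- amounts / tot
    out_conc[i] <<- tot / (volume * 1000)
  }
  ti <- 1L
  t <- 0
  while (TRUE) {
    if (ti <= length(time) && t >= time[ti] - dt / 2) {
      record(ti); ti <- ti + 1L
    }
    if (t >= tmax) break
    X <- x0 * exp(mu * t) / 1e6
    tot <- sum(amounts)
    uptake <- v_total * X * dt * amounts / tot
    amounts <- amounts - uptake
    amounts[7] <- amounts[7] + v_rel_frac * v_total * X * dt
    t <- t + dt
  }
  if (mid_sd > 0) {
    noisy <- pmax(out_mid + matrix(stats::rnorm(length(out_mid), 0, mid_sd),
                                   nrow(out_mid)), 0)
    out_mid <- noisy / rowSums(noisy)
  }
  cycling_experiment(time, out_mid, out_conc,
                     cells = x0 * exp(mu * time), volume = volume,
                     glucose_mM = glucose_mM)
}
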