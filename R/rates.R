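# Cell-specific uptake/excretion rates from medium concentration time
# courses and viable cell counts. The estimator regresses the
# degradation-corrected extracellular amount against the integrated viable
# cell density, whose slope is the specific rate q (exact when growth is
# exponential and q is constant). Sign convention: excretion positive,
# uptake negative.

#' Fit exponential growth to viable cell counts
#'
#' Log-linear regression of counts on time. The fit exposes the integral
#' of cell density over arbitrary intervals, which the rate estimator uses
#' as its regressor.
#'
#' @param time Times (h).
#' @param counts Viable cell counts (> 0).
#' @return A `growth_fit` with `x0` (cells at t = 0), `mu` (specific
#'   growth rate, 1/h), `se_mu`, `r_squared`, and function `integral(t1,
#'   t2)` returning cell-hours.
#' @export
fit_growth <- function(time, counts) {
  stopifnot(length(time) == length(counts))
  if (length(time) < 3L) stop("need >= 3 counts for a growth fit",
                              call. = FALSE)
  if (any(counts <= 0)) stop("nonpositive cell count", call. = FALSE)
  fit <- stats::lm(log(counts) ~ time)
  mu <- unname(stats::coef(fit)[2])
  x0 <- exp(unname(stats::coef(fit)[1]))
  integral <- function(t1, t2) {
    if (abs(mu) < 1e-12) x0 * (t2 - t1)
    else x0 * (exp(mu * t2) - exp(mu * t1)) / mu
  }
  sm <- suppressWarnings(summary(fit))  # noise-free courses fit exactly
  structure(list(x0 = x0, mu = mu,
                 se_mu = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 integral = integral),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: X0 = %.3g cells, mu = %.4g /h (doubling %.1f h), R^2 = %.3f\n",
              x$x0, x$mu, log(2) / x$mu, x$r_squared))
  invisible(x)
}

#' First-order degradation rate from a cell-free time course
#'
#' Log-linear fit of concentration against time in control, cell-free
#' dishes; used for spontaneously degrading metabolites such as glutamine
#' (decay to ammonia and pyrrolidone carboxylate).
#'
#' @param time Times (h).
#' @param conc Concentrations (> 0).
#' @param tol Warn when the log-course departs from linearity by more than
#'   `tol` (RMS of residuals, log units).
#' @return First-order rate constant k (1/h; >= 0 means decay).
#' @export
estimate_degradation <- function(time, conc, tol = 0.05) {
  stopifnot(length(time) == length(conc))
  if (any(conc <= 0)) stop("nonpositive concentration", call. = FALSE)
  fit <- stats::lm(log(conc) ~ time)
  k <- -unname(stats::coef(fit)[2])
  if (sqrt(mean(stats::resid(fit)^2)) > tol) {
    warning("cell-free course departs from first-order decay beyond tolerance")
  }
  k
}

#' Cell-specific uptake or excretion rate from a time course
#'
#' Regresses the cumulative degradation-corrected extracellular amount
#' `A(t) = C(t) V + k_deg * integral(C V dt)` on the integrated viable cell
#' density from a [fit_growth()] fit; the slope is the specific rate q in
#' nmol/10^6 cells/h (excretion positive, uptake negative). Evaporation
#' may be modeled as a constant fractional volume-loss rate (negligible in
#' practice, default 0).
#'
#' @param time Times (h).
#' @param conc Metabolite concentrations (mM) at `time`; may contain one
#'   value per time-replicate combination (supply `replicate`).
#' @param growth A `growth_fit`.
#' @param volume Medium volume (ml; scalar).
#' @param k_deg First-order degradation rate (1/h).
#' @param k_evap Fractional volume-loss rate (1/h).
#' @param replicate Optional replicate labels, same length as `time`.
#' @return A `specific_rate` list with `q` (nmol/10^6 cells/h), `se`,
#'   `n`, and the regression inputs.
#' @export
specific_rate <- function(time, conc, growth, volume, k_deg = 0,
                          k_evap = 0, replicate = NULL) {
  stopifnot(length(time) == length(conc), inherits(growth, "growth_fit"))
  if (is.null(replicate)) replicate <- rep(1L, length(time))
  ord <- order(replicate, time)
  time <- time[ord]; conc <- conc[ord]; replicate <- replicate[ord]
  amount <- degint <- numeric(length(time))
  for (rp in unique(replicate)) {
    sel <- which(replicate == rp)
    tt <- time[sel]
    vol <- volume * exp(-k_evap * (tt - tt[1]))
    a <- conc[sel] * vol * 1000            # mM * ml -> nmol
    # cumulative trapezoidal integral of k_deg * C * V
    cum <- c(0, cumsum(diff(tt) * (utils::head(a, -1) + utils::tail(a, -1)) / 2))
    amount[sel] <- a
    degint[sel] <- k_deg * cum
  }
  x <- vapply(seq_along(time), function(i) {
    growth$integral(min(time), time[i]) / 1e6   # 10^6 cell-hours
  }, 0)
  if (max(x) <= 0) stop("integrated cell density is zero", call. = FALSE)
  y <- amount + degint
  fit <- stats::lm(y ~ x)
  structure(list(q = unname(stats::coef(fit)[2]),
                 se = suppressWarnings(summary(fit))$coefficients[2, 2],
                 n = length(time),
                 data = data.frame(time = time, replicate = replicate,
                                   amount = y, cell_hours = x)),
            class = "specific_rate")
}

#' @export
print.specific_rate <- function(x, ...) {
  cat(sprintf("Specific rate q = %.4g +/- %.2g nmol/10^6 cells/h (n = %d; %s)\n",
              x$q, x$se, x$n,
              if (x$q >= 0) "net excretion" else "net uptake"))
  invisible(x)
}

#' Estimate all rates from a long-format time-course table
#'
#' Convenience wrapper over [fit_growth()] and [specific_rate()] for a
#' table with columns `time_h`, `metabolite`, `conc_mM`, `cells`,
#' `volume_ml`, `replicate`.
#'
#' @param tc Time-course data frame.
#' @param k_deg Named vector of degradation rates (1/h) per metabolite;
#'   missing entries default to 0.
#' @return List with the `growth_fit` and a data frame `rates`
#'   (`metabolite`, `q`, `se`).
#' @export
estimate_exchange_rates <- function(tc, k_deg = c()) {
  need <- c("time_h", "metabolite", "conc_mM", "cells", "volume_ml",
            "replicate")
  if (!all(need %in% names(tc))) {
    stop("time-course table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cc <- unique(tc[c("time_h", "replicate", "cells")])
  growth <- fit_growth(cc$time_h, cc$cells)
  mets <- unique(tc$metabolite)
  rows <- lapply(mets, function(m) {
    sub <- tc[tc$metabolite == m, ]
    k <- if (m %in% names(k_deg)) k_deg[[m]] else 0
    sr <- specific_rate(sub$time_h, sub$conc_mM, growth,
                        volume = sub$volume_ml[1], k_deg = k,
                        replicate = sub$replicate)
    data.frame(metabolite = m, q = sr$q, se = sr$se)
  })
  list(growth = growth, rates = do.call(rbind, rows))
}
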