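# Weighted least-squares flux regression against isotope labeling and
# exchange-rate measurements, fitted jointly over parallel tracers.
#
# Parameterization: net fluxes live in the null space of the balanced
# stoichiometry (v = N u); each reversible reaction additionally carries a
# nonnegative exchange flux, optimized on the bounded transform
# t = x / (x + scale) in [0, 0.99]. Irreversibility and flux bounds are
# enforced through penalty residuals, so the optimizer (Levenberg-
# Marquardt, with a derivative-free polish fallback) searches a box.

.exch_from_t <- function(t, scale) scale * t / (1 - t)
.t_from_exch <- function(x, scale) x / (x + scale)

# Precompute the residual map for a model + measurement set.
.make_objective <- function(model, emus, fragments, measurements, tracers,
                            N, exch_scale, vmax, nat13c, window,
                            pen_weight = 1e3) {
  mids <- measurements$mids[measurements$mids$mass >= 1L, , drop = FALSE]
  tr_names <- names(tracers)
  if (!all(unique(mids$tracer) %in% tr_names)) {
    stop("measurement tracers not all present in `tracers`: ",
         paste(setdiff(unique(mids$tracer), tr_names), collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(tr_names, function(tn) {
    sub <- mids[mids$tracer == tn, , drop = FALSE]
    list(tracer = tracers[[tn]], fragment = sub$fragment,
         mass = sub$mass, value = sub$value, se = sub$se)
  })
  names(blocks) <- tr_names
  rmap <- .medium_rate_map(model)
  rk <- measurements$rates$metabolite
  bad <- rk[!rk %in% names(rmap)]
  if (length(bad)) {
    stop("measured rate for species without uptake/release reaction: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rate_rxn <- vapply(rk, function(s) rmap[[s]]$id, "")
  rate_sign <- vapply(rk, function(s) rmap[[s]]$sign, 0)
  irrev <- setdiff(model$net_names, model$exch_names)
  n_meas <- sum(vapply(blocks, function(b) length(b$value), 0L)) +
    nrow(measurements$rates)
  f <- ncol(N)
  e <- length(model$exch_names)

  resid_fn <- function(par) {
    u <- par[seq_len(f)]
    t <- par[f + seq_len(e)]
    t <- pmin(pmax(t, 0), 0.99)
    v <- drop(N %*% u)
    names(v) <- model$net_names
    exch <- stats::setNames(.exch_from_t(t, exch_scale), model$exch_names)
    pen <- pen_weight / vmax * c(pmax(0, -v[irrev]), pmax(0, abs(v) - vmax))
    out <- tryCatch({
      res <- numeric(0)
      for (b in blocks) {
        sim <- simulate_fragments(model, emus, v, exch, b$tracer, fragments,
                                  nat13c = nat13c, window = window)
        simv <- vapply(seq_along(b$value), function(i) {
          sim[[b$fragment[i]]][b$mass[i] + 1L]
        }, 0)
        res <- c(res, (simv - b$value) / b$se)
      }
      vr <- rate_sign * v[rate_rxn]
      res <- c(res, (vr - measurements$rates$value) / measurements$rates$se)
      res
    }, error = function(err) rep(1e4, n_meas))
    c(out, pen)
  }
  list(resid = resid_fn, n_meas = n_meas, f = f, e = e, irrev = irrev,
       rate_rxn = rate_rxn, rate_sign = rate_sign, blocks = blocks)
}

#' Fit metabolic fluxes to parallel-tracer measurements
#'
#' Estimates net and exchange fluxes by minimizing the variance-weighted
#' sum of squared residuals (SSR) between model-simulated and measured
#' fragment MIDs (all tracers jointly, M+0 excluded as redundant) and
#' extracellular exchange rates. Optimization is repeated from `n_starts`
#' randomized initial guesses (net candidates drawn log-uniformly within
#' the flux bounds) and the best solution is retained.
#'
#' @param model A `network_model`.
#' @param fragments A `fragment_table` covering all measured fragments.
#' @param measurements A `measurement_set`.
#' @param tracers Named list of [tracer_spec()]s; names must match the
#'   `tracer` labels in the measurement set.
#' @param n_starts Number of randomized restarts (>= 1; 25 or more is
#'   recommended to claim a global solution).
#' @param seed Integer seed controlling the restart draws (recorded in the
#'   result; same seed + same `n_starts` reproduces the restart log).
#' @param vmax Upper flux bound; default 10x the largest measured rate
#'   magnitude.
#' @param exch_scale Scale of the bounded exchange transform
#'   `x = scale * t / (1 - t)`; default `vmax / 10`.
#' @param nat13c Natural 13C abundance for non-tracer skeleton carbons.
#' @param window Measurement-space mass window (see [fragment_mid()]).
#' @param emus Optional precomputed `emu_system` (else derived from
#'   `fragments`).
#' @param init Optional list of starting values `list(net = , exch = )`
#'   prepended to the randomized starts.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `mfa_fit` with components `net`, `exch`
#'   (named flux vectors, nmol/10^6 cells/h), `ssr`, `dof`, `restarts`,
#'   `cov` (linearized covariance of net fluxes), and the model context.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `deviance`, `df.residual`, `confint`, `plot`.
#' @export
fit_fluxes <- function(model, fragments, measurements, tracers,
                       n_starts = 25L, seed = 1L, vmax = NULL,
                       exch_scale = NULL, nat13c = natural_13c(),
                       window = 2L, emus = NULL, init = NULL,
                       control = NULL) {
  stopifnot(inherits(model, "network_model"),
            inherits(measurements, "measurement_set"), n_starts >= 1L)
  if (is.null(emus)) emus <- emu_decompose(model, fragments)
  N <- null_space(model$S)
  if (ncol(N) == 0L) stop("network has no free fluxes", call. = FALSE)
  if (is.null(vmax)) vmax <- 10 * max(abs(measurements$rates$value))
  if (is.null(exch_scale)) exch_scale <- vmax / 10
  obj <- .make_objective(model, emus, fragments, measurements, tracers,
                         N, exch_scale, vmax, nat13c, window)
  f <- obj$f; e <- obj$e
  lower <- c(rep(-vmax * sqrt(ncol(model$S) + 1), f), rep(0, e))
  upper <- c(rep(vmax * sqrt(ncol(model$S) + 1), f), rep(0.99, e))
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  c(list(), if (is.null(control))
                    list(maxiter = 200, ftol = 1e-12, ptol = 1e-10)
                    else control))

  set.seed(seed)
  starts <- list()
  if (!is.null(init)) {
    u0 <- drop(crossprod(N, init$net[model$net_names]))
    t0 <- rep(0.1, e)
    if (!is.null(init$exch)) {
      t0 <- .t_from_exch(
        vapply(model$exch_names,
               function(nm) if (nm %in% names(init$exch)) init$exch[[nm]] else 0,
               0), exch_scale)
    }
    starts[[1]] <- c(u0, pmin(t0, 0.95))
  }
  while (length(starts) < n_starts) {
    vc <- exp(stats::runif(length(model$net_names),
                           log(1e-3 * vmax), log(vmax)))
    sgn <- ifelse(model$net_names %in% model$exch_names,
                  sample(c(-1, 1), length(vc), replace = TRUE), 1)
    u0 <- drop(crossprod(N, vc * sgn))
    t0 <- stats::runif(e, 0, 0.9)
    starts[[length(starts) + 1L]] <- c(u0, t0)
  }

  best <- NULL
  log_rows <- list()
  for (si in seq_along(starts)) {
    fitk <- tryCatch(
      minpack.lm::nls.lm(par = starts[[si]], lower = lower, upper = upper,
                         fn = obj$resid, control = ctrl),
      error = function(err) NULL)
    if (is.null(fitk)) {
      log_rows[[si]] <- data.frame(start = si, ssr = NA_real_,
                                   converged = FALSE, niter = NA_integer_)
      next
    }
    r <- obj$resid(fitk$par)
    ssr_k <- sum(r[seq_len(obj$n_meas)]^2)
    feasible <- sum(r[-seq_len(obj$n_meas)]^2) < 1e-6
    log_rows[[si]] <- data.frame(start = si, ssr = ssr_k,
                                 converged = fitk$info %in% 1:4 && feasible,
                                 niter = fitk$niter)
    if (feasible && (is.null(best) || ssr_k < best$ssr)) {
      best <- list(par = fitk$par, ssr = ssr_k, hessian = fitk$hessian)
    }
  }
  restarts <- do.call(rbind, log_rows)
  if (is.null(best)) {
    stop("no restart converged to a feasible flux solution; restart log:\n",
         paste(utils::capture.output(print(restarts)), collapse = "\n"),
         call. = FALSE)
  }

  u <- best$par[seq_len(f)]
  tt <- best$par[f + seq_len(e)]
  net <- stats::setNames(drop(N %*% u), model$net_names)
  exch <- stats::setNames(.exch_from_t(tt, exch_scale), model$exch_names)
  dof <- obj$n_meas - (f + e)

  # linearized covariance of the free parameters; near-zero curvature
  # directions are structurally unidentifiable
  cov_par <- tryCatch({
    H <- best$hessian
    sv <- svd(H)
    pos <- sv$d > max(sv$d) * 1e-10
    Vp <- sv$v[, pos, drop = FALSE]
    Vp %*% diag(1 / sv$d[pos], sum(pos)) %*% t(Vp)
  }, error = function(err) matrix(NA_real_, f + e, f + e))
  cov_net <- N %*% cov_par[seq_len(f), seq_len(f), drop = FALSE] %*% t(N)
  dimnames(cov_net) <- list(model$net_names, model$net_names)

  structure(list(net = net, exch = exch, ssr = best$ssr, dof = dof,
                 n_meas = obj$n_meas, par = best$par, restarts = restarts,
                 seed = seed, vmax = vmax, exch_scale = exch_scale,
                 nat13c = nat13c, window = window,
                 cov_net = cov_net, cov_par = cov_par,
                 model = model, emus = emus, fragments = fragments,
                 measurements = measurements, tracers = tracers,
                 N = N, objective = obj),
            class = "mfa_fit")
}

#' @export
coef.mfa_fit <- function(object, ...) {
  c(object$net,
    stats::setNames(object$exch, paste0(names(object$exch), ".exch")))
}

#' @export
deviance.mfa_fit <- function(object, ...) object$ssr

#' @export
df.residual.mfa_fit <- function(object, ...) object$dof

#' @export
residuals.mfa_fit <- function(object, ...) {
  r <- object$objective$resid(object$par)
  r[seq_len(object$n_meas)]
}

#' @export
fitted.mfa_fit <- function(object, ...) .fitted_values(object)

.fitted_values <- function(object) {
  out <- numeric(0)
  for (b in object$objective$blocks) {
    sim <- simulate_fragments(object$model, object$emus, object$net,
                              object$exch, b$tracer, object$fragments,
                              nat13c = object$nat13c, window = object$window)
    out <- c(out, vapply(seq_along(b$value), function(i) {
      sim[[b$fragment[i]]][b$mass[i] + 1L]
    }, 0))
  }
  c(out, object$objective$rate_sign * object$net[object$objective$rate_rxn])
}

#' Predict measurements from a fitted flux model
#'
#' @param object An `mfa_fit`.
#' @param type `"mids"` for per-tracer simulated fragment MIDs, `"rates"`
#'   for model-predicted extracellular rates.
#' @param ... Unused.
#' @export
predict.mfa_fit <- function(object, type = c("mids", "rates"), ...) {
  type <- match.arg(type)
  if (type == "rates") {
    return(stats::setNames(
      object$objective$rate_sign * object$net[object$objective$rate_rxn],
      object$measurements$rates$metabolite))
  }
  out <- list()
  for (tn in names(object$tracers)) {
    out[[tn]] <- simulate_fragments(object$model, object$emus, object$net,
                                    object$exch, object$tracers[[tn]],
                                    object$fragments, nat13c = object$nat13c,
                                    window = object$window)
  }
  out
}

#' @export
print.mfa_fit <- function(x, ...) {
  gof <- chi_square_gof(x)
  cat("13C-MFA flux fit\n")
  cat(sprintf("  SSR %.3f on %d degrees of freedom (chi-square 95%% interval [%.1f, %.1f]: %s)\n",
              x$ssr, x$dof, gof$lower, gof$upper,
              if (gof$accepted) "accepted" else "rejected"))
  cat(sprintf("  %d net fluxes, %d exchange fluxes; best of %d restarts (seed %d)\n",
              length(x$net), length(x$exch), nrow(x$restarts), x$seed))
  cat("  net fluxes (nmol/10^6 cells/h):\n")
  print(round(x$net, 3))
  if (length(x$exch)) {
    cat("  exchange fluxes:\n")
    print(round(x$exch, 3))
  }
  invisible(x)
}

#' @export
summary.mfa_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$cov_net), 0))
  tab <- data.frame(flux = names(object$net), estimate = object$net,
                    se = se, row.names = NULL)
  gof <- chi_square_gof(object)
  out <- list(fluxes = tab, exch = object$exch, ssr = object$ssr,
              dof = object$dof, gof = gof, restarts = object$restarts)
  class(out) <- "summary.mfa_fit"
  out
}

#' @export
print.summary.mfa_fit <- function(x, ...) {
  cat("13C-MFA flux fit summary\n")
  cat(sprintf("  SSR %.3f, DOF %d, accepted: %s\n", x$ssr, x$dof,
              x$gof$accepted))
  print(x$fluxes, digits = 4)
  invisible(x)
}

#' @export
plot.mfa_fit <- function(x, ...) {
  fv <- .fitted_values(x)
  mv <- c(unlist(lapply(x$objective$blocks, `[[`, "value")),
          x$measurements$rates$value)
  graphics::plot(mv, fv, xlab = "measured", ylab = "simulated",
                 main = "Measured vs simulated (MIDs + rates)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Chi-square goodness-of-fit test for a flux fit
#'
#' Two-sided acceptance: the fit is accepted when the SSR falls inside the
#' central (1 - alpha) chi-square interval for the fit's degrees of
#' freedom, flagging both lack-of-fit (high) and overfitting / inflated
#' measurement errors (low).
#'
#' @param fit An `mfa_fit`, or a numeric SSR (with `dof` supplied).
#' @param dof Degrees of freedom (taken from the fit if omitted).
#' @param alpha Test level (default 0.05).
#' @return List with `ssr`, `dof`, `lower`, `upper`, `accepted`, and the
#'   one-sided tail probability `p_value`.
#' @export
chi_square_gof <- function(fit, dof = NULL, alpha = 0.05) {
  if (inherits(fit, "mfa_fit")) {
    ssr <- fit$ssr
    if (is.null(dof)) dof <- fit$dof
  } else {
    ssr <- fit
  }
  if (is.null(dof) || dof <= 0) {
    stop("degrees of freedom must be positive", call. = FALSE)
  }
  lo <- stats::qchisq(alpha / 2, dof)
  hi <- stats::qchisq(1 - alpha / 2, dof)
  list(ssr = ssr, dof = dof, lower = lo, upper = hi,
       accepted = ssr >= lo && ssr <= hi,
       p_value = stats::pchisq(ssr, dof, lower.tail = FALSE))
}

#' Normalize fitted fluxes to a reference flux
#'
#' Divides every net flux by a chosen denominator flux (net glucose uptake
#' or total citrate synthase flux in the beta-cell network), so the
#' denominator row equals 1 and the rest express pathway usage per unit of
#' reference flux.
#'
#' @param fit An `mfa_fit`, or a named numeric net flux vector.
#' @param denominator Name of the reference flux (e.g. the glucokinase or
#'   citrate synthase reaction id).
#' @return Data frame with columns `flux`, `value`, `relative`.
#' @export
normalize_fluxes <- function(fit, denominator) {
  net <- if (inherits(fit, "mfa_fit")) fit$net else fit
  if (!denominator %in% names(net)) {
    stop("unknown denominator flux: ", denominator, call. = FALSE)
  }
  d <- net[[denominator]]
  if (d <= 0) stop("denominator flux must be > 0, got ", d, call. = FALSE)
  data.frame(flux = names(net), value = unname(net),
             relative = unname(net) / d, row.names = NULL)
}

#' Citrate M+4 / M+5 ratio
#'
#' Under [U-13C5]glutamine, M+4 citrate reports oxidative (forward) CAC
#' turning while M+5 citrate reports reductive carboxylation of
#' alpha-ketoglutarate by IDH; their ratio falls as IDH exchange flux
#' rises.
#'
#' @param mid Citrate MID (length >= 6).
#' @return The ratio; `Inf` (with a warning) when M+5 is zero.
#' @export
citrate_m4_m5_ratio <- function(mid) {
  if (length(mid) < 6L) stop("citrate MID must have at least 6 channels",
                             call. = FALSE)
  m4 <- mid[5]; m5 <- mid[6]
  if (m5 <= 0) {
    warning("M+5 fraction is zero; ratio is infinite (no reductive flux)")
    return(Inf)
  }
  m4 / m5
}
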