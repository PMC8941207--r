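# Profile-likelihood confidence intervals by parameter continuation: a
# flux is stepped away from its optimum, all other parameters are
# re-optimized, and the interval bound is the value where the SSR exceeds
# SSR_min by the chi-square increment (3.84 for 95%, one parameter).

# Re-optimize with one flux fixed. Returns list(ssr, par) in full space.
.profile_refit <- function(fit, kind, target_name, value, par_start,
                           maxiter = 100) {
  obj <- fit$objective
  f <- obj$f; e <- obj$e
  N <- fit$N
  if (kind == "net") {
    a <- drop(crossprod(N, as.numeric(names(fit$net) == target_name)))
    if (sqrt(sum(a^2)) < 1e-12) {
      # flux structurally fixed at its value; profile is flat
      return(list(ssr = fit$ssr, par = par_start))
    }
    u_p <- a * value / sum(a^2)
    Z <- null_space(matrix(a, 1))
    w0 <- drop(crossprod(Z, par_start[seq_len(f)] - u_p))
    t0 <- par_start[f + seq_len(e)]
    pack <- function(p) {
      w <- p[seq_len(ncol(Z))]
      c(u_p + drop(Z %*% w), p[ncol(Z) + seq_len(e)])
    }
    p0 <- c(w0, t0)
    lower <- c(rep(-Inf, ncol(Z)), rep(0, e))
    upper <- c(rep(Inf, ncol(Z)), rep(0.99, e))
  } else {
    j <- which(names(fit$exch) == target_name)
    tj <- .t_from_exch(value, fit$exch_scale)
    pack <- function(p) {
      full <- numeric(f + e)
      full[seq_len(f)] <- p[seq_len(f)]
      tfree <- p[f + seq_len(e - 1L)]
      tv <- numeric(e)
      tv[-j] <- tfree
      tv[j] <- tj
      full[f + seq_len(e)] <- tv
      full
    }
    p0 <- c(par_start[seq_len(f)], par_start[f + seq_len(e)][-j])
    lower <- c(rep(-Inf, f), rep(0, e - 1L))
    upper <- c(rep(Inf, f), rep(0.99, e - 1L))
  }
  fn <- function(p) obj$resid(pack(p))
  if (length(p0) == 0L) {
    r <- fn(numeric(0))
    return(list(ssr = sum(r[seq_len(obj$n_meas)]^2), par = pack(numeric(0))))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-10, ptol = 1e-8)),
    error = function(err) NULL)
  if (is.null(res)) return(list(ssr = Inf, par = par_start))
  r <- fn(res$par)
  list(ssr = sum(r[seq_len(obj$n_meas)]^2), par = pack(res$par))
}

# One-sided bound search with doubling expansion then bisection.
.profile_bound <- function(fit, kind, name, value, dir, target, step0,
                           hard_min, hard_max, rel_tol = 0.01,
                           max_expand = 14L) {
  par <- fit$par
  step <- step0
  x_in <- value
  x <- value
  for (k in seq_len(max_expand)) {
    x_try <- x + dir * step
    clamped <- FALSE
    if (x_try < hard_min) { x_try <- hard_min; clamped <- TRUE }
    if (x_try > hard_max) { x_try <- hard_max; clamped <- TRUE }
    pr <- .profile_refit(fit, kind, name, x_try, par)
    par <- pr$par
    if (pr$ssr > target) { x <- x_try; break }
    x_in <- x_try
    if (clamped) {
      # the SSR never crossed the threshold inside the search range; a
      # clamp at zero is a real physical bound, anything else is reported
      # as unbounded
      if (dir < 0 && hard_min == 0) {
        return(list(bound = 0, flagged = FALSE, truncated = TRUE))
      }
      return(list(bound = dir * Inf, flagged = TRUE, truncated = FALSE))
    }
    step <- step * 2
    if (k == max_expand) {
      return(list(bound = dir * Inf, flagged = TRUE, truncated = FALSE))
    }
    x <- x_try
  }
  # bisection between x_in (inside) and x (outside)
  lo <- x_in; hi <- x
  for (k in seq_len(20L)) {
    mid <- (lo + hi) / 2
    if (abs(hi - lo) < rel_tol * max(abs(value), step0)) break
    pr <- .profile_refit(fit, kind, name, mid, par)
    par <- pr$par
    if (pr$ssr > target) hi <- mid else lo <- mid
  }
  list(bound = (lo + hi) / 2, flagged = FALSE, truncated = FALSE)
}

#' Profile-likelihood confidence interval for one flux
#'
#' Steps the chosen flux away from its optimum while re-optimizing all
#' remaining parameters, and reports the values where the SSR crosses
#' `SSR_min + qchisq(level, 1)` (+3.84 at 95%). Irreversible net fluxes
#' and exchange fluxes are truncated at 0; a bound that cannot be found
#' within the search range is reported as infinite and flagged.
#'
#' @param fit An `mfa_fit`.
#' @param flux Flux name: a reaction id (net flux) or `"<id>.exch"`.
#' @param level Confidence level (default 0.95).
#' @param step0 Initial step; defaults to the linearized SE when finite.
#' @return List with `lower`, `upper`, `estimate`, `level`, and logical
#'   flags `lower_unbounded`, `upper_unbounded`.
#' @export
confidence_intervals <- function(fit, flux, level = 0.95, step0 = NULL) {
  stopifnot(inherits(fit, "mfa_fit"))
  is_exch <- grepl("\\.exch$", flux)
  name <- sub("\\.exch$", "", flux)
  if (is_exch) {
    if (!name %in% names(fit$exch)) stop("unknown exchange flux: ", name,
                                         call. = FALSE)
    value <- fit$exch[[name]]
    hard_min <- 0
    hard_max <- .exch_from_t(0.99, fit$exch_scale)
  } else {
    if (!name %in% names(fit$net)) stop("unknown net flux: ", name,
                                        call. = FALSE)
    value <- fit$net[[name]]
    irrev <- !(name %in% fit$model$exch_names)
    hard_min <- if (irrev) 0 else -fit$vmax
    hard_max <- fit$vmax
  }
  target <- fit$ssr + stats::qchisq(level, 1)
  if (is.null(step0)) {
    se <- if (!is_exch) sqrt(max(diag(fit$cov_net)[name], 0)) else NA_real_
    step0 <- if (is.finite(se) && se > 0) se else
      max(abs(value) * 0.2, fit$vmax / 100)
  }
  lo <- .profile_bound(fit, if (is_exch) "exch" else "net", name, value,
                       -1, target, step0, hard_min, hard_max)
  hi <- .profile_bound(fit, if (is_exch) "exch" else "net", name, value,
                       +1, target, step0, hard_min, hard_max)
  list(estimate = value, lower = min(lo$bound, value),
       upper = max(hi$bound, value), level = level,
       lower_unbounded = lo$flagged, upper_unbounded = hi$flagged)
}

#' @export
confint.mfa_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(parm)) parm <- names(object$net)
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  for (p in parm) {
    ci <- confidence_intervals(object, p, level = level)
    out[p, ] <- c(ci$lower, ci$upper)
  }
  out
}
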