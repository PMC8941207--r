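# Flux regression: error assembly, optimization, goodness-of-fit,
# confidence intervals, and normalization.

empty_fragments <- function() {
  read_fragments(data.frame(fragment = character(0), species = character(0),
                            carbons = character(0),
                            derivative_formula = character(0)))
}
empty_mids <- function() {
  data.frame(fragment = character(0), tracer = character(0),
             mass = integer(0), value = numeric(0), se = numeric(0))
}

test_that("measurement errors follow the max(control RMSD, replicate SEM) rule", {
  frg <- read_fragments(data.frame(
    fragment = "X123", species = "X", carbons = "1-3",
    derivative_formula = "-"))
  theo <- fragment_mid(natural_mid("C3"), "-", warn_loss = Inf)
  # controls deviating from theory by exactly +/- d in every channel
  d <- 0.004
  controls <- do.call(rbind, lapply(1:2, function(rp) {
    data.frame(fragment = "X123", replicate = rp,
               mass = seq_along(theo) - 1L,
               value = theo + d * (-1)^(rp + seq_along(theo)))
  }))
  base <- c(0.2, 0.3, 0.3, 0.1, 0.06, 0.04)
  mk_mids <- function(spread) do.call(rbind, lapply(1:3, function(rp) {
    data.frame(fragment = "X123", tracer = "glc", replicate = rp,
               mass = 0:5, value = base + spread * (rp - 2))
  }))
  rates <- data.frame(metabolite = "Glc.ext", replicate = 1:3,
                      value = c(-9, -10, -11))
  # small replicate spread: control RMSD (0.004) dominates
  ms1 <- assemble_errors(mk_mids(1e-4), controls, rates, frg)
  expect_true(all(abs(ms1$mids$se - d) < 1e-10))
  # large replicate spread: SEM dominates; matches the textbook formula
  ms2 <- assemble_errors(mk_mids(0.02), controls, rates, frg)
  sem <- stats::sd(0.02 * ((1:3) - 2)) / sqrt(3)
  expect_true(all(abs(ms2$mids$se - sem) < 1e-10))
  # rate SEM
  expect_equal(ms2$rates$se, stats::sd(c(-9, -10, -11)) / sqrt(3),
               tolerance = 1e-10)
  expect_error(assemble_errors(mk_mids(0.02)[mk_mids(0.02)$replicate == 1, ],
                               NULL, rates, frg),
               "controls or >= 2 replicates")
})

test_that("noise-free two-tracer data are recovered from random restarts", {
  net <- core_network()
  frg <- core_fragments()
  emus <- emu_decompose(net, frg)
  truth <- core_truth()
  ms <- core_measurements(net, emus, frg, truth, noise_sd = 0)
  fit <- fit_fluxes(net, frg, ms, core_tracers(), n_starts = 25, seed = 7,
                    emus = emus)
  expect_lt(fit$ssr, 1e-8)
  rel <- abs(fit$net - truth$net[names(fit$net)]) /
    pmax(abs(truth$net[names(fit$net)]), 1e-9)
  expect_lt(max(rel), 1e-4)
  expect_equal(fit$exch[["IDH"]], truth$exch[["IDH"]], tolerance = 1e-3)
  expect_equal(fit$dof, fit$n_meas - ncol(fit$N) - length(fit$exch))
  # restart log bookkeeping
  expect_equal(nrow(fit$restarts), 25)
  expect_true(any(fit$restarts$converged))
})

test_that("restart draws are seed-deterministic and SSR is permutation-invariant", {
  net <- core_network()
  frg <- core_fragments()
  emus <- emu_decompose(net, frg)
  truth <- core_truth()
  ms <- core_measurements(net, emus, frg, truth, noise_sd = 0.003, seed = 3)
  f1 <- fit_fluxes(net, frg, ms, core_tracers(), n_starts = 3, seed = 42,
                   emus = emus)
  f2 <- fit_fluxes(net, frg, ms, core_tracers(), n_starts = 3, seed = 42,
                   emus = emus)
  expect_identical(f1$restarts, f2$restarts)
  expect_identical(f1$net, f2$net)
  # permuting measurement rows leaves the objective unchanged
  set.seed(9)
  perm <- sample(nrow(ms$mids))
  ms_perm <- betaflux:::.new_measurement_set(ms$mids[perm, ], ms$rates)
  init <- list(net = truth$net, exch = truth$exch)
  g1 <- fit_fluxes(net, frg, ms, core_tracers(), n_starts = 1, seed = 1,
                   emus = emus, init = init)
  g2 <- fit_fluxes(net, frg, ms_perm, core_tracers(), n_starts = 1, seed = 1,
                   emus = emus, init = init)
  expect_equal(g1$ssr, g2$ssr, tolerance = 1e-8)
})

test_that("two-sided chi-square acceptance matches its quantiles", {
  expect_true(chi_square_gof(20, dof = 20)$accepted)
  expect_false(chi_square_gof(100, dof = 10)$accepted)   # lack of fit
  g <- chi_square_gof(0, dof = 20)                       # overfit / SE inflated
  expect_false(g$accepted)
  expect_gt(g$lower, 0)
  expect_equal(g$lower, qchisq(0.025, 20))
  expect_equal(g$upper, qchisq(0.975, 20))
  expect_error(chi_square_gof(5, dof = 0), "positive")
})

test_that("profile CI matches the analytic interval on a linear toy model", {
  net <- toy_network(list(
    list("U", "S.ext (ab) -> P (ab)", FALSE, "uptake"),
    list("L", "P (ab) -> P.ext (ab)", FALSE, "release")))
  ms <- betaflux:::.new_measurement_set(
    empty_mids(),
    data.frame(metabolite = c("S.ext", "P.ext"), value = c(-10, 10),
               se = c(1, 1)))
  fit <- fit_fluxes(net, empty_fragments(), ms, tracers = list(),
                    n_starts = 3, seed = 1)
  expect_equal(unname(fit$net[["U"]]), 10, tolerance = 1e-6)
  ci <- confidence_intervals(fit, "U")
  # two unit-SE observations of the same flux: SE = 1/sqrt(2)
  expect_equal(ci$lower, 10 - 1.96 / sqrt(2), tolerance = 0.02)
  expect_equal(ci$upper, 10 + 1.96 / sqrt(2), tolerance = 0.02)
  expect_false(ci$lower_unbounded || ci$upper_unbounded)
})

test_that("an uninformed exchange flux has an unbounded upper CI", {
  net <- toy_network(list(
    list("U", "A.ext (ab) -> A (ab)", FALSE, "uptake"),
    list("RX", "A (ab) -> B (ab)", TRUE, "internal"),
    list("RL", "B (ab) -> B.ext (ab)", FALSE, "release")))
  ms <- betaflux:::.new_measurement_set(
    empty_mids(),
    data.frame(metabolite = c("A.ext", "B.ext"), value = c(-5, 5),
               se = c(0.5, 0.5)))
  fit <- fit_fluxes(net, empty_fragments(), ms, tracers = list(),
                    n_starts = 2, seed = 1)
  ci <- confidence_intervals(fit, "RX.exch")
  expect_true(ci$upper_unbounded)
  expect_identical(ci$upper, Inf)
})

test_that("flux normalization behaves like a ratio table", {
  v <- c(GK = 2, PK = 4, CS = 1)
  tab <- normalize_fluxes(v, "GK")
  expect_equal(tab$relative[tab$flux == "GK"], 1)
  expect_equal(tab$relative[tab$flux == "PK"], 2)
  # commutes with uniform rescaling
  tab2 <- normalize_fluxes(v * 7.3, "GK")
  expect_equal(tab$relative, tab2$relative)
  expect_error(normalize_fluxes(c(GK = 0, PK = 1), "GK"), "> 0")
  expect_error(normalize_fluxes(v, "NOPE"), "unknown")
})

test_that("citrate M+4/M+5 ratio and its degenerate case", {
  expect_equal(citrate_m4_m5_ratio(c(0, 0, 0, 0, 0.2, 0.1, 0)), 2.0)
  expect_warning(r <- citrate_m4_m5_ratio(c(1, 0, 0, 0, 0.2, 0)), "infinite")
  expect_identical(r, Inf)
})

test_that("fit methods expose the usual modelling surface", {
  net <- core_network()
  frg <- core_fragments()
  emus <- emu_decompose(net, frg)
  truth <- core_truth()
  ms <- core_measurements(net, emus, frg, truth, noise_sd = 0.003, seed = 5)
  fit <- fit_fluxes(net, frg, ms, core_tracers(), n_starts = 1, seed = 1,
                    emus = emus, init = list(net = truth$net,
                                             exch = truth$exch))
  expect_named(coef(fit))
  expect_equal(deviance(fit), fit$ssr)
  expect_equal(df.residual(fit), fit$dof)
  expect_length(residuals(fit), fit$n_meas)
  expect_equal(sum(residuals(fit)^2), fit$ssr, tolerance = 1e-10)
  pr <- predict(fit, type = "rates")
  expect_named(pr)
  expect_equal(length(pr), nrow(ms$rates))
  mids <- predict(fit, type = "mids")
  expect_named(mids, c("glc", "gln"))
  expect_output(print(fit), "SSR")
  s <- summary(fit)
  expect_s3_class(s, "summary.mfa_fit")
  expect_true(all(c("flux", "estimate", "se") %in% names(s$fluxes)))
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
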