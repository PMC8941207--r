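# Synthetic experiment generator: ground-truth fluxes for WT / G6PC2-KO
# scenarios at 5 or 11 mM glucose, forward-simulated into the full
# two-tracer measurement bundle (fragment MIDs with replicate noise,
# unlabeled controls, extracellular rate time courses, a deuterated-
# glucose cycling course, and metabolite pools for redox inference).

# Hand-balanced wild-type flux vector at 5 mM glucose
# (nmol/10^6 cells/h); satisfies S v = 0 on the bundled network.
.wt5_net <- c(GK = 60, PGI = 58.8, G6PDH = 1.2, TKT1 = 0.4, TALA = 0.4,
              TKT2 = 0.4, ALD = 59.6, TPI = 58.8, GAPD = 118.8, PK = 114.8,
              PSP = 4, SHMT = 2.5, GPD = 0.8, G3PP = 0.8, LDH = 70,
              ALT = 4, PDH = 36.8, PC = 6, ME = 8, CS = 36.8, IDH = 33.8,
              AKGDH = 40.3, SDH = 39.8, FUM = 39.8, MDH = 31.5, AAT = 0.7,
              GLNU = 8, GLS = 8, GDH = 6.5, PYRR = 6, LACR = 70, ALAR = 4,
              CITR = 3, GLUR = 1.5, SERR = 1.5, GLYR = 2.5, C1R = 2.5,
              GLYCR = 0.8, MALR = 0.3, SUCR = 0.5, ASPR = 0.7)
.wt5_exch <- c(IDH = 15, MDH = 20, GDH = 25)

# medium species whose exchange rates are "measured" (13 of them)
.measured_rates <- c("Glc.ext", "Gln.ext", "Pyr.ext", "Lac.ext", "Ala.ext",
                     "Cit.ext", "Glu.ext", "Ser.ext", "Gly.ext", "Glyc.ext",
                     "Mal.ext", "Suc.ext", "Asp.ext")

# Least-squares projection onto {v : S v = 0, v[names(fix)] = fix},
# starting from a target vector.
.balance_project <- function(S, v_target, fix = NULL) {
  A <- S
  b <- rep(0, nrow(S))
  if (length(fix)) {
    E <- matrix(0, length(fix), ncol(S), dimnames = list(NULL, colnames(S)))
    for (i in seq_along(fix)) E[i, names(fix)[i]] <- 1
    A <- rbind(S, E)
    b <- c(b, unname(fix))
  }
  resid <- drop(A %*% v_target) - b
  v <- v_target - drop(t(A) %*% solve(A %*% t(A) + diag(1e-12, nrow(A)),
                                      resid))
  stats::setNames(v, colnames(S))
}

#' Ground-truth scenario for synthetic experiments
#'
#' Builds a balanced flux vector and experiment parameters for a wild-type
#' or G6PC2-knockout beta-cell scenario at 5 or 11 mM glucose. Rates at
#' 11 mM are twice the 5 mM values (nutrient exchange roughly doubles with
#' glucose). The knockout applies pathway multipliers — glycolysis x1.67,
#' citric acid cycle x1.6, glutamine entry x1.78, pyruvate carboxylase x2,
#' malic enzyme x2.2, IDH exchange x2 — then re-balances by constrained
#' projection with the glycolytic (pyruvate kinase) ratio pinned at 1.67.
#' Knockout scenarios have zero glucose futile cycling; wild-type cycling
#' is 10% of total glucose phosphorylation at 5 mM and 20% at 11 mM.
#'
#' @param scenario `"WT"` or `"KO"`.
#' @param glucose_mM 5 or 11.
#' @param model The network (default [beta_cell_network()]).
#' @return A `ground_truth` list: `net`, `exch`, `rates` (the 13 medium
#'   exchange rates implied by the fluxes), `cycling_percent`,
#'   `cycling_v_total`, `growth` (`x0`, `mu`), `volume_ml`, `conc0`,
#'   `pools_uM`, and labels.
#' @export
make_ground_truth <- function(scenario = c("WT", "KO"),
                              glucose_mM = 5, model = beta_cell_network()) {
  scenario <- match.arg(scenario)
  stopifnot(glucose_mM %in% c(5, 11))
  scale <- if (glucose_mM == 11) 2 else 1
  net <- .wt5_net * scale
  exch <- .wt5_exch * scale
  cycling <- if (glucose_mM == 11) 20 else 10
  # total phosphorylation in the high-density cycling dishes; chosen so a
  # 10%-cycling wild-type course accumulates ~8-10% recycled glucose in 24 h
  v_total_assay <- 100 * scale
  if (scenario == "KO") {
    mult <- c(GK = 1.67, PGI = 1.67, G6PDH = 1.67, TKT1 = 1.67, TALA = 1.67,
              TKT2 = 1.67, ALD = 1.67, TPI = 1.67, GAPD = 1.67, PK = 1.67,
              PSP = 1.9, SHMT = 1.9, SERR = 1.9, GLYR = 1.9, C1R = 1.9,
              PDH = 1.6, CS = 1.6, IDH = 1.6, AKGDH = 1.6, SDH = 1.6,
              FUM = 1.6, MDH = 1.45, GLNU = 1.78, GLS = 1.78, GDH = 1.78,
              PC = 2.0, ME = 2.2, GLYCR = 2.2, GPD = 2.2, G3PP = 2.2,
              LDH = 1.55, LACR = 1.55, PYRR = 1.9, ALAR = 1.9, ALT = 1.9,
              CITR = 1.9)
    target <- net
    target[names(mult)] <- target[names(mult)] * mult
    net <- .balance_project(model$S, target[colnames(model$S)],
                            fix = c(PK = unname(net[["PK"]]) * 1.67))
    if (any(net < -1e-6)) {
      stop("knockout multipliers yield no nonnegative balanced solution",
           call. = FALSE)
    }
    net[net < 0] <- 0
    net <- .balance_project(model$S, net,
                            fix = c(PK = unname(.wt5_net[["PK"]]) * scale * 1.67))
    exch[["IDH"]] <- exch[["IDH"]] * 2
    cycling <- 0
    v_total_assay <- v_total_assay * 1.6
  }
  rmap <- .medium_rate_map(model)
  rates <- vapply(.measured_rates, function(sp) {
    rmap[[sp]]$sign * net[[rmap[[sp]]$id]]
  }, 0)
  conc0 <- stats::setNames(rep(0, length(.measured_rates)), .measured_rates)
  conc0["Glc.ext"] <- glucose_mM
  conc0["Gln.ext"] <- 2
  pools <- c(Lac = 1500, Pyr = 150, Mal = 400, Glu = 8000, AKG = 150,
             CO2 = 1200, NH4 = 300)
  if (scenario == "KO") {
    # more reduced cytosol, more oxidized mitochondria
    pools["Pyr"] <- 120
    pools["Mal"] <- 560
    pools["AKG"] <- 180
    if (glucose_mM == 11) pools["Lac"] <- 2100
  }
  structure(list(scenario = scenario, glucose_mM = glucose_mM,
                 net = net, exch = exch, rates = rates,
                 cycling_percent = cycling,
                 cycling_v_total = v_total_assay,
                 growth = list(x0 = 1.5e6, mu = 0.015),
                 volume_ml = 10, conc0 = conc0, pools_uM = pools),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %s at %g mM glucose\n", x$scenario,
              x$glucose_mM))
  cat(sprintf("  V_GK net %.1f, V_PK %.1f, V_CS %.1f, IDH exchange %.1f, cycling %.0f%%\n",
              x$net[["GK"]], x$net[["PK"]], x$net[["CS"]], x$exch[["IDH"]],
              x$cycling_percent))
  invisible(x)
}

# truncated-Gaussian channel noise + renormalization
.noisy_mid <- function(mid, sd) {
  if (sd <= 0) return(mid)
  x <- pmax(mid + stats::rnorm(length(mid), 0, sd), 0)
  x / sum(x)
}

#' Simulate a complete synthetic experiment bundle
#'
#' Forward-simulates both tracers ([1,2-13C2]glucose and
#' [U-13C5]glutamine) through the network at the ground-truth fluxes and
#' emits the full measurement bundle: replicate fragment MIDs with
#' truncated-Gaussian channel noise (renormalized), unlabeled control
#' MIDs at natural abundance, extracellular concentration time courses at
#' 0/12/24/48/72 h under exponential growth (glutamine additionally
#' decays at `k_deg`), a deuterated-glucose cycling course, and a redox
#' pool panel. Regenerating with the same seed is bit-identical.
#'
#' @param truth A `ground_truth`.
#' @param model,fragments Network and fragment set (defaults match
#'   [make_ground_truth()]).
#' @param n_reps Biological replicates (default 3).
#' @param mid_sd MID channel noise SD (default 0.003, the scale of the
#'   RMSD between unlabeled standards and theoretical MIDs).
#' @param rate_cv Coefficient of variation applied per replicate to each
#'   true exchange rate (default 0.1).
#' @param k_deg_gln Spontaneous glutamine degradation rate (default
#'   0.0031 1/h).
#' @param pool_cv Replicate CV for the redox pool panel.
#' @param seed Integer seed (recorded in the bundle).
#' @return A `synthetic_dataset` list with `mids`, `controls`,
#'   `time_courses`, `cycling`, `pools`, `tracers`, `truth`, `seed`.
#' @export
simulate_experiment <- function(truth, model = beta_cell_network(),
                                fragments = beta_cell_fragments(),
                                n_reps = 3L, mid_sd = 0.003, rate_cv = 0.1,
                                k_deg_gln = 0.0031, pool_cv = 0.08,
                                seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_reps >= 1L)
  set.seed(seed)
  emus <- emu_decompose(model, fragments)
  tracers <- list(
    glc = tracer_spec("Glc.ext", c(1, 2)),
    gln = tracer_spec("Gln.ext", 1:5))
  # --- fragment MIDs, both tracers, n_reps replicates
  mid_rows <- list()
  for (tn in names(tracers)) {
    sim <- simulate_fragments(model, emus, truth$net, truth$exch,
                              tracers[[tn]], fragments)
    for (fr in names(sim)) {
      for (rp in seq_len(n_reps)) {
        val <- .noisy_mid(sim[[fr]], mid_sd)
        mid_rows[[length(mid_rows) + 1L]] <-
          data.frame(fragment = fr, tracer = tn, replicate = rp,
                     mass = seq_along(val) - 1L, value = val)
      }
    }
  }
  mids <- do.call(rbind, mid_rows)
  # --- unlabeled controls at natural abundance
  ctl_rows <- list()
  for (i in seq_len(nrow(fragments))) {
    theo <- fragment_mid(
      natural_mid(paste0("C", length(fragments$carbons[[i]]))),
      fragments$derivative_formula[i], warn_loss = Inf)
    for (rp in seq_len(n_reps)) {
      val <- .noisy_mid(theo, mid_sd)
      ctl_rows[[length(ctl_rows) + 1L]] <-
        data.frame(fragment = fragments$fragment[i], replicate = rp,
                   mass = seq_along(val) - 1L, value = val)
    }
  }
  controls <- do.call(rbind, ctl_rows)
  # --- rate time courses
  times <- c(0, 12, 24, 48, 72)
  x0 <- truth$growth$x0; mu <- truth$growth$mu; V <- truth$volume_ml
  conc_at <- function(C0, q, k, t) {
    # dC/dt = q X(t) / (1000 V) - k C, X in 10^6 cells
    C0 * exp(-k * t) +
      q * (x0 / 1e6) / (1000 * V) * (exp(mu * t) - exp(-k * t)) / (mu + k)
  }
  tc_rows <- list()
  for (m in names(truth$rates)) {
    k <- if (m == "Gln.ext") k_deg_gln else 0
    for (rp in seq_len(n_reps)) {
      q_rep <- truth$rates[[m]] * (1 + rate_cv * stats::rnorm(1))
      cc <- conc_at(truth$conc0[[m]], q_rep, k, times)
      attempts <- 0L
      while (any(cc < 0) && attempts < 50L) {
        # rejection: redraw replicates that would empty the medium
        q_rep <- truth$rates[[m]] * (1 + rate_cv * stats::rnorm(1))
        cc <- conc_at(truth$conc0[[m]], q_rep, k, times)
        attempts <- attempts + 1L
      }
      tc_rows[[length(tc_rows) + 1L]] <-
        data.frame(time_h = times, metabolite = m, conc_mM = cc,
                   cells = x0 * exp(mu * times), volume_ml = V,
                   replicate = rp)
    }
  }
  time_courses <- do.call(rbind, tc_rows)
  # --- cycling course
  cyc <- simulate_cycling(truth$cycling_percent, truth$cycling_v_total,
                          glucose_mM = truth$glucose_mM, mid_sd = mid_sd)
  # --- redox pools
  pool_rows <- list()
  for (rp in seq_len(n_reps)) {
    vals <- truth$pools_uM * (1 + pool_cv * stats::rnorm(length(truth$pools_uM)))
    vals <- pmax(vals, 0.01 * truth$pools_uM)
    pool_rows[[length(pool_rows) + 1L]] <-
      data.frame(metabolite = names(vals), value = unname(vals),
                 unit = "uM", replicate = rp)
  }
  pools <- do.call(rbind, pool_rows)
  structure(list(mids = mids, controls = controls,
                 time_courses = time_courses, cycling = cyc, pools = pools,
                 tracers = tracers, fragments = fragments, truth = truth,
                 n_reps = n_reps, mid_sd = mid_sd, rate_cv = rate_cv,
                 k_deg_gln = k_deg_gln, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %s at %g mM glucose (seed %d)\n",
              x$truth$scenario, x$truth$glucose_mM, x$seed))
  cat(sprintf("  %d fragments x %d tracers x %d replicates; %d rate courses\n",
              length(unique(x$mids$fragment)), length(x$tracers), x$n_reps,
              length(unique(x$time_courses$metabolite))))
  invisible(x)
}
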