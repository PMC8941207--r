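# Steady-state labeling simulation: EMU solver vs exhaustive isotopomer
# enumeration, tracer diagnostics, and structural invariants.

test_that("EMU solver equals brute-force isotopomer enumeration", {
  # 12-carbon toy with condensation, cleavage, reversibility, symmetry
  net <- toy12()
  tr <- tracer_spec("A.ext", 1, enrichment = 0.99, fraction = 0.8)
  targets <- list(list(species = "E", positions = 1:2),
                  list(species = "F", positions = 1),
                  list(species = "C", positions = 1:3),
                  list(species = "D", positions = 1:3))
  es <- emu_decompose(net, targets)
  mids <- simulate_labeling(net, es, toy12_net, toy12_exch, tr,
                            nat13c = 0.0107)
  bf <- bf_simulate(net, toy12_net, toy12_exch, tr, nat13c = 0.0107)
  for (tg in targets) {
    got <- mids[[betaflux:::.emu_key(tg$species, tg$positions)]]
    want <- bf$emu_mid(tg$species, tg$positions)
    expect_lt(max(abs(got - want)), 1e-9)
  }

  # self-condensation toy (same pool convolved with itself)
  dimer <- toy_network(list(
    list("U", "S.ext (a) -> S (a)", FALSE, "uptake"),
    list("DIM", "S (a) + S (b) -> T (ab)", FALSE, "internal"),
    list("TL", "T (ab) -> T.ext (ab)", FALSE, "release")))
  tr2 <- tracer_spec("S.ext", 1, enrichment = 1, fraction = 0.5)
  es2 <- emu_decompose(dimer, list(list(species = "T", positions = 1:2)))
  got <- simulate_labeling(dimer, es2, c(U = 2, DIM = 1, TL = 1), NULL, tr2,
                           nat13c = 0)[["T[1,2]"]]
  expect_equal(got, c(0.25, 0.5, 0.25), tolerance = 1e-12)
})

test_that("every simulated MID is normalized and nonnegative", {
  net <- core_network()
  frg <- core_fragments()
  es <- emu_decompose(net, frg)
  truth <- core_truth()
  N <- null_space(net$S)
  set.seed(11)
  for (rep in 1:5) {
    # random feasible flux vector near the truth
    v <- truth$net * exp(runif(length(truth$net), -0.3, 0.3))
    v <- betaflux:::.balance_project(net$S, v[colnames(net$S)])
    if (any(v < 0)) next
    ex <- truth$exch * runif(3, 0.2, 2)
    mids <- simulate_labeling(net, es, v, ex,
                              core_tracers()$gln)
    for (m in mids) {
      expect_lt(abs(sum(m) - 1), 1e-9)
      expect_gt(min(m), -1e-12)
    }
  }
})

test_that("[1,2-13C2]glucose through pure glycolysis gives pyruvate M+0/M+2", {
  net <- beta_cell_network()
  frg <- beta_cell_fragments()
  es <- emu_decompose(net, frg)
  gly <- stats::setNames(numeric(length(net$net_names)), net$net_names)
  gly[c("GK", "PGI", "ALD", "TPI")] <- 10
  gly[c("GAPD", "PK", "LDH", "LACR")] <- 20
  tr <- tracer_spec("Glc.ext", c(1, 2), enrichment = 1)
  mids <- simulate_labeling(net, es, gly, NULL, tr, nat13c = 0)
  pyr <- mids[["Pyr[1,2,3]"]]
  expect_equal(pyr[1:3], c(0.5, 0, 0.5), tolerance = 1e-10)
  expect_equal(pyr[4], 0, tolerance = 1e-10)
  # zero tracer enrichment: everything M+0
  tr0 <- tracer_spec("Glc.ext", c(1, 2), enrichment = 0)
  mids0 <- simulate_labeling(net, es, gly, NULL, tr0, nat13c = 0)
  for (m in mids0) if (!anyNA(m)) expect_equal(m[1], 1, tolerance = 1e-12)
})

test_that("citrate M+5 under [U-13C5]glutamine requires IDH exchange", {
  net <- beta_cell_network()
  es <- emu_decompose(net, list(list(species = "Cit", positions = 1:6)))
  # oxidative-only variant of the WT truth (no malic enzyme recycling)
  tr <- make_ground_truth("WT", 5, net)
  oxi <- tr$net
  oxi[c("ME", "PDH", "CS", "IDH", "AKGDH", "SDH", "FUM", "AAT", "ASPR")] <-
    c(0, 28.8, 28.8, 25.8, 32.3, 31.8, 31.8, 8.7, 8.7)
  expect_true(flux_balanced(net, oxi))
  gln <- tracer_spec("Gln.ext", 1:5, enrichment = 1)
  cit0 <- simulate_labeling(net, es, oxi, c(IDH = 0, MDH = 20, GDH = 25),
                            gln, nat13c = 0)[["Cit[1,2,3,4,5,6]"]]
  expect_gt(cit0[5], 0.05)            # M+4 from oxidative turning
  expect_equal(cit0[6], 0, tolerance = 1e-12)  # no M+5 without exchange
  cit1 <- simulate_labeling(net, es, oxi, c(IDH = 15, MDH = 20, GDH = 25),
                            gln, nat13c = 0)[["Cit[1,2,3,4,5,6]"]]
  expect_gt(cit1[6], 0)
  # doubling the exchange lowers the M+4/M+5 ratio, monotonically in M+5
  cit2 <- simulate_labeling(net, es, oxi, c(IDH = 30, MDH = 20, GDH = 25),
                            gln, nat13c = 0)[["Cit[1,2,3,4,5,6]"]]
  expect_gt(cit2[6], cit1[6])
  expect_lt(citrate_m4_m5_ratio(cit2), citrate_m4_m5_ratio(cit1))
})

test_that("oxidative PPP raises lactate M+1 under [1,2-13C2]glucose", {
  net <- beta_cell_network()
  es <- emu_decompose(net, list(list(species = "Lac", positions = 1:3)))
  tr <- make_ground_truth("WT", 5, net)
  base <- tr$net
  # shut the PPP and re-balance by sending everything through PGI
  noppp <- base
  noppp[c("G6PDH", "TKT1", "TALA", "TKT2")] <- 0
  noppp["PGI"] <- noppp["GK"]
  noppp["ALD"] <- noppp["PGI"]
  noppp["GAPD"] <- noppp["ALD"] + noppp["TPI"]
  noppp["PK"] <- noppp["GAPD"] - noppp["PSP"]
  noppp["TPI"] <- noppp["ALD"] - noppp["GPD"]
  noppp["GAPD"] <- noppp["ALD"] + noppp["TPI"]
  noppp["PK"] <- noppp["GAPD"] - noppp["PSP"]
  noppp["LDH"] <- noppp["PK"] + noppp["ME"] - noppp["PYRR"] - noppp["ALT"] -
    noppp["PDH"] - noppp["PC"]
  noppp["LACR"] <- noppp["LDH"]
  expect_true(flux_balanced(net, noppp, tol = 1e-6))
  glc <- tracer_spec("Glc.ext", c(1, 2), enrichment = 1)
  lac_no <- simulate_labeling(net, es, noppp, tr$exch, glc,
                              nat13c = 0)[["Lac[1,2,3]"]]
  lac_yes <- simulate_labeling(net, es, base, tr$exch, glc,
                               nat13c = 0)[["Lac[1,2,3]"]]
  expect_gt(lac_yes[2], lac_no[2])
})

test_that("symmetric succinate yields palindromic positional enrichment", {
  net <- core_network()
  targets <- c(lapply(1:4, function(i) list(species = "Suc", positions = i)),
               lapply(1:5, function(i) list(species = "AKG", positions = i)))
  es <- emu_decompose(net, targets)
  truth <- core_truth()
  mids <- simulate_labeling(net, es, truth$net, truth$exch,
                            core_tracers()$glc)
  suc <- vapply(1:4, function(i) mids[[sprintf("Suc[%d]", i)]][2], 0)
  akg <- vapply(1:5, function(i) mids[[sprintf("AKG[%d]", i)]][2], 0)
  # palindromic pool
  expect_equal(suc[1], suc[4], tolerance = 1e-12)
  expect_equal(suc[2], suc[3], tolerance = 1e-12)
  # and exactly the 50/50 average of the two precursor orientations
  # (succinate derives from alpha-ketoglutarate carbons 2-5)
  for (i in 1:4) {
    expect_equal(suc[i], (akg[i + 1] + akg[6 - i]) / 2, tolerance = 1e-12)
  }
  expect_gt(stats::sd(akg), 0)  # the precursor is not uniformly labeled
})

test_that("measurement-space conversion convolves the derivative backbone", {
  # identity convolution
  expect_equal(fragment_mid(c(0.5, 0, 0.5), ""), c(0.5, 0, 0.5))
  # pure-M0 skeleton with a C6 derivative: M+1 from derivative carbons only
  got <- fragment_mid(c(1, 0, 0, 0), "C6")
  want_m1 <- 6 * 0.0107 * 0.9893^5
  expect_equal(got[2] / got[1], want_m1 / 0.9893^6, tolerance = 1e-10)
  expect_equal(got[2], want_m1, tolerance = 2e-4)  # renormalization is mild
  # unlabeled skeleton + no derivative = natural MID
  nat <- natural_mid("C3")
  expect_equal(fragment_mid(nat[1:4], ""), nat[1:4] / sum(nat[1:4]),
               tolerance = 1e-12)
  # heavy derivative with a tight window warns about truncated mass
  expect_warning(fragment_mid(c(1, 0), "Si4", window = 1L), "truncates")
})

test_that("singular pools are reported by species name", {
  net <- core_network()
  frg <- core_fragments()
  es <- emu_decompose(net, frg)
  v <- c(GLY = 30, LDH = 43, LACR = 43, PYRR = 3, PDH = 12, PC = 5,
         CS = 12, IDH = 10, AKGDH = 10, SDH = 10, MDH = 7, ME = 3,
         GLNU = 0, GDH = 0, CITR = 2)  # no flux through the glutamate pool
  expect_true(flux_balanced(net, v))
  expect_error(
    simulate_fragments(net, es, v, c(IDH = 6, MDH = 8, GDH = 0),
                       core_tracers()$gln, frg),
    "Glu")
})
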