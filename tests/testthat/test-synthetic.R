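# Synthetic experiment generation: ground truths, determinism, noise model.

test_that("ground truths are balanced and encode the knockout contrasts", {
  net <- beta_cell_network()
  wt5 <- make_ground_truth("WT", 5, net)
  ko5 <- make_ground_truth("KO", 5, net)
  wt11 <- make_ground_truth("WT", 11, net)
  for (tr in list(wt5, ko5, wt11)) {
    expect_true(flux_balanced(net, tr$net, tol = 1e-9))
    expect_true(all(tr$net > -1e-9))
  }
  # glycolytic flux ratio pinned at ~1.67, CAC ~1.6, glutamine entry ~1.8
  expect_equal(ko5$net[["PK"]] / wt5$net[["PK"]], 1.67, tolerance = 1e-6)
  expect_equal(ko5$net[["CS"]] / wt5$net[["CS"]], 1.6, tolerance = 0.05)
  expect_equal(ko5$net[["GLNU"]] / wt5$net[["GLNU"]], 1.78, tolerance = 0.1)
  expect_equal(ko5$exch[["IDH"]] / wt5$exch[["IDH"]], 2)
  # knockout means no futile cycling; 11 mM doubles the exchange scale
  expect_equal(ko5$cycling_percent, 0)
  expect_equal(wt5$cycling_percent, 10)
  expect_equal(wt11$cycling_percent, 20)
  expect_equal(wt11$rates, 2 * wt5$rates)
})

test_that("dataset bundles are seed-deterministic with the stated shape", {
  net <- beta_cell_network()
  frg <- beta_cell_fragments()
  tr <- make_ground_truth("WT", 5, net)
  d1 <- simulate_experiment(tr, net, frg, seed = 20)
  d2 <- simulate_experiment(tr, net, frg, seed = 20)
  expect_identical(d1$mids, d2$mids)
  expect_identical(d1$time_courses, d2$time_courses)
  expect_identical(d1$cycling$mids, d2$cycling$mids)
  d3 <- simulate_experiment(tr, net, frg, seed = 21)
  expect_false(identical(d1$mids$value, d3$mids$value))
  # 21 fragment MIDs per tracer, 13 rate courses
  expect_equal(length(unique(d1$mids$fragment)), 21)
  expect_equal(length(unique(d1$time_courses$metabolite)), 13)
  expect_equal(length(unique(paste(d1$mids$fragment, d1$mids$tracer))), 42)
  # every replicate MID sums to 1
  sums <- aggregate(value ~ fragment + tracer + replicate, d1$mids, sum)
  expect_true(all(abs(sums$value - 1) < 1e-9))
})

test_that("control noise reproduces the configured RMSD scale", {
  net <- beta_cell_network()
  frg <- beta_cell_fragments()
  tr <- make_ground_truth("WT", 5, net)
  d <- simulate_experiment(tr, net, frg, n_reps = 5, seed = 33)
  rmsds <- c()
  for (i in seq_len(nrow(frg))) {
    theo <- fragment_mid(natural_mid(paste0("C", length(frg$carbons[[i]]))),
                         frg$derivative_formula[i], warn_loss = Inf)
    sub <- d$controls[d$controls$fragment == frg$fragment[i], ]
    for (rp in unique(sub$replicate)) {
      v <- sub$value[sub$replicate == rp][order(sub$mass[sub$replicate == rp])]
      rmsds <- c(rmsds, mid_rmsd(v, theo))
    }
  }
  expect_gte(length(rmsds), 100)
  expect_lt(abs(mean(rmsds) - 0.003) / 0.003, 0.2)
})

test_that("zero-noise bundles round-trip through every estimator", {
  net <- beta_cell_network()
  frg <- beta_cell_fragments()
  tr <- make_ground_truth("WT", 5, net)
  d <- simulate_experiment(tr, net, frg, mid_sd = 0, rate_cv = 0, seed = 2)
  # rates: estimated from the time courses = truth
  er <- estimate_exchange_rates(d$time_courses,
                                k_deg = c(Gln.ext = d$k_deg_gln))
  for (m in names(tr$rates)) {
    q <- er$rates$q[er$rates$metabolite == m]
    expect_equal(q, unname(tr$rates[[m]]),
                 tolerance = 0.01 * max(abs(tr$rates[[m]]), 0.1))
  }
  # cycling: estimator recovers the ground-truth percentage
  cr <- cycling_rates(d$cycling)
  expect_lt(abs(cr$cycling_percent - tr$cycling_percent), 0.5)
  # replicate-mean MIDs equal the forward simulation exactly
  emus <- emu_decompose(net, frg)
  sim <- simulate_fragments(net, emus, tr$net, tr$exch, d$tracers$glc, frg)
  sub <- d$mids[d$mids$tracer == "glc" & d$mids$fragment == "Cit123456" &
                  d$mids$replicate == 1, ]
  expect_equal(sub$value[order(sub$mass)], unname(sim$Cit123456),
               tolerance = 1e-12)
  # redox pools: panel matches the direct formulas on the truth pools
  panel <- redox_panel(tr$pools_uM, unit = "uM")
  expect_equal(panel$cNADH_NAD,
               (tr$pools_uM[["Lac"]] / tr$pools_uM[["Pyr"]]) / 1.11e-4)
})
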