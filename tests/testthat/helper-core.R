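# Shared fixtures built in code: toy networks, the reduced-core ground
# truth, and a measurement-set builder used by the fitting tests.

toy_network <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], equation = r[[2]], reversible = r[[3]],
               role = r[[4]])
  }))
  read_network(df)
}

# 12-carbon toy exercising condensation, cleavage, reversibility and a
# symmetric species (E).
toy12 <- function() {
  net <- toy_network(list(
    list("U1", "A.ext (ab) -> A (ab)", FALSE, "uptake"),
    list("U2", "B.ext (c) -> B (c)", FALSE, "uptake"),
    list("CND", "A (ab) + B (c) -> C (abc)", FALSE, "internal"),
    list("REV", "C (abc) -> D (cba)", TRUE, "internal"),
    list("CLV", "D (abc) -> E (ab) + F (c)", FALSE, "internal"),
    list("EL", "E (ab) -> E.ext (ab)", FALSE, "release"),
    list("FL", "F (a) -> F.ext (a)", FALSE, "release")))
  net$symmetric <- "E"
  net
}
toy12_net <- c(U1 = 2, U2 = 2, CND = 2, REV = 2, CLV = 2, EL = 2, FL = 2)
toy12_exch <- c(REV = 3)

core_truth <- function() {
  list(net = c(GLY = 30, LDH = 45, LACR = 45, PYRR = 3, PDH = 14, PC = 5,
               CS = 14, IDH = 12, AKGDH = 16, SDH = 16, MDH = 9, ME = 7,
               GLNU = 4, GDH = 4, CITR = 2),
       exch = c(IDH = 6, MDH = 8, GDH = 10))
}

core_tracers <- function() {
  list(glc = tracer_spec("Glc.ext", c(1, 2)),
       gln = tracer_spec("Gln.ext", 1:5))
}

# Measurement set simulated from a truth on the core network.
# noise_sd = 0 gives noise-free data with the same SEs.
core_measurements <- function(model, emus, fragments, truth,
                              noise_sd = 0, seed = 1, mid_se = 0.003) {
  set.seed(seed)
  tracers <- core_tracers()
  rows <- list()
  for (tn in names(tracers)) {
    sim <- simulate_fragments(model, emus, truth$net, truth$exch,
                              tracers[[tn]], fragments)
    for (fr in names(sim)) {
      v <- sim[[fr]]
      if (noise_sd > 0) {
        v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
        v <- v / sum(v)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fragment = fr, tracer = tn, mass = seq_along(v) - 1L,
        value = v, se = mid_se)
    }
  }
  mids <- do.call(rbind, rows)
  rmap <- betaflux:::.medium_rate_map(model)
  rsp <- names(rmap)
  rv <- vapply(rsp, function(s) rmap[[s]]$sign * truth$net[[rmap[[s]]$id]], 0)
  rse <- pmax(0.05 * abs(rv), 0.2)
  if (noise_sd > 0) rv <- rv + stats::rnorm(length(rv), 0, rse)
  betaflux:::.new_measurement_set(
    mids, data.frame(metabolite = rsp, value = rv, se = rse))
}
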