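# Network parsing, validation and EMU decomposition.

test_that("atom-mapped reactions parse and are carbon-balanced", {
  net <- toy_network(list(
    list("CS", "OAA (abcd) + AcCoA (ef) -> Cit (efbcda)", FALSE, "internal"),
    list("IN1", "OAA.ext (abcd) -> OAA (abcd)", FALSE, "uptake"),
    list("IN2", "Ac.ext (ab) -> AcCoA (ab)", FALSE, "uptake"),
    list("OUT", "Cit (abcdef) -> Cit.ext (abcdef)", FALSE, "release")))
  r <- net$reactions$CS
  expect_equal(length(r$products[[1]]$atoms), 6)
  expect_equal(sort(unlist(lapply(r$reactants, `[[`, "atoms"))),
               sort(r$products[[1]]$atoms))
  # atom conservation across every bundled reaction
  full <- beta_cell_network()
  for (rx in full$reactions) {
    expect_identical(sort(unlist(lapply(rx$reactants, `[[`, "atoms"))),
                     sort(unlist(lapply(rx$products, `[[`, "atoms"))),
                     label = rx$id)
  }
})

test_that("malformed networks are rejected with informative errors", {
  expect_error(
    toy_network(list(list("BAD", "A (ab) -> B (abc)", FALSE, "internal"))),
    "BAD.*unbalanced")
  expect_error(
    toy_network(list(
      list("R1", "A.ext (a) -> A (a)", FALSE, "uptake"),
      list("R1", "A (a) -> B.ext (a)", FALSE, "release"))),
    "duplicate reaction id")
  expect_error(
    toy_network(list(list("DUP", "A (aa) -> B (aa)", FALSE, "internal"))),
    "letter used twice")
  expect_error(
    toy_network(list(list("CO", "2 A (ab) -> B (ab) + C (a)", FALSE,
                          "internal"))),
    "coefficients")
})

test_that("validation reports dead ends and the free-flux dimension", {
  full <- beta_cell_network()
  rep <- validate_network(full)
  expect_length(rep$dead_ends, 0)
  # independent rank oracle: free dim = #fluxes - rank, rank via svd
  sv <- svd(full$S)$d
  rank_svd <- sum(sv > 1e-10 * max(sv))
  expect_equal(rep$free_dim, ncol(full$S) - rank_svd)
  expect_equal(rep$free_dim, ncol(null_space(full$S)))
  expect_gt(rep$free_dim, 0)

  orphan <- toy_network(list(
    list("U", "A.ext (a) -> A (a)", FALSE, "uptake"),
    list("R", "A (a) -> X (a)", FALSE, "internal"),
    list("L", "A (a) -> A.out (a)", FALSE, "release")))
  expect_true("X" %in% validate_network(orphan)$dead_ends)
})

test_that("EMU decomposition traces minimal backward closures", {
  lin <- toy_network(list(
    list("U", "A.ext (ab) -> A (ab)", FALSE, "uptake"),
    list("R1", "A (ab) -> B (ab)", FALSE, "internal"),
    list("R2", "B (ab) -> C (ab)", FALSE, "internal"),
    list("L", "C (ab) -> C.ext (ab)", FALSE, "release")))
  es <- emu_decompose(lin, list(list(species = "C", positions = c(1, 2))))
  keys <- names(es$emus)
  expect_setequal(keys, c("C[1,2]", "B[1,2]", "A[1,2]", "A.ext[1,2]"))

  clv <- toy_network(list(
    list("U", "F.ext (abcdef) -> F6P (abcdef)", FALSE, "uptake"),
    list("ALD", "F6P (abcdef) -> DHAP (cba) + GAP (def)", FALSE, "internal"),
    list("L1", "GAP (abc) -> GAP.ext (abc)", FALSE, "release"),
    list("L2", "DHAP (abc) -> DHAP.ext (abc)", FALSE, "release")))
  es <- emu_decompose(clv, list(list(species = "GAP", positions = 1:3)))
  expect_true("F6P[4,5,6]" %in% names(es$emus))
  expect_false("F6P[1,2,3]" %in% names(es$emus))

  expect_error(
    emu_decompose(lin, list(list(species = "C", positions = c(1, 3)))),
    "out of range")
})

test_that("EMU closure matches an independent brute-force closure oracle", {
  full <- beta_cell_network()
  es <- emu_decompose(full, list(list(species = "Cit", positions = 1:6)))
  # oracle: naive worklist over (species, positions) using raw atom maps
  inputs <- c(full$medium, full$unbalanced)
  seen <- character(0)
  work <- list(list(sp = "Cit", pos = 1:6))
  keyf <- function(sp, pos) paste0(sp, "[", paste(sort(pos), collapse = ","), "]")
  while (length(work)) {
    it <- work[[1]]; work[[1]] <- NULL
    k <- keyf(it$sp, it$pos)
    if (k %in% seen) next
    seen <- c(seen, k)
    if (it$sp %in% inputs) next
    orients <- list(it$pos)
    if (it$sp %in% full$symmetric) {
      orients <- c(orients, list(sort(full$species[[it$sp]] + 1 - it$pos)))
    }
    for (e in full$expanded) {
      for (p in e$products) {
        if (p$species != it$sp) next
        for (pos in orients) {
          need <- p$atoms[pos]
          for (r in e$reactants) {
            hit <- which(r$atoms %in% need)
            if (length(hit)) {
              work[[length(work) + 1L]] <- list(sp = r$species, pos = sort(hit))
            }
          }
        }
      }
    }
  }
  expect_setequal(names(es$emus), seen)
})
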