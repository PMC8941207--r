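# Independent oracles, deliberately implemented with different algorithms
# than the package internals.

# ---- Brute-force steady-state isotopomer simulator -------------------------
# Represents every balanced species by its full 2^n isotopomer distribution
# (bitmask state over carbon positions, bit i = carbon i+1 labeled) and
# iterates the flux-weighted production balance to a fixed point. Pool
# independence across reactant entries, as in any steady-state MFA model.

bf_simulate <- function(model, net, exch = NULL, tracer = NULL, nat13c = 0,
                        tol = 1e-13, maxit = 50000) {
  w <- betaflux:::.oneway_fluxes(model, net, exch)
  expd <- model$expanded
  nsp <- model$species
  inputs <- c(model$medium, model$unbalanced)

  input_dist <- function(sp) {
    n <- nsp[[sp]]
    per_pos_nat <- lapply(seq_len(n), function(i) c(1 - nat13c, nat13c))
    dist_from <- function(perpos) {
      d <- 1
      for (p in perpos) d <- as.vector(outer(d, p))  # bit i-1 <-> position i
      d
    }
    natd <- dist_from(per_pos_nat)
    if (!is.null(tracer) && tracer$species == sp) {
      perpos <- lapply(seq_len(n), function(i) {
        if (i %in% tracer$positions) c(1 - tracer$enrichment, tracer$enrichment)
        else c(1 - nat13c, nat13c)
      })
      tracer$fraction * dist_from(perpos) + (1 - tracer$fraction) * natd
    } else natd
  }

  dists <- list()
  for (sp in names(nsp)) {
    n <- nsp[[sp]]
    dists[[sp]] <- if (sp %in% inputs) input_dist(sp) else {
      d <- rep(0, 2^n); d[1] <- 1; d
    }
  }

  # per (reaction, product entry): mapping from product positions to
  # (reactant entry, reactant position)
  prod_terms <- list()
  for (k in seq_along(expd)) {
    e <- expd[[k]]
    for (pi in seq_along(e$products)) {
      p <- e$products[[pi]]
      n <- length(p$atoms)
      srcs <- lapply(seq_len(n), function(j) {
        for (ri in seq_along(e$reactants)) {
          hit <- which(e$reactants[[ri]]$atoms == p$atoms[j])
          if (length(hit)) return(c(ri, hit))
        }
        stop("unmapped atom")
      })
      prod_terms[[length(prod_terms) + 1L]] <-
        list(k = k, species = p$species, n = n,
             rsp = vapply(e$reactants, `[[`, "", "species"),
             src = srcs)
    }
  }

  product_dist <- function(tm) {
    out <- rep(0, 2^tm$n)
    for (state in 0:(2^tm$n - 1)) {
      bits <- bitwAnd(bitwShiftR(state, 0:(tm$n - 1)), 1L)
      # group positions by reactant entry; probability = product of
      # marginals of each reactant entry over its mapped positions
      pr <- 1
      for (ri in unique(vapply(tm$src, `[[`, 0, 1))) {
        ppos <- which(vapply(tm$src, `[[`, 0, 1) == ri)
        rpos <- vapply(tm$src[ppos], `[[`, 0, 2)
        want <- bits[ppos]
        d <- dists[[tm$rsp[ri]]]
        nr <- nsp[[tm$rsp[ri]]]
        m <- 0
        for (rs in 0:(2^nr - 1)) {
          rb <- bitwAnd(bitwShiftR(rs, 0:(nr - 1)), 1L)
          if (all(rb[rpos] == want)) m <- m + d[rs + 1]
        }
        pr <- pr * m
      }
      out[state + 1] <- pr
    }
    out
  }

  balanced <- model$balanced
  for (it in seq_len(maxit)) {
    delta <- 0
    for (sp in balanced) {
      num <- rep(0, 2^nsp[[sp]])
      tot <- 0
      for (tm in prod_terms) {
        if (tm$species != sp || w[tm$k] == 0) next
        num <- num + w[tm$k] * product_dist(tm)
        tot <- tot + w[tm$k]
      }
      if (tot == 0) next
      newd <- num / tot
      if (sp %in% model$symmetric) {
        n <- nsp[[sp]]
        rev_idx <- vapply(0:(2^n - 1), function(st) {
          bits <- bitwAnd(bitwShiftR(st, 0:(n - 1)), 1L)
          sum(rev(bits) * 2^(0:(n - 1)))
        }, 0)
        newd <- 0.5 * (newd + newd[rev_idx + 1])
      }
      delta <- max(delta, max(abs(newd - dists[[sp]])))
      dists[[sp]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("brute-force simulator did not converge")

  list(dists = dists,
       emu_mid = function(sp, positions) {
         d <- dists[[sp]]
         n <- nsp[[sp]]
         out <- rep(0, length(positions) + 1)
         for (st in 0:(2^n - 1)) {
           bits <- bitwAnd(bitwShiftR(st, 0:(n - 1)), 1L)
           out[sum(bits[positions]) + 1] <- out[sum(bits[positions]) + 1] +
             d[st + 1]
         }
         out
       })
}

# ---- Natural-abundance MID by explicit heavy-atom counting -----------------
# Sums binomial/trinomial terms over the number of heavy atoms of each
# element, independent of the package's convolution code.

bf_natural_mid <- function(counts, max_shift) {
  iso <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
              N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
              Si = c(0.9222, 0.0468, 0.0310))
  # per element: probability of total shift s from n atoms
  el_shift <- function(ab, n, smax) {
    out <- rep(0, smax + 1)
    if (length(ab) == 2) {
      for (k in 0:min(n, smax)) out[k + 1] <- stats::dbinom(k, n, ab[2])
      out[smax + 1] <- out[smax + 1] * 1  # truncated tail ignored
    } else {
      for (k1 in 0:n) for (k2 in 0:(n - k1)) {
        s <- k1 + 2 * k2
        if (s > smax) next
        out[s + 1] <- out[s + 1] +
          factorial(n) / (factorial(k1) * factorial(k2) *
                            factorial(n - k1 - k2)) *
          ab[2]^k1 * ab[3]^k2 * ab[1]^(n - k1 - k2)
      }
    }
    out
  }
  total <- rep(0, max_shift + 1); total[1] <- 1
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    es <- el_shift(iso[[el]], counts[[el]], max_shift)
    new <- rep(0, max_shift + 1)
    for (a in 0:max_shift) for (b in 0:(max_shift - a)) {
      new[a + b + 1] <- new[a + b + 1] + total[a + 1] * es[b + 1]
    }
    total <- new
  }
  total
}
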