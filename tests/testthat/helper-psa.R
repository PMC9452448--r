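# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately re-derive every quantity by per-iteration
# enumeration (loops, counting), sharing no code with the package internals
# they check.

# PSA whose NMB at any WTP equals `nmb` exactly: effects 0, costs = -nmb.
# `nmb` is an S x N matrix in the row-per-strategy orientation of the
# worked examples.
psa_from_nmb <- function(nmb, labels = paste0("S", seq_len(nrow(nmb)))) {
  psa_from_matrices(costs = -t(nmb),
                    effects = matrix(0, ncol(nmb), nrow(nmb)),
                    strategies = labels)
}

# The two-strategy worked example: NMB rows A = (10, 20, 30), B = (15, 15, 15).
toy_psa <- function() {
  psa_from_nmb(rbind(A = c(10, 20, 30), B = c(15, 15, 15)),
               labels = c("A", "B"))
}

random_psa <- function(s, n, seed) {
  withr::with_seed(seed, {
    psa_from_matrices(
      costs = matrix(stats::runif(n * s, 1000, 50000), n, s),
      effects = matrix(stats::runif(n * s, 0.5, 3), n, s)
    )
  })
}

nmb_of <- function(psa, w) w * psa$effects - psa$costs  # N x S

# --- brute-force per-iteration oracles (S x N / per-strategy loops) -------

oracle_ceac <- function(psa, w) {
  nmb <- nmb_of(psa, w)
  s <- ncol(nmb)
  wins <- numeric(s)
  for (i in seq_len(nrow(nmb))) {
    row <- nmb[i, ]
    best <- which(row == max(row))
    wins[best] <- wins[best] + 1 / length(best)
  }
  wins / nrow(nmb)
}

oracle_elc <- function(psa, w) {
  nmb <- nmb_of(psa, w)
  s <- ncol(nmb)
  loss <- numeric(s)
  for (i in seq_len(nrow(nmb))) {
    loss <- loss + (max(nmb[i, ]) - nmb[i, ])
  }
  unname(loss / nrow(nmb))
}

oracle_evpi <- function(psa, w) {
  nmb <- nmb_of(psa, w)
  e_max <- mean(apply(nmb, 1, max))
  max_e <- max(colMeans(nmb))
  e_max - max_e
}

oracle_inb <- function(psa, w) {
  nmb <- nmb_of(psa, w)
  out <- nmb
  for (i in seq_len(nrow(nmb))) {
    row <- sort(nmb[i, ], decreasing = TRUE)
    for (j in seq_len(ncol(nmb))) {
      out[i, j] <- if (nmb[i, j] == row[1]) row[1] - row[2]
                   else nmb[i, j] - row[1]
    }
  }
  out
}

oracle_exceedance <- function(values, x) {
  vapply(x, function(xx) sum(values >= xx) / length(values), numeric(1))
}

oracle_cdf <- function(values, x) {
  vapply(x, function(xx) sum(values <= xx) / length(values), numeric(1))
}

oracle_rank_cumprob <- function(psa, w) {
  nmb <- nmb_of(psa, w)
  s <- ncol(nmb)
  n <- nrow(nmb)
  cum <- matrix(0, s, s)  # strategy x rank
  for (i in seq_len(n)) {
    row <- nmb[i, ]
    for (j in seq_len(s)) {
      rk <- 1 + sum(row > row[j])   # competition rank
      cum[j, rk:s] <- cum[j, rk:s] + 1
    }
  }
  cum / n
}

# value column of a curve tibble for one strategy, in wtp order
curve_values <- function(tbl, strat) {
  sub <- tbl[tbl$strategy == strat, ]
  sub$value[order(sub$wtp)]
}
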