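test_that("incremental NMB follows the winner/loser rule", {
  p <- toy_psa()
  inb <- incremental_nmb(p, wtp = 1)
  expect_equal(inb$values[, "A"], c(-5, 5, 15))
  expect_equal(inb$values[, "B"], c(5, -5, -15))

  # two equal maxima: both tied strategies carry exactly zero
  tie <- psa_from_nmb(rbind(X = c(9, 9, 1), Y = c(9, 9, 2)),
                      labels = c("X", "Y"))
  inb2 <- incremental_nmb(tie, wtp = 1)
  expect_equal(unname(inb2$values[1, ]), c(0, 0))
  expect_equal(unname(inb2$values[2, ]), c(0, 0))
  expect_equal(unname(inb2$values[3, ]), c(-1, 1))

  expect_error(incremental_nmb(psa_from_nmb(rbind(c(1, 2, 3)))),
               "at least two strategies")
})

test_that("per iteration exactly the winning set is non-negative", {
  p <- random_psa(4, 25, seed = 2)
  inb <- incremental_nmb(p, wtp = 50000)
  v <- inb$values
  for (i in seq_len(nrow(v))) {
    expect_equal(sum(v[i, ] >= 0), 1)       # continuous draws: no ties
    expect_true(all(v[i, -which.max(v[i, ])] <= 0))
  }
})

test_that("incremental NMB matches the brute-force oracle", {
  for (seed in 1:5) {
    p <- random_psa(s = 2 + seed %% 3, n = 6, seed = 40 + seed)
    inb <- incremental_nmb(p, wtp = 45000)
    expect_equal(inb$values, oracle_inb(p, 45000), ignore_attr = TRUE)
  }
})

test_that("benefit density with zero smoothing is the normalized histogram", {
  p <- random_psa(3, 50, seed = 8)
  nmb <- compute_benefit(p, 50000)
  d <- benefit_density(nmb, n_bins = 20, smooth_param = 0)

  v <- nmb$values
  lo <- min(v)
  width <- (max(v) - lo) / 20
  mids <- lo + width * (1:20 - 0.5)
  for (s in colnames(v)) {
    idx <- pmin(pmax(ceiling((v[, s] - lo) / width), 1), 20)
    counts <- tabulate(idx, 20)
    y0 <- counts / (nrow(v) * width)
    # same trapezoid normalization convention, computed independently
    tr <- sum(diff(mids) * (y0[-1] + y0[-20]) / 2)
    expect_equal(d$y[d$strategy == s], y0 / tr)
  }
})

test_that("benefit densities integrate to one for all parameter settings", {
  p <- random_psa(4, 120, seed = 13)
  for (setting in list(c(100, 0.5), c(500, 0.5), c(50, 0), c(30, 2))) {
    d <- benefit_density(compute_benefit(p, 50000),
                         n_bins = setting[1], smooth_param = setting[2])
    for (s in levels(d$strategy)) {
      sub <- d[d$strategy == s, ]
      integral <- sum(diff(sub$x) * (sub$y[-1] + sub$y[-nrow(sub)]) / 2)
      expect_lt(abs(integral - 1), 1e-6)
      expect_true(all(sub$y >= 0))
    }
  }
})

test_that("degenerate (constant) benefit values give a flagged spike", {
  const <- psa_from_nmb(rbind(rep(3, 10), rep(3, 10)))
  expect_warning(
    d <- benefit_density(compute_benefit(const, 1), n_bins = 11,
                         smooth_param = 0),
    "single-spike"
  )
  expect_true(attr(d, "degenerate"))
  sub <- d[d$strategy == "S1", ]
  expect_equal(sum(sub$y > 0), 1)
  expect_equal(sub$x[sub$y > 0], 3, tolerance = 0.1)
})

test_that("stochastic dominance curves are exceedance probabilities", {
  p <- psa_from_nmb(rbind(c(10, 20, 30), c(5, 5, 5)), labels = c("A", "B"))
  d <- stochastic_dominance_curves(p, wtp = 1)
  a <- d[d$strategy == "A", ]
  expect_equal(a$y[a$x == 20], 2 / 3)
  expect_equal(a$y[a$x == 5], 1)          # below A's minimum
  expect_true(all(d$y[d$x == min(d$x)] == 1))
  expect_true(all(diff(a$y) <= 0))

  # pointwise dominance: A >= B in every iteration => curve_A >= curve_B
  b <- d[d$strategy == "B", ]
  expect_true(all(a$y >= b$y))
})

test_that("incremental benefit curves are CDFs with an x = 0 reference", {
  p <- toy_psa()
  ib <- incremental_benefit_curve(p, wtp = 1)
  a <- ib[ib$strategy == "A", ]
  expect_equal(a$y[a$x == -5], 1 / 3)  # P(INB_A <= 0) via the step at -5
  expect_equal(a$y[a$x == max(a$x)], 1)
  expect_true(all(diff(a$y) >= 0))
  expect_equal(attr(ib, "reference_x"), 0)
})

test_that("dominance and IBC agree with direct counting oracles", {
  for (seed in 1:4) {
    p <- random_psa(3, 6, seed = 60 + seed)
    nmb <- compute_benefit(p, 50000)
    d <- stochastic_dominance_curves(nmb)
    x <- sort(unique(as.vector(nmb$values)))
    for (j in 1:3) {
      expect_equal(d$y[d$strategy == nmb$strategies[j]],
                   oracle_exceedance(nmb$values[, j], x))
    }
    inb <- incremental_nmb(nmb)
    ib <- incremental_benefit_curve(inb)
    xi <- sort(unique(as.vector(inb$values)))
    for (j in 1:3) {
      expect_equal(ib$y[ib$strategy == inb$strategies[j]],
                   oracle_cdf(inb$values[, j], xi))
    }
  }
})

test_that("return-risk points are sample means and n-1 standard deviations", {
  const <- psa_from_nmb(rbind(rep(6, 5)))
  rr <- return_risk(const, wtp = 1)
  expect_equal(rr$mean, 6)
  expect_equal(rr$sd, 0)

  p <- psa_from_nmb(rbind(c(10, 20, 30)))
  rr2 <- return_risk(p, wtp = 1)
  expect_equal(rr2$mean, 20)
  expect_equal(rr2$sd, 10)

  shifted <- psa_from_nmb(rbind(c(10, 20, 30) + 7))
  rr3 <- return_risk(shifted, wtp = 1)
  expect_equal(rr3$mean, 27)
  expect_equal(rr3$sd, 10)
})

test_that("cumulative rankogram counts competition ranks", {
  p <- toy_psa()
  rg <- cumulative_rankogram(p, wtp = 1)
  a <- rg[rg$strategy == "A", ]
  b <- rg[rg$strategy == "B", ]
  expect_equal(a$cum_prob[a$rank == 1], 2 / 3)
  expect_equal(b$cum_prob[b$rank == 1], 1 / 3)
  expect_equal(a$cum_prob[a$rank == 2], 1)
  expect_equal(b$cum_prob[b$rank == 2], 1)

  # without ties each iteration assigns each rank once:
  # sum over strategies of P(rank <= r) = r
  p2 <- random_psa(4, 30, seed = 21)
  rg2 <- cumulative_rankogram(p2, wtp = 50000)
  for (r in 1:4) {
    expect_equal(sum(rg2$cum_prob[rg2$rank == r]), r)
  }
  expect_true(all(rg2$cum_prob[rg2$rank == 4] == 1))

  # matches the enumeration oracle
  cum <- oracle_rank_cumprob(p2, 50000)
  for (j in 1:4) {
    expect_equal(rg2$cum_prob[rg2$strategy == p2$strategies[j]], cum[j, ])
  }
})

test_that("rank-1 probability equals the strict CEAC without ties", {
  p <- random_psa(5, 40, seed = 17)
  w <- 50000
  rg <- cumulative_rankogram(p, wtp = w)
  cc <- ceac(p, wtp = w)
  r1 <- rg$cum_prob[rg$rank == 1]
  expect_equal(r1, cc$value[order(match(cc$strategy, p$strategies))])
})
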