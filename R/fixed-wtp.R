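#' Incremental net monetary benefit per iteration
#'
#' For each PSA iteration, a strategy's incremental NMB (INB) is its NMB
#' minus the maximum NMB of that iteration — unless the strategy *is* the
#' iteration's best, in which case its INB is the maximum minus the second
#' highest NMB. So in every iteration exactly the winning strategy carries a
#' non-negative value (its winning margin) and all others carry non-positive
#' values; when several strategies tie for the maximum they all carry 0.
#'
#' @param nmb An `nmb_matrix` from [compute_benefit()], or a [psa()] result /
#'   long data frame (then NMB at `wtp` is computed first). At least two
#'   strategies are required.
#' @param wtp Fixed WTP threshold used when `nmb` is not already a benefit
#'   matrix; default 50,000 currency units per effect unit.
#' @return An `inb_matrix`: same shape and fields as an `nmb_matrix`, with
#'   `measure` suffixed `"_incremental"`.
#' @examples
#' p <- example_psa()
#' inb <- incremental_nmb(p, wtp = 50000)
#' @export
incremental_nmb <- function(nmb, wtp = 50000) {
  nmb <- as_nmb(nmb, wtp)
  v <- nmb$values
  if (ncol(v) < 2) {
    stop("incremental NMB requires at least two strategies", call. = FALSE)
  }
  m1 <- row_max(v)
  # second highest: mask one occurrence of the max per row, then re-max
  first_max <- max.col(v, ties.method = "first")
  masked <- v
  masked[cbind(seq_len(nrow(v)), first_max)] <- -Inf
  m2 <- row_max(masked)
  inb <- v - m1
  winners <- v == m1
  margin <- m1 - m2
  for (j in seq_len(ncol(v))) {
    w <- winners[, j]
    inb[w, j] <- margin[w]
  }
  structure(
    list(values = inb, wtp = nmb$wtp,
         measure = paste0(nmb$measure, "_incremental"),
         strategies = nmb$strategies, currency = nmb$currency,
         effect_unit = nmb$effect_unit),
    class = c("inb_matrix", "nmb_matrix")
  )
}

#' Smoothed, normalized benefit density per strategy
#'
#' Approximates the distribution of (incremental) net monetary benefit per
#' strategy by a normalized smoothened histogram: all strategies share one
#' equal-width bin grid spanning the pooled value range; per-strategy counts
#' are converted to a density, passed once through a three-point weighted
#' moving average with kernel `(a, 1, a) / (1 + 2a)` (`a` = `smooth_param`,
#' edges reflected), and renormalized so the trapezoid integral over the bin
#' midpoints is exactly 1. With `smooth_param = 0` the smoothing pass is the
#' identity and the curve is the raw histogram under the same normalization.
#'
#' @inheritParams incremental_nmb
#' @param n_bins Number of equal-width bins (>= 2); the reference analyses
#'   use 100 (net benefit) and 500 (incremental benefit) bins.
#' @param smooth_param Smoothing weight `a >= 0`; default 0.5.
#' @return A `density_curves` tibble with columns `strategy`, `x` (bin
#'   midpoint), `y` (density), `n_bins`, `smooth_param`; attributes `wtp`,
#'   `measure` and `degenerate` (TRUE when all pooled values are equal, in
#'   which case the mass sits in the central bin of an artificial unit-width
#'   range).
#' @export
benefit_density <- function(nmb, n_bins = 100, smooth_param = 0.5,
                            wtp = 50000) {
  nmb <- as_nmb(nmb, wtp)
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2) {
    stop("n_bins must be a single integer >= 2", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (!is.numeric(smooth_param) || length(smooth_param) != 1 ||
      smooth_param < 0) {
    stop("smooth_param must be a single value >= 0", call. = FALSE)
  }
  v <- nmb$values
  lo <- min(v)
  hi <- max(v)
  degenerate <- lo == hi
  if (degenerate) {
    lo <- lo - 0.5
    hi <- hi + 0.5
    warning("all benefit values are equal; returning a single-spike density ",
            "on an artificial unit-width range", call. = FALSE)
  }
  width <- (hi - lo) / n_bins
  mids <- lo + width * (seq_len(n_bins) - 0.5)
  n <- nrow(v)
  out <- lapply(seq_len(ncol(v)), function(j) {
    idx <- pmin.int(pmax.int(ceiling((v[, j] - lo) / width), 1L), n_bins)
    y <- tabulate(idx, nbins = n_bins) / (n * width)
    y <- smooth_density(y, smooth_param)
    y / trapezoid(mids, y)
  })
  tbl <- tibble::tibble(
    strategy = factor(rep(nmb$strategies, each = n_bins),
                      levels = nmb$strategies),
    x = rep(mids, ncol(v)),
    y = unlist(out),
    n_bins = n_bins,
    smooth_param = smooth_param
  )
  new_curve_tbl(tbl, "density_curves", wtp = nmb$wtp, measure = nmb$measure,
                degenerate = degenerate, currency = nmb$currency)
}

# One pass of the (a, 1, a)/(1+2a) moving average, reflecting at the edges
# (y[0] := y[1], y[K+1] := y[K]). Mass-preserving; identity when a = 0.
smooth_density <- function(y, a) {
  if (a == 0 || length(y) < 2) return(y)
  k <- length(y)
  left <- c(y[1], y[-k])
  right <- c(y[-1], y[k])
  (a * left + y + a * right) / (1 + 2 * a)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Stochastic dominance curves
#'
#' Empirical exceedance curves per strategy: the probability that the
#' strategy's net monetary benefit is greater than or equal to the value on
#' the x axis. Curves are evaluated at the pooled observed values (exact step
#' functions, no binning); a strategy whose curve lies above another's
#' everywhere first-order dominates it.
#'
#' @inheritParams incremental_nmb
#' @return A `dominance_curves` tibble with columns `strategy`, `x` and `y`
#'   (`P(NMB >= x)`); attributes `wtp` and `measure`.
#' @export
stochastic_dominance_curves <- function(nmb, wtp = 50000) {
  cumulative_curves(as_nmb(nmb, wtp), direction = "geq", "dominance_curves")
}

#' Incremental benefit curves
#'
#' Empirical cumulative curves of the incremental NMB per strategy: the
#' probability that a strategy's INB is less than or equal to the value on
#' the x axis, evaluated at the pooled observed values. The vertical
#' reference at x = 0 — the point where the maximum and second highest NMB
#' coincide, i.e. where the INB rule switches — is carried as attribute
#' `reference_x`.
#'
#' @param inb An `inb_matrix` from [incremental_nmb()], or a [psa()] result /
#'   long data frame (the INB at `wtp` is then computed first).
#' @inheritParams incremental_nmb
#' @return An `ibc_curves` tibble with columns `strategy`, `x` and `y`
#'   (`P(INB <= x)`); attributes `wtp`, `measure`, `reference_x = 0`.
#' @export
incremental_benefit_curve <- function(inb, wtp = 50000) {
  if (!inherits(inb, "inb_matrix")) inb <- incremental_nmb(inb, wtp)
  out <- cumulative_curves(inb, direction = "leq", "ibc_curves")
  attr(out, "reference_x") <- 0
  out
}

cumulative_curves <- function(nmb, direction, class) {
  v <- nmb$values
  x <- sort(unique(as.vector(v)))
  ys <- lapply(seq_len(ncol(v)), function(j) {
    sv <- sort(v[, j])
    n <- length(sv)
    if (direction == "leq") {
      findInterval(x, sv) / n                         # P(V <= x)
    } else {
      (n - findInterval(x, sv, left.open = TRUE)) / n # P(V >= x)
    }
  })
  tbl <- tibble::tibble(
    strategy = factor(rep(nmb$strategies, each = length(x)),
                      levels = nmb$strategies),
    x = rep(x, ncol(v)),
    y = unlist(ys)
  )
  new_curve_tbl(tbl, class, wtp = nmb$wtp, measure = nmb$measure,
                direction = direction, currency = nmb$currency)
}

#' Return-risk points
#'
#' Per-strategy mean (return) and sample standard deviation (risk,
#' denominator n - 1) of the net monetary benefit at a fixed WTP. Reading sd
#' as the full description of uncertainty presumes NMB is roughly normal;
#' the density and cumulative methods show the actual shape.
#'
#' @inheritParams incremental_nmb
#' @return A `return_risk_points` tibble with columns `strategy`, `mean` and
#'   `sd`; attributes `wtp` and `measure`.
#' @export
return_risk <- function(nmb, wtp = 50000) {
  nmb <- as_nmb(nmb, wtp)
  tbl <- tibble::tibble(
    strategy = factor(nmb$strategies, levels = nmb$strategies),
    mean = unname(colMeans(nmb$values)),
    sd = unname(apply(nmb$values, 2, stats::sd))
  )
  new_curve_tbl(tbl, "return_risk_points", wtp = nmb$wtp,
                measure = nmb$measure, currency = nmb$currency)
}

# Per-iteration competition ranks of NMB: 1 = highest; ties all get the
# lowest applicable rank (min/competition), keeping rank 1 aligned with
# "has the highest NMB".
rank_matrix <- function(values) {
  t(apply(-values, 1, rank, ties.method = "min"))
}

#' Cumulative rankogram
#'
#' Ranks the strategies within each PSA iteration by net monetary benefit
#' (rank 1 = highest; ties share the best applicable rank) and plots, for
#' each strategy, the cumulative probability of achieving a rank less than
#' or equal to r, for r = 1..S. Every curve reaches 1 at r = S, and the value
#' at r = 1 is the strategy's probability of being best.
#'
#' @inheritParams incremental_nmb
#' @return A `rankogram_curves` tibble with columns `strategy`, `rank` and
#'   `cum_prob`; attributes `wtp` and `measure`.
#' @export
cumulative_rankogram <- function(nmb, wtp = 50000) {
  nmb <- as_nmb(nmb, wtp)
  v <- nmb$values
  if (ncol(v) < 2) {
    stop("the rankogram requires at least two strategies", call. = FALSE)
  }
  rk <- rank_matrix(v)
  s <- ncol(v)
  cum <- vapply(seq_len(s), function(r) colMeans(rk <= r), numeric(s))
  tbl <- tibble::tibble(
    strategy = factor(rep(nmb$strategies, each = s), levels = nmb$strategies),
    rank = rep(seq_len(s), s),
    cum_prob = as.vector(t(cum))
  )
  new_curve_tbl(tbl, "rankogram_curves", wtp = nmb$wtp, measure = nmb$measure)
}
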