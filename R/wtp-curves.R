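#' Cost-effectiveness acceptability curve (CEAC)
#'
#' For each strategy and each willingness-to-pay value, the proportion of PSA
#' iterations in which that strategy has the highest net monetary benefit.
#' Iterations where several strategies tie for the maximum split the win
#' equally among the tied strategies, so the probabilities at every WTP sum
#' to one. The frontier column marks the CEAF: the strategy with the highest
#' *expected* NMB, which need not be the one with the highest probability.
#'
#' @param psa A [psa()] result or long data frame.
#' @param wtp Numeric WTP grid; defaults to [wtp_grid()].
#' @return A `ceac_curves` tibble with columns `strategy`, `wtp`, `value`
#'   (probability of cost-effectiveness) and `on_frontier`; attribute
#'   `value_kind = "probability"`.
#' @examples
#' p <- example_psa()
#' head(ceac(p, wtp = c(0, 25000, 50000)))
#' @export
ceac <- function(psa, wtp = wtp_grid()) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  probs <- vapply(wtp, function(w) {
    nmb <- w * psa$effects - psa$costs
    m <- row_max(nmb)
    wins <- nmb == m                      # N x S logical
    colSums(wins / rowSums(wins)) / nrow(nmb)
  }, numeric(n_strategies(psa)))
  curve_set(psa, wtp, probs, "probability", "ceac_curves")
}

#' Expected loss curves (ELC)
#'
#' The per-iteration loss of a strategy is the difference between the highest
#' net monetary benefit reached in that iteration and the strategy's own NMB;
#' the ELC plots the mean of that loss over iterations against
#' willingness-to-pay. The strategy with the lowest expected loss at a WTP is
#' exactly the frontier (highest expected NMB) strategy, and the lower
#' envelope of the curves is the EVPI.
#'
#' @inheritParams ceac
#' @return An `elc_curves` tibble with columns `strategy`, `wtp`, `value`
#'   (expected loss, currency units) and `on_frontier`; attribute
#'   `value_kind = "expected_loss"`.
#' @export
elc <- function(psa, wtp = wtp_grid()) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  losses <- vapply(wtp, function(w) {
    nmb <- w * psa$effects - psa$costs
    colMeans(row_max(nmb) - nmb)
  }, numeric(n_strategies(psa)))
  curve_set(psa, wtp, losses, "expected_loss", "elc_curves")
}

#' Expected value of perfect information (EVPI)
#'
#' EVPI at a willingness-to-pay value is the expected NMB under perfect
#' information minus the expected NMB of the best-on-average strategy:
#' `E[max_s NMB_s] - max_s E[NMB_s]`. It equals the minimum of the expected
#' loss curves at that WTP (the ELC lower envelope), which is how it is
#' computed here, so the envelope identity holds exactly.
#'
#' @inheritParams ceac
#' @return A tibble with columns `wtp`, `evpi` and `strategy` (the frontier
#'   strategy whose loss curve attains the envelope).
#' @export
evpi <- function(psa, wtp = wtp_grid()) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  s <- n_strategies(psa)
  val <- numeric(length(wtp))
  front <- integer(length(wtp))
  for (i in seq_along(wtp)) {
    nmb <- wtp[i] * psa$effects - psa$costs
    loss <- colMeans(row_max(nmb) - nmb)
    front[i] <- which.min(loss)
    val[i] <- loss[front[i]]
  }
  tibble::tibble(wtp = wtp, evpi = val,
                 strategy = strategy_factor(psa, front))
}

#' Expected benefit plot data
#'
#' Mean net monetary benefit per strategy over a WTP grid, with an empirical
#' 95% band (2.5th and 97.5th percentiles of the per-iteration NMB values).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7); the band is convention sensitive, so the
#' convention is fixed and documented here.
#'
#' @inheritParams ceac
#' @param probs Lower and upper band percentiles, defaults `c(0.025, 0.975)`.
#' @return An `ebp_curves` tibble with columns `strategy`, `wtp`, `value`
#'   (mean NMB), `lower`, `upper` and `on_frontier`; attribute
#'   `value_kind = "mean_benefit"`.
#' @export
expected_benefit_curve <- function(psa, wtp = wtp_grid(),
                                   probs = c(0.025, 0.975)) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  stopifnot(length(probs) == 2, probs[1] < probs[2])
  s <- n_strategies(psa)
  stats_fun <- function(w) {
    nmb <- w * psa$effects - psa$costs
    rbind(colMeans(nmb),
          apply(nmb, 2, stats::quantile, probs = probs, names = FALSE,
                type = 7))
  }
  arr <- vapply(wtp, stats_fun, matrix(0, 3, s))
  dim(arr) <- c(3, s, length(wtp))                 # 3 x S x |grid|
  out <- curve_set(psa, wtp, matrix(arr[1, , ], nrow = s), "mean_benefit",
                   "ebp_curves")
  # curve_set lays out strategy-major blocks; match that order for the bands
  out$lower <- as.vector(t(matrix(arr[2, , ], nrow = s)))
  out$upper <- as.vector(t(matrix(arr[3, , ], nrow = s)))
  out
}

#' Frontier segments and their boundary ICERs
#'
#' Partitions the WTP grid into maximal intervals over which the frontier
#' (highest expected NMB) strategy is constant. The boundary between two
#' adjacent frontier strategies is reported as their incremental
#' cost-effectiveness ratio, computed analytically from mean costs and
#' effects — not read off the grid — so the expected loss curves of the two
#' strategies cross exactly at the reported ICER. A boundary where the two
#' strategies have equal mean effects has no defined ICER and is returned as
#' `NA` with `icer_defined = FALSE`.
#'
#' @inheritParams ceac
#' @return A tibble with one row per segment: `strategy`, `wtp_low`,
#'   `wtp_high`, `boundary_icer` (NA for the last segment) and
#'   `icer_defined`.
#' @export
frontier_segments <- function(psa, wtp = wtp_grid()) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  idx <- frontier_index(psa, wtp)
  runs <- rle(idx)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  k <- length(runs$values)
  mc <- colMeans(psa$costs)
  me <- colMeans(psa$effects)
  icer <- rep(NA_real_, k)
  defined <- rep(TRUE, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      a <- runs$values[i]
      b <- runs$values[i + 1]
      de <- me[b] - me[a]
      if (de == 0) {
        defined[i] <- FALSE
      } else {
        icer[i] <- (mc[b] - mc[a]) / de
      }
    }
  }
  tibble::tibble(
    strategy = strategy_factor(psa, runs$values),
    wtp_low = wtp[starts],
    wtp_high = wtp[ends],
    boundary_icer = icer,
    icer_defined = defined
  )
}

# Assemble the long curve tibble shared by ceac/elc/ebp.
# `values` is an S x |grid| matrix (or a vector when S == 1).
curve_set <- function(psa, wtp, values, value_kind, class) {
  s <- n_strategies(psa)
  g <- length(wtp)
  values <- matrix(values, nrow = s)
  front <- frontier_index(psa, wtp)
  strategy <- factor(rep(psa$strategies, times = g), levels = psa$strategies)
  on_front <- rep(seq_len(s), times = g) == rep(front, each = s)
  tbl <- tibble::tibble(
    strategy = strategy,
    wtp = rep(wtp, each = s),
    value = as.vector(values),
    on_frontier = on_front
  )
  # strategy-major within wtp; reorder to strategy blocks for readability
  tbl <- tbl[order(match(tbl$strategy, psa$strategies), tbl$wtp), ]
  new_curve_tbl(tbl, class, value_kind = value_kind,
                currency = psa$currency, effect_unit = psa$effect_unit)
}
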