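#' Per-iteration benefit of each strategy at one willingness-to-pay
#'
#' Converts a PSA result into a benefit matrix at a single willingness-to-pay
#' (WTP) threshold, under one of three benefit measures:
#' net monetary benefit `NMB = WTP * effect - cost` (currency units),
#' net health benefit `NHB = effect - cost / WTP` (effect units), or
#' return on investment `ROI = (WTP * effect - cost) / cost` (dimensionless).
#'
#' NMB is the measure every downstream method defaults to. NHB is NMB / WTP
#' cell-for-cell, so all winner-counting methods are identical under the two.
#' ROI is not translation invariant — adding a constant cost to every
#' strategy changes ROI rankings — so loss- and rank-based methods computed
#' from ROI answer a different question; they are permitted but the choice of
#' measure is carried in the result so exports stay labelled.
#'
#' @param psa A [psa()] result (or long data frame coercible with [as_psa()]).
#' @param wtp A single WTP threshold, currency per effect unit. Must be
#'   strictly positive for NHB and ROI.
#' @param measure `"NMB"`, `"NHB"` or `"ROI"`.
#' @return An `nmb_matrix`: a list with `values` (N x S numeric matrix),
#'   `wtp`, `measure`, `strategies`, `currency` and `effect_unit`.
#' @examples
#' p <- example_psa()
#' nmb <- compute_benefit(p, wtp = 50000)
#' expected_benefit(nmb)
#' @export
compute_benefit <- function(psa, wtp, measure = c("NMB", "NHB", "ROI")) {
  psa <- as_psa(psa)
  measure <- match.arg(measure)
  if (!is.numeric(wtp) || length(wtp) != 1 || !is.finite(wtp) || wtp < 0) {
    stop("wtp must be a single finite value >= 0", call. = FALSE)
  }
  if (measure %in% c("NHB", "ROI") && wtp == 0) {
    stop(measure, " is undefined at wtp = 0", call. = FALSE)
  }
  if (measure == "ROI" && any(psa$costs <= 0)) {
    stop("ROI requires all costs to be strictly positive", call. = FALSE)
  }
  values <- switch(measure,
    NMB = wtp * psa$effects - psa$costs,
    NHB = psa$effects - psa$costs / wtp,
    ROI = (wtp * psa$effects - psa$costs) / psa$costs
  )
  structure(
    list(values = values, wtp = wtp, measure = measure,
         strategies = psa$strategies, currency = psa$currency,
         effect_unit = psa$effect_unit),
    class = "nmb_matrix"
  )
}

#' @export
print.nmb_matrix <- function(x, ...) {
  cat("<nmb_matrix> ", x$measure, " at WTP ", format(x$wtp, big.mark = ","),
      ": ", ncol(x$values), " strategies x ", nrow(x$values),
      " iterations\n", sep = "")
  invisible(x)
}

#' Tidy a benefit matrix into a long tibble
#'
#' @param x An `nmb_matrix` from [compute_benefit()].
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `strategy`, `value`, `measure`,
#'   `wtp`.
#' @export
tidy.nmb_matrix <- function(x, ...) {
  n <- nrow(x$values)
  s <- ncol(x$values)
  tibble::tibble(
    iteration = rep(seq_len(n), s),
    strategy = factor(rep(x$strategies, each = n), levels = x$strategies),
    value = as.vector(x$values),
    measure = x$measure,
    wtp = x$wtp
  )
}

#' One-row-per-strategy summary of a benefit matrix
#'
#' @param x An `nmb_matrix` from [compute_benefit()].
#' @param ... Unused.
#' @return A tibble with per-strategy mean and sample standard deviation.
#' @export
tidy_summary <- function(x, ...) {
  tibble::tibble(
    strategy = factor(x$strategies, levels = x$strategies),
    mean = unname(colMeans(x$values)),
    sd = unname(apply(x$values, 2, stats::sd)),
    measure = x$measure,
    wtp = x$wtp
  )
}

# Accept either an nmb_matrix or anything as_psa() takes (then NMB at `wtp`).
as_nmb <- function(x, wtp = 50000, measure = "NMB") {
  if (inherits(x, "nmb_matrix")) x else compute_benefit(as_psa(x), wtp, measure)
}

#' Expected benefit per strategy
#'
#' Arithmetic mean of the per-iteration benefit over PSA iterations, for each
#' strategy — the quantity the acceptability frontier maximizes.
#'
#' @param nmb An `nmb_matrix` from [compute_benefit()].
#' @return A tibble with columns `strategy` and `expected_benefit`.
#' @export
expected_benefit <- function(nmb) {
  stopifnot(inherits(nmb, "nmb_matrix"))
  tibble::tibble(
    strategy = factor(nmb$strategies, levels = nmb$strategies),
    expected_benefit = unname(colMeans(nmb$values))
  )
}

# Index of the frontier (max expected NMB) strategy at each wtp value.
# Ties go to the lowest strategy index, so output is deterministic.
frontier_index <- function(psa, wtp) {
  me <- colMeans(psa$effects)
  mc <- colMeans(psa$costs)
  vapply(wtp, function(w) which.max(w * me - mc), integer(1))
}

#' Cost-effectiveness frontier strategy along a WTP grid
#'
#' At each willingness-to-pay value, the strategy with the highest expected
#' net monetary benefit (the CEAF strategy). Ties resolve to the strategy
#' listed first.
#'
#' @param psa A [psa()] result or long data frame.
#' @param wtp Numeric WTP grid (strictly increasing, >= 0); defaults to
#'   [wtp_grid()].
#' @return A tibble with columns `wtp` and `strategy`.
#' @export
frontier_strategy <- function(psa, wtp = wtp_grid()) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  tibble::tibble(
    wtp = wtp,
    strategy = strategy_factor(psa, frontier_index(psa, wtp))
  )
}
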