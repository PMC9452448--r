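#' Relaxation scheme for the relaxed CEAC
#'
#' The strict CEAC counts a strategy only when it attains the iteration
#' maximum NMB, which makes the curves collapse when many near-equivalent
#' strategies are compared. A relaxation loosens the cost-effectiveness
#' criterion; three schemes are supported:
#'
#' * `rank`: count a strategy when its within-iteration competition rank is
#'   `<= k` (k = 1 reduces to the strict CEAC).
#' * `absolute`: count when its NMB is within `delta` currency units of the
#'   iteration maximum (delta = 0 reduces to strict).
#' * `relative`: count when its NMB is within a fraction `1 - f` of the
#'   iteration maximum in magnitude, i.e. loss `<= (1 - f) * |max NMB|`
#'   (f = 1 reduces to strict). When the iteration maximum is positive this
#'   is exactly "NMB >= f x max NMB" — e.g. `f = 0.9995` counts strategies
#'   whose NMB is at least 99.95% of the best; defining it through the loss
#'   keeps the rule meaningful (and monotone in f) when the maximum is zero
#'   or negative.
#'
#' No default threshold is applied: the threshold drives the interpretation
#' of the relaxed curve and must be chosen — and motivated — by the analyst.
#' `f = 0.995` and `f = 0.9995` are conservative reference choices when NMB
#' differences between strategies are smaller than the accuracy with which
#' costs and effects are measured.
#'
#' @param scheme `"rank"`, `"absolute"` or `"relative"`.
#' @param k Rank cutoff (integer >= 1), `rank` scheme only.
#' @param delta Currency tolerance (>= 0), `absolute` scheme only.
#' @param f Fraction in (0, 1], `relative` scheme only.
#' @return A `relaxation_spec` object.
#' @examples
#' relaxation("relative", f = 0.9995)
#' relaxation("absolute", delta = 250)
#' relaxation("rank", k = 3)
#' @export
relaxation <- function(scheme = c("rank", "absolute", "relative"),
                       k = NULL, delta = NULL, f = NULL) {
  scheme <- match.arg(scheme)
  given <- c(rank = !is.null(k), absolute = !is.null(delta),
             relative = !is.null(f))
  if (!given[[scheme]] || sum(given) != 1) {
    stop("exactly the parameter matching the scheme must be given (rank: k, ",
         "absolute: delta, relative: f)", call. = FALSE)
  }
  par <- switch(scheme,
    rank = {
      if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
        stop("k must be a single integer >= 1", call. = FALSE)
      }
      as.integer(k)
    },
    absolute = {
      if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
          delta < 0) {
        stop("delta must be a single value >= 0", call. = FALSE)
      }
      as.numeric(delta)
    },
    relative = {
      if (!is.numeric(f) || length(f) != 1 || is.na(f) || f <= 0 || f > 1) {
        stop("f must lie in (0, 1]", call. = FALSE)
      }
      as.numeric(f)
    }
  )
  structure(list(scheme = scheme, parameter = par), class = "relaxation_spec")
}

#' @export
print.relaxation_spec <- function(x, ...) {
  nm <- switch(x$scheme, rank = "k", absolute = "delta", relative = "f")
  cat("<relaxation_spec> scheme = ", x$scheme, ", ", nm, " = ", x$parameter,
      "\n", sep = "")
  invisible(x)
}

#' Relaxed cost-effectiveness acceptability curve
#'
#' The CEAC with a loosened cost-effectiveness criterion (see [relaxation()]):
#' per iteration, every strategy meeting the criterion is counted, and the
#' curve shows the counted fraction per strategy. Several strategies may be
#' counted in one iteration, so — unlike the strict CEAC — the per-WTP values
#' are *not* renormalized and may sum to more than one: each curve is that
#' strategy's own acceptability. Every relaxed probability is >= the
#' strategy's strict CEAC probability.
#'
#' @inheritParams ceac
#' @param relax A [relaxation()] spec.
#' @return A `relaxed_ceac_curves` tibble with columns `strategy`, `wtp`,
#'   `value` and `on_frontier`; attributes `value_kind = "probability"`,
#'   `relaxation`.
#' @examples
#' p <- example_psa()
#' relaxed_ceac(p, wtp = c(25000, 50000), relax = relaxation("relative", f = 0.9995))
#' @export
relaxed_ceac <- function(psa, wtp = wtp_grid(), relax) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  if (!inherits(relax, "relaxation_spec")) {
    stop("relax must be a relaxation() spec", call. = FALSE)
  }
  s <- n_strategies(psa)
  probs <- vapply(wtp, function(w) {
    nmb <- w * psa$effects - psa$costs
    accepted <- switch(relax$scheme,
      rank = rank_matrix(nmb) <= relax$parameter,
      absolute = nmb >= row_max(nmb) - relax$parameter,
      relative = (row_max(nmb) - nmb) <=
        (1 - relax$parameter) * abs(row_max(nmb))
    )
    colMeans(accepted)
  }, numeric(s))
  out <- curve_set(psa, wtp, probs, "probability", "relaxed_ceac_curves")
  attr(out, "relaxation") <- relax
  out
}

#' Heat map data joining the CEAC and the ELC
#'
#' The CEAC carries the probability of cost-effectiveness, the ELC the
#' expected loss of picking a strategy; policy makers need both. This joins
#' the two curve sets per (strategy, WTP) so one can be drawn on the y axis
#' and the other on a color scale, and attaches the frontier segments whose
#' boundary ICERs become tick marks and whose strategies become region
#' labels.
#'
#' @inheritParams ceac
#' @param base Which quantity goes on the y axis: `"elc"` (expected loss,
#'   probability on the color scale — the variant that stays readable with
#'   many strategies) or `"ceac"` (the mirror image).
#' @param relax Optional [relaxation()] spec; when given, the color (or y)
#'   probabilities come from the relaxed CEAC instead of the strict one,
#'   which broadens the used color range when the strict CEAC has collapsed.
#' @return A `psa_heatmap` tibble with columns `strategy`, `wtp`, `y_value`,
#'   `color_value` and `on_frontier`; attributes `base`, `relaxation`
#'   (possibly NULL), `segments` (the [frontier_segments()] tibble),
#'   `y_kind` and `color_kind`.
#' @export
nmb_heatmap <- function(psa, wtp = wtp_grid(), base = c("elc", "ceac"),
                        relax = NULL) {
  psa <- as_psa(psa)
  wtp <- check_wtp(wtp)
  base <- match.arg(base)
  loss <- elc(psa, wtp)
  prob <- if (is.null(relax)) ceac(psa, wtp) else relaxed_ceac(psa, wtp, relax)
  stopifnot(identical(loss$strategy, prob$strategy),
            identical(loss$wtp, prob$wtp))
  if (base == "elc") {
    y <- loss$value; col <- prob$value
    y_kind <- "expected_loss"; color_kind <- "probability"
  } else {
    y <- prob$value; col <- loss$value
    y_kind <- "probability"; color_kind <- "expected_loss"
  }
  tbl <- tibble::tibble(
    strategy = loss$strategy,
    wtp = loss$wtp,
    y_value = y,
    color_value = col,
    on_frontier = loss$on_frontier
  )
  new_curve_tbl(tbl, "psa_heatmap",
                base = base, relaxation = relax,
                segments = frontier_segments(psa, wtp),
                y_kind = y_kind, color_kind = color_kind,
                currency = psa$currency)
}
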