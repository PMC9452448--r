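#' Construct a PSA result object
#'
#' A `psa` object holds the output of a probabilistic sensitivity analysis:
#' for each of S strategies and N iterations, one cost (currency units) and
#' one effect (QALYs or life-years). It is the single input every
#' uncertainty-representation method in this package derives from.
#'
#' @param data A data frame in long layout with columns `iteration`,
#'   `strategy`, `cost` and `effect`; every strategy x iteration pair must be
#'   present exactly once.
#' @param effect_unit Unit of the effect column, `"QALY"` or `"LY"`.
#' @param currency Free-text currency label used in output and plots.
#'
#' @return A `psa` object: a list with elements `costs` and `effects`
#'   (numeric N x S matrices, iterations in rows, strategies in columns,
#'   column names = strategy labels), `strategies` (character), `effect_unit`
#'   and `currency`.
#'
#' @examples
#' df <- data.frame(
#'   iteration = rep(1:3, 2),
#'   strategy  = rep(c("A", "B"), each = 3),
#'   cost      = c(20000, 21000, 19000, 25000, 24000, 26000),
#'   effect    = c(1.0, 1.1, 0.9, 1.2, 1.3, 1.1)
#' )
#' p <- psa(df)
#' glance(p)
#' @export
psa <- function(data, effect_unit = c("QALY", "LY"), currency = "€") {
  effect_unit <- match.arg(effect_unit)
  data <- as.data.frame(data)
  required <- c("iteration", "strategy", "cost", "effect")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("long PSA data must have columns iteration, strategy, cost, effect; ",
         "missing: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  strategies <- unique(as.character(data$strategy))
  iterations <- sort(unique(data$iteration))
  n <- length(iterations)
  s <- length(strategies)
  if (nrow(data) != n * s) {
    stop("long PSA data must be complete: expected ", n * s,
         " rows (", s, " strategies x ", n, " iterations), got ", nrow(data),
         call. = FALSE)
  }
  key <- paste(data$strategy, data$iteration)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (strategy, iteration) pair in long PSA data: ", dup,
         call. = FALSE)
  }
  row_idx <- match(data$iteration, iterations)
  col_idx <- match(as.character(data$strategy), strategies)
  costs <- matrix(NA_real_, n, s, dimnames = list(NULL, strategies))
  effects <- costs
  costs[cbind(row_idx, col_idx)] <- data$cost
  effects[cbind(row_idx, col_idx)] <- data$effect
  new_psa(costs, effects, strategies, effect_unit, currency)
}

#' Construct a PSA result from cost and effect matrices
#'
#' @param costs,effects Numeric N x S matrices (iterations in rows, one
#'   column per strategy) of costs and effects.
#' @param strategies Character vector of S unique strategy labels; defaults
#'   to the column names of `costs`, or `"S1"`, `"S2"`, ... if unnamed.
#' @inheritParams psa
#' @return A `psa` object; see [psa()].
#' @export
psa_from_matrices <- function(costs, effects, strategies = NULL,
                              effect_unit = c("QALY", "LY"),
                              currency = "€") {
  effect_unit <- match.arg(effect_unit)
  costs <- as.matrix(costs)
  effects <- as.matrix(effects)
  if (is.null(strategies)) {
    strategies <- colnames(costs)
    if (is.null(strategies)) strategies <- paste0("S", seq_len(ncol(costs)))
  }
  new_psa(costs, effects, as.character(strategies), effect_unit, currency)
}

new_psa <- function(costs, effects, strategies, effect_unit, currency) {
  storage.mode(costs) <- "double"
  storage.mode(effects) <- "double"
  if (!identical(dim(costs), dim(effects))) {
    stop("costs and effects must have identical dimensions", call. = FALSE)
  }
  s <- ncol(costs)
  n <- nrow(costs)
  if (s < 1) stop("at least one strategy is required", call. = FALSE)
  if (n < 2) stop("at least two PSA iterations are required", call. = FALSE)
  if (length(strategies) != s) {
    stop("number of strategy labels (", length(strategies),
         ") does not match number of strategy columns (", s, ")",
         call. = FALSE)
  }
  if (anyDuplicated(strategies)) {
    stop("strategy labels must be unique; duplicated: ",
         paste(unique(strategies[duplicated(strategies)]), collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("costs", "effects")) {
    m <- if (nm == "costs") costs else effects
    if (anyNA(m) || any(!is.finite(m))) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      stop("non-finite ", nm, " at iteration ", bad[1], ", strategy '",
           strategies[bad[2]], "'", call. = FALSE)
    }
  }
  colnames(costs) <- strategies
  colnames(effects) <- strategies
  structure(
    list(costs = costs, effects = effects, strategies = strategies,
         effect_unit = effect_unit, currency = currency),
    class = "psa"
  )
}

#' Coerce to a PSA result
#'
#' Data frames are interpreted as long-layout PSA tables (columns
#' `iteration`, `strategy`, `cost`, `effect`); `psa` objects pass through.
#'
#' @param x Object to coerce.
#' @param ... Passed on to [psa()].
#' @return A `psa` object.
#' @export
as_psa <- function(x, ...) UseMethod("as_psa")

#' @export
as_psa.psa <- function(x, ...) x

#' @export
as_psa.data.frame <- function(x, ...) psa(x, ...)

#' @export
as_psa.default <- function(x, ...) {
  stop("cannot coerce an object of class '", class(x)[1], "' to a psa result",
       call. = FALSE)
}

n_strategies <- function(psa) ncol(psa$costs)
n_iterations <- function(psa) nrow(psa$costs)

#' @export
print.psa <- function(x, ...) {
  cat("<psa> ", n_strategies(x), " strategies x ", n_iterations(x),
      " iterations (", x$effect_unit, ", ", x$currency, ")\n", sep = "")
  cat("strategies:", paste(utils::head(x$strategies, 8), collapse = ", "),
      if (n_strategies(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PSA result into a long tibble
#'
#' @param x A `psa` object.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `strategy`, `cost`, `effect`,
#'   one row per strategy x iteration.
#' @export
tidy.psa <- function(x, ...) {
  s <- n_strategies(x)
  n <- n_iterations(x)
  tibble::tibble(
    iteration = rep(seq_len(n), s),
    strategy = factor(rep(x$strategies, each = n), levels = x$strategies),
    cost = as.vector(x$costs),
    effect = as.vector(x$effects)
  )
}

#' One-row summary of a PSA result
#'
#' @param x A `psa` object.
#' @param ... Unused.
#' @return A one-row tibble: strategy and iteration counts, units, and the
#'   across-strategy ranges of mean cost and mean effect.
#' @export
glance.psa <- function(x, ...) {
  mc <- colMeans(x$costs)
  me <- colMeans(x$effects)
  tibble::tibble(
    n_strategies = n_strategies(x),
    n_iterations = n_iterations(x),
    effect_unit = x$effect_unit,
    currency = x$currency,
    min_mean_cost = min(mc), max_mean_cost = max(mc),
    min_mean_effect = min(me), max_mean_effect = max(me)
  )
}

#' Default willingness-to-pay grid
#'
#' Thresholds from 0 to 100,000 currency units per effect unit in steps of
#' 500, the grid used by the WTP-axis methods when none is given.
#'
#' @param min,max,step Grid limits and spacing, currency per effect unit.
#' @return A strictly increasing numeric vector of WTP values.
#' @export
wtp_grid <- function(min = 0, max = 1e5, step = 500) {
  check_wtp(seq(min, max, by = step))
}

check_wtp <- function(wtp) {
  if (!is.numeric(wtp) || length(wtp) < 1) {
    stop("wtp must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (anyNA(wtp) || any(!is.finite(wtp))) {
    stop("wtp values must be finite", call. = FALSE)
  }
  if (any(wtp < 0)) stop("wtp values must be >= 0", call. = FALSE)
  if (length(wtp) > 1 && any(diff(wtp) <= 0)) {
    stop("wtp grid must be strictly increasing", call. = FALSE)
  }
  as.numeric(wtp)
}

strategy_factor <- function(psa, idx) {
  factor(psa$strategies[idx], levels = psa$strategies)
}

# Row-wise maximum of a numeric matrix without apply() overhead.
row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

new_curve_tbl <- function(data, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(data, nm) <- attrs[[nm]]
  class(data) <- c(class, "psa_curves", class(data))
  data
}
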