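#' Read a PSA table from CSV
#'
#' Two dialects are supported. `wide`: one row per iteration with paired
#' columns `cost_<label>` and `effect_<label>` per strategy (plus an optional
#' `iteration` column). `long`: columns `iteration`, `strategy`, `cost`,
#' `effect`, with every strategy x iteration pair present exactly once.
#' `auto` picks the dialect from the header. Strategy labels come from the
#' header (wide) or the `strategy` column (long). Files written by
#' [write_psa()] round-trip exactly: values are written with the shortest
#' decimal representation that parses back to the identical double.
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param layout `"auto"`, `"wide"` or `"long"`.
#' @inheritParams psa
#' @return A `psa` object.
#' @export
read_psa <- function(path, layout = c("auto", "wide", "long"),
                     effect_unit = c("QALY", "LY"), currency = "€") {
  layout <- match.arg(layout)
  effect_unit <- match.arg(effect_unit)
  # read everything as text and convert with strtod (as.numeric), which is
  # correctly rounded — the fast vectorized double parser can be 1 ulp off,
  # which would break the exact round-trip contract
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          .default = readr::col_character()))
  nms <- names(df)
  if (layout == "auto") {
    layout <- if (all(c("strategy", "cost", "effect") %in% nms)) "long"
              else "wide"
  }
  if (layout == "long") {
    needed <- c("iteration", "strategy", "cost", "effect")
    if (!all(needed %in% nms)) {
      stop("long PSA file ", path, " must have columns ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    df$iteration <- parse_numeric_column(df, "iteration", path)
    df$cost <- parse_numeric_column(df, "cost", path)
    df$effect <- parse_numeric_column(df, "effect", path)
    return(psa(df, effect_unit = effect_unit, currency = currency))
  }
  cost_cols <- grep("^cost_", nms, value = TRUE)
  effect_cols <- grep("^effect_", nms, value = TRUE)
  labels <- sub("^cost_", "", cost_cols)
  if (length(cost_cols) == 0) {
    stop("wide PSA file ", path, " has no cost_<strategy> columns",
         call. = FALSE)
  }
  if (!setequal(sub("^effect_", "", effect_cols), labels) ||
      length(effect_cols) != length(cost_cols)) {
    stop("wide PSA file ", path, ": cost_* and effect_* columns do not pair ",
         "up strategy-for-strategy", call. = FALSE)
  }
  for (cc in c(cost_cols, paste0("effect_", labels))) {
    df[[cc]] <- parse_numeric_column(df, cc, path)
  }
  costs <- as.matrix(df[cost_cols])
  effects <- as.matrix(df[paste0("effect_", labels)])
  psa_from_matrices(costs, effects, labels, effect_unit = effect_unit,
                    currency = currency)
}

parse_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  num <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(num))
  if (length(bad) > 0) {
    what <- if (is.na(v[bad[1]]) || v[bad[1]] == "") "missing" else
      "non-numeric"
    stop(what, " value in column '", col, "' of ", path,
         " (data row ", bad[1], ")", call. = FALSE)
  }
  num
}

#' Write a PSA table to CSV
#'
#' @param psa A [psa()] result.
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`; see [read_psa()].
#' @return `path`, invisibly.
#' @export
write_psa <- function(psa, path, layout = c("wide", "long")) {
  psa <- as_psa(psa)
  layout <- match.arg(layout)
  if (layout == "long") {
    df <- tidy(psa)
  } else {
    costs <- as.data.frame(psa$costs)
    names(costs) <- paste0("cost_", psa$strategies)
    effects <- as.data.frame(psa$effects)
    names(effects) <- paste0("effect_", psa$strategies)
    df <- cbind(iteration = seq_len(n_iterations(psa)), costs, effects)
  }
  # 17 significant digits: every double parses back to the identical value
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Export a curve tibble as tidy CSV
#'
#' Writes any of the package's curve results in its tidy layout, with the
#' method name and carried settings (WTP, value kind, bins, smoothing,
#' relaxation) as columns so the file is self-describing.
#'
#' @param x A curve tibble produced by the method functions (`ceac()`,
#'   `elc()`, `evpi()`, density/dominance/rankogram results, heat map data,
#'   ...), or any data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_curves <- function(x, path) {
  df <- as.data.frame(x)
  meta <- list(
    method = setdiff(class(x), c("psa_curves", "tbl_df", "tbl",
                                 "data.frame"))[1],
    value_kind = attr(x, "value_kind"),
    wtp = attr(x, "wtp"),
    measure = attr(x, "measure"),
    base = attr(x, "base")
  )
  relax <- attr(x, "relaxation")
  if (!is.null(relax)) {
    meta$relax_scheme <- relax$scheme
    meta$relax_parameter <- relax$parameter
  }
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]]) && !nm %in% names(df)) df[[nm]] <- meta[[nm]]
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
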