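#' Specification for a synthetic PSA
#'
#' Describes a synthetic probabilistic sensitivity analysis whose statistical
#' structure mimics real multi-strategy PSA output: per-strategy mean costs
#' and effects, Gaussian noise on the cost and effect scales, and a
#' between-strategy correlation control. Real PSAs evaluate all strategies on
#' the *same* parameter draw per iteration, which correlates their outputs
#' strongly; here each iteration draws one shared cost/effect noise pair and
#' mixes it with strategy-specific noise:
#'
#' `noise = (rho * z_shared + (1 - rho) * z_own) / sqrt(rho^2 + (1 - rho)^2)`
#'
#' The standardization keeps the marginal sd exactly at the specified sd for
#' every `rho`, while the implied between-strategy correlation of costs (and
#' of effects) is `rho^2 / (rho^2 + (1 - rho)^2)`: 0 at `rho = 0`, 1 at
#' `rho = 1`. At `rho = 1` the noise cancels in every between-strategy
#' difference, the degenerate limit in which the strict CEAC collapses onto
#' the frontier strategy.
#'
#' @param n_strategies S >= 1.
#' @param n_iterations N >= 2.
#' @param mean_costs,mean_effects Length-S vectors of per-strategy means.
#' @param cost_sd,effect_sd Scalars or length-S vectors of marginal standard
#'   deviations (>= 0).
#' @param rho Shared-noise weight in `[0, 1]`.
#' @param seed Integer seed; identical specs generate byte-identical output.
#' @param cost_dist `"normal"` or `"lognormal"`. The log-normal option keeps
#'   costs strictly positive (real costs are), moment-matched so mean and sd
#'   equal the specified values; it requires positive mean costs.
#' @inheritParams psa
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(n_strategies, n_iterations, mean_costs, mean_effects,
                       cost_sd, effect_sd, rho = 0, seed = 1L,
                       cost_dist = c("normal", "lognormal"),
                       effect_unit = c("QALY", "LY"), currency = "€") {
  cost_dist <- match.arg(cost_dist)
  effect_unit <- match.arg(effect_unit)
  s <- as.integer(n_strategies)
  n <- as.integer(n_iterations)
  if (s < 1) stop("n_strategies must be >= 1", call. = FALSE)
  if (n < 2) stop("n_iterations must be >= 2", call. = FALSE)
  mean_costs <- rep_len(as.numeric(mean_costs), s)
  mean_effects <- rep_len(as.numeric(mean_effects), s)
  if (length(mean_costs) != s || length(mean_effects) != s) {
    stop("mean vectors must have length n_strategies", call. = FALSE)
  }
  cost_sd <- rep_len(as.numeric(cost_sd), s)
  effect_sd <- rep_len(as.numeric(effect_sd), s)
  if (any(cost_sd < 0) || any(effect_sd < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    stop("rho must lie in [0, 1]", call. = FALSE)
  }
  if (cost_dist == "lognormal" && any(mean_costs <= 0)) {
    stop("lognormal costs require strictly positive mean costs",
         call. = FALSE)
  }
  structure(
    list(n_strategies = s, n_iterations = n, mean_costs = mean_costs,
         mean_effects = mean_effects, cost_sd = cost_sd,
         effect_sd = effect_sd, rho = rho, seed = as.integer(seed),
         cost_dist = cost_dist, effect_unit = effect_unit,
         currency = currency),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> ", x$n_strategies, " strategies x ", x$n_iterations,
      " iterations, rho = ", x$rho, ", costs ", x$cost_dist,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic PSA
#'
#' Draws a [psa()] result from a [synth_spec()]; see that page for the noise
#' model. The generator uses its own RNG state (the spec's `seed`) and leaves
#' the caller's RNG untouched.
#'
#' @param spec A [synth_spec()].
#' @return A `psa` object with strategy labels `"S1"`, `"S2"`, ...
#' @examples
#' spec <- synth_spec(3, 100, mean_costs = c(0, 10000, 30000),
#'                    mean_effects = c(1, 1.3, 1.5),
#'                    cost_sd = 2000, effect_sd = 0.2, rho = 0.8, seed = 42)
#' p <- generate_psa(spec)
#' @export
generate_psa <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- spec$n_strategies
  n <- spec$n_iterations
  rho <- spec$rho
  norm <- sqrt(rho^2 + (1 - rho)^2)
  withr::with_seed(spec$seed, {
    z_cost <- stats::rnorm(n)
    z_eff <- stats::rnorm(n)
    u_cost <- matrix(stats::rnorm(n * s), n, s)
    u_eff <- matrix(stats::rnorm(n * s), n, s)
  })
  mix <- function(z, u) (rho * z + (1 - rho) * u) / norm
  noise_cost <- mix(z_cost, u_cost)
  noise_eff <- mix(z_eff, u_eff)
  effects <- sweep(sweep(noise_eff, 2, spec$effect_sd, `*`), 2,
                   spec$mean_effects, `+`)
  if (spec$cost_dist == "normal") {
    costs <- sweep(sweep(noise_cost, 2, spec$cost_sd, `*`), 2,
                   spec$mean_costs, `+`)
  } else {
    # moment-matched log-normal: mean and sd equal the specified values
    cv2 <- (spec$cost_sd / spec$mean_costs)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(spec$mean_costs) - sdlog^2 / 2
    costs <- exp(sweep(sweep(noise_cost, 2, sdlog, `*`), 2, meanlog, `+`))
  }
  psa_from_matrices(costs, effects, paste0("S", seq_len(s)),
                    effect_unit = spec$effect_unit, currency = spec$currency)
}

#' Preset synthetic scenarios
#'
#' Named [synth_spec()]s emulating the qualitative regimes seen when the
#' uncertainty methods are applied to decision models with growing numbers
#' of strategies: a handful of clearly distinct strategies (`few3`, `few5`),
#' a mid-sized screening-style comparison (`mid`, 37 strategies), and a large
#' surveillance-style comparison (`many`, 108 strategies) whose strategies
#' have tightly clustered means and highly correlated outputs — the regime
#' in which the strict CEAC collapses while expected loss curves stay
#' readable.
#'
#' All presets place strategies on a convex cost-effect gradient (so many
#' strategies appear on the frontier as WTP grows), use log-normal costs, a
#' shared-noise weight `rho = 0.95`, and a reference WTP of 50,000 per
#' effect unit.
#'
#' @param n_iterations Iterations per preset; default 10,000.
#' @param seed Base seed; each preset offsets it so presets differ.
#' @return A named list of `synth_spec` objects with an attribute
#'   `reference_wtp = 50000`.
#' @export
preset_scenarios <- function(n_iterations = 10000, seed = 1L) {
  seed <- as.integer(seed)
  gradient_spec <- function(s, n, seed, effect_step, cost_lin, cost_quad,
                            effect_sd, cost_sd, rho = 0.95) {
    i <- seq_len(s) - 1
    synth_spec(
      n_strategies = s, n_iterations = n,
      mean_costs = 10000 + cost_lin * i + cost_quad * i^2,
      mean_effects = 1.5 + effect_step * i,
      cost_sd = cost_sd, effect_sd = effect_sd, rho = rho, seed = seed,
      cost_dist = "lognormal"
    )
  }
  presets <- list(
    # few strategies, well separated: strict CEAC stays readable
    few3 = gradient_spec(3, n_iterations, seed, effect_step = 0.15,
                         cost_lin = 5000, cost_quad = 1500,
                         effect_sd = 0.25, cost_sd = 2500),
    few5 = gradient_spec(5, n_iterations, seed + 1L, effect_step = 0.10,
                         cost_lin = 3500, cost_quad = 600,
                         effect_sd = 0.25, cost_sd = 2500),
    # 37 strategies, closer together
    mid = gradient_spec(37, n_iterations, seed + 2L, effect_step = 0.012,
                        cost_lin = 450, cost_quad = 6,
                        effect_sd = 0.25, cost_sd = 2500),
    # 108 near-equivalent strategies: the CEAC-collapse regime
    many = gradient_spec(108, n_iterations, seed + 3L, effect_step = 0.004,
                         cost_lin = 150, cost_quad = 0.7,
                         effect_sd = 0.25, cost_sd = 2500)
  )
  attr(presets, "reference_wtp") <- 50000
  presets
}

#' Small deterministic example PSA
#'
#' Three strategies, 200 iterations, moderate correlation; used in examples
#' and as a quick way to try the methods.
#'
#' @param seed Seed passed to the generator.
#' @return A `psa` object.
#' @export
example_psa <- function(seed = 7L) {
  generate_psa(synth_spec(
    n_strategies = 3, n_iterations = 200,
    mean_costs = c(12000, 20000, 34000),
    mean_effects = c(1.2, 1.45, 1.6),
    cost_sd = 2500, effect_sd = 0.2, rho = 0.8, seed = seed,
    cost_dist = "lognormal"
  ))
}
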