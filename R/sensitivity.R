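#' Triangular random deviates
#'
#' Inverse-CDF sampler for the triangular distribution with support
#' `[low, high]` and mode `mode`; the standard parameterisation for
#' sensitivity-analysis inputs known only by a plausible range.
#'
#' @param n number of draws.
#' @param low,mode,high distribution parameters, `low <= mode <= high`.
#' @return numeric vector of length `n`.
#' @export
rtriangular <- function(n, low, mode, high) {
  if (!(low <= mode && mode <= high)) {
    stop("rtriangular: need low <= mode <= high")
  }
  if (low == high) return(rep(low, n))
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

# Gamma draws by method of moments: mean = base, sd = (high - low) / (2 * 1.96)
rgamma_moments <- function(n, base, low, high) {
  if (base <= 0) return(rep(base, n))
  sdv <- (high - low) / (2 * 1.96)
  if (sdv <= 0) return(rep(base, n))
  shape <- (base / sdv)^2
  stats::rgamma(n, shape = shape, scale = sdv^2 / base)
}

# Scale the positive-time entries of a cumulative fraction series, clamped
# to [0, 1]; t = 0 anchors (0 for rescue, 1 for survival) are never scaled.
scale_fractions <- function(x, factor) {
  c(x[1], pmax(0, pmin(1, x[-1] * factor)))
}

# Apply scalar perturbations to a parameter set without re-validating the
# cross-schedule dominance invariant (the caller decides clamp vs reject).
perturb_params <- function(params, rescued_survival = 1, trapped_survival = 1,
                           discount_rate = 1, av_costs = 1,
                           productivity_loss = 1, clamp_dominance = TRUE) {
  p <- params
  for (lab in names(p$schedules)) {
    s <- p$schedules[[lab]]$survival
    s$rescued_survival <- scale_fractions(s$rescued_survival, rescued_survival)
    s$trapped_survival <- scale_fractions(s$trapped_survival, trapped_survival)
    if (clamp_dominance) {
      s$trapped_survival <- pmin(s$trapped_survival, s$rescued_survival)
    }
    p$schedules[[lab]]$survival <- s
  }
  p$utilities$discount_rate <- p$utilities$discount_rate * discount_rate
  for (nm in c("av_cost_per_person", "overhead_per_person", "gas_per_mile",
               "maintenance_per_mile")) {
    p$costs[[nm]] <- p$costs[[nm]] * av_costs
  }
  p$costs$value_of_lost_life <- p$costs$value_of_lost_life * productivity_loss
  p
}

#' One-way (tornado) sensitivity analysis of the ICER
#'
#' Scales each named input by `1 - pct` and `1 + pct` in turn, holding all
#' other inputs at base, re-runs both arms and recomputes the ICER. Survival
#' and rescue schedules are perturbed as a single scalar multiplying the
#' fractions at all positive time points, clamped to `[0, 1]`; `"av_costs"`
#' scales the AV-programme cost block (aggregate AV cost per person,
#' overhead, and the variable per-mile rates - the regulation fee is a
#' separately sourced input and is not part of this block);
#' `"productivity_loss"` scales the value of lost life; `"discount_rate"`
#' scales the annual discount rate.
#'
#' @param params a [model_params()].
#' @param variables subset of `c("rescued_survival", "trapped_survival",
#'   "discount_rate", "av_costs", "productivity_loss")`.
#' @param pct perturbation fraction (default 0.25).
#' @param intervention,reference arm labels.
#' @param config optional [model_config()] override.
#' @return data frame of class `tornado_result` with columns `variable`,
#'   `icer_low` (input at `-pct`), `icer_high` (input at `+pct`),
#'   `dominance_low`, `dominance_high`; base-case ICER in attribute
#'   `base_icer`.
#' @export
tornado <- function(params,
                    variables = c("rescued_survival", "trapped_survival",
                                  "discount_rate", "av_costs",
                                  "productivity_loss"),
                    pct = 0.25, intervention = "improvement_5",
                    reference = "status_quo", config = NULL) {
  config <- config %||% params$config
  valid <- c("rescued_survival", "trapped_survival", "discount_rate",
             "av_costs", "productivity_loss")
  bad <- setdiff(variables, valid)
  if (length(bad)) {
    stop("tornado: unknown variable(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "))
  }
  base_ce <- compare_arms(params, intervention, reference, config)$ce
  one <- function(var, factor) {
    args <- list(params)
    args[[var]] <- factor
    pp <- do.call(perturb_params, args)
    compare_arms(pp, intervention, reference, config)$ce
  }
  rows <- lapply(variables, function(v) {
    lo <- one(v, 1 - pct)
    hi <- one(v, 1 + pct)
    data.frame(variable = v, icer_low = lo$icer, icer_high = hi$icer,
               dominance_low = lo$dominance, dominance_high = hi$dominance)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "base_icer") <- base_ce$icer
  attr(out, "pct") <- pct
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Configuration of the probabilistic sensitivity analysis
#'
#' The default distribution map follows standard health-economics
#' convention: Gamma distributions (method of moments, mean at base, standard
#' deviation `(high - low) / (2 * 1.96)`) for the monetary inputs, and
#' triangular distributions over the plausible range `(1 - range, 1,
#' 1 + range)` for the bounded scale factors (rescue performance, survival,
#' utility, discount rate). Rescue-performance factors are sampled
#' *independently for each arm*: the operational performance of human-driven
#' and autonomous fleets in a disaster are separately uncertain quantities,
#' and a shared factor would assert that the efficiency differential between
#' the arms is known exactly, which the width of the reported uncertainty
#' plainly contradicts. Survival factors (victim physiology) and economic
#' inputs are common to both arms.
#'
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed; every run with the same seed and configuration
#'   reproduces the draw sequence exactly.
#' @param wtp_grid willingness-to-pay thresholds (USD/QALY) for the
#'   acceptability computation.
#' @param scale_range half-width of the triangular scale-factor
#'   distributions (default 0.25, the model's plausible range).
#' @return object of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = 1,
                       wtp_grid = c(0, 25000, 50000, 75000, 100000,
                                    150000, 200000),
                       scale_range = 0.25) {
  stopifnot(n_draws > 0, scale_range >= 0, scale_range < 1)
  structure(
    list(n_draws = as.integer(n_draws), seed = as.integer(seed),
         wtp_grid = wtp_grid, scale_range = scale_range),
    class = "psa_config"
  )
}

# Sample one block of n draws for every PSA variable, in fixed order.
psa_sample_block <- function(n, params, sr) {
  cb <- params$costs
  g <- function(nm) rgamma_moments(n, cb[[nm]][["base"]], cb[[nm]][["low"]],
                                   cb[[nm]][["high"]])
  tri <- function() rtriangular(n, 1 - sr, 1, 1 + sr)
  # fixed sorted variable order; one shared RNG stream
  data.frame(
    av_cost_per_person = g("av_cost_per_person"),
    discount_scale = tri(),
    gas_per_mile = g("gas_per_mile"),
    maintenance_per_mile = g("maintenance_per_mile"),
    medical_cost_per_person = g("medical_cost_per_person"),
    overhead_per_person = g("overhead_per_person"),
    regulation_fee_per_person = g("regulation_fee_per_person"),
    rescue_scale_intervention = tri(),
    rescue_scale_reference = tri(),
    rescued_survival_scale = tri(),
    trapped_survival_scale = tri(),
    utility_scale = tri(),
    value_of_lost_life = g("value_of_lost_life")
  )
}

psa_draw_valid <- function(d, params) {
  u <- params$utilities$utility_survivor * d$utility_scale
  if (u > 1 || u < 0) return(FALSE)
  for (lab in names(params$schedules)) {
    s <- params$schedules[[lab]]$survival
    sr <- scale_fractions(s$rescued_survival, d$rescued_survival_scale)
    st <- scale_fractions(s$trapped_survival, d$trapped_survival_scale)
    if (any(st > sr + 1e-12)) return(FALSE)
    if (any(sr <= 0) || any(st <= 0)) return(FALSE)
  }
  TRUE
}

psa_evaluate_draw <- function(d, params, intervention, reference, config) {
  p <- params
  for (nm in c("av_cost_per_person", "gas_per_mile", "maintenance_per_mile",
               "medical_cost_per_person", "overhead_per_person",
               "regulation_fee_per_person", "value_of_lost_life")) {
    p$costs[[nm]][["base"]] <- d[[nm]]
  }
  p$utilities$discount_rate <- p$utilities$discount_rate * d$discount_scale
  p$utilities$utility_survivor <-
    min(1, p$utilities$utility_survivor * d$utility_scale)
  for (lab in names(p$schedules)) {
    s <- p$schedules[[lab]]$survival
    s$rescued_survival <- scale_fractions(s$rescued_survival,
                                          d$rescued_survival_scale)
    s$trapped_survival <- scale_fractions(s$trapped_survival,
                                          d$trapped_survival_scale)
    p$schedules[[lab]]$survival <- s
    r <- p$schedules[[lab]]$rescue
    f <- if (lab == reference) d$rescue_scale_reference else
      d$rescue_scale_intervention
    r$cumulative_rescued <- cummax(scale_fractions(r$cumulative_rescued, f))
    p$schedules[[lab]]$rescue <- r
  }
  ce <- compare_arms(p, intervention, reference, config)$ce
  c(ce$incremental_cost, ce$incremental_qaly)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws every mapped input from its distribution (see [psa_config()]),
#' rebuilds both arms per draw and records the incremental cost and
#' incremental QALYs. Draws producing an invalid parameter set (utility
#' above 1, or a perturbed trapped-survival curve exceeding the rescued
#' one) are rejected and resampled; the rejection count is reported.
#' Results are reproducible bit-for-bit for a fixed seed.
#'
#' @param params a [model_params()].
#' @param psa a [psa_config()].
#' @param intervention,reference arm labels.
#' @param config optional [model_config()] override.
#' @return object of class `psa_result`: `draws` (data frame `delta_cost`,
#'   `delta_qaly`), `ceac` (data frame `wtp`, `prob_cost_effective`),
#'   `ci_delta_cost`, `ci_delta_qaly` (95% percentile intervals),
#'   `icer_interval` (labelled, ordered by net monetary benefit),
#'   `n_draws`, `seed`, `rejections`, `base` (the base-case `ce_result`).
#' @export
run_psa <- function(params, psa = psa_config(),
                    intervention = "improvement_5",
                    reference = "status_quo", config = NULL) {
  config <- config %||% params$config
  set.seed(psa$seed)
  n <- psa$n_draws
  draws <- psa_sample_block(n, params, psa$scale_range)
  rejections <- 0L
  ok <- vapply(seq_len(n), function(i)
    psa_draw_valid(draws[i, ], params), logical(1))
  while (any(!ok)) {
    idx <- which(!ok)
    rejections <- rejections + length(idx)
    repl <- psa_sample_block(length(idx), params, psa$scale_range)
    draws[idx, ] <- repl
    ok[idx] <- vapply(seq_along(idx), function(j)
      psa_draw_valid(repl[j, ], params), logical(1))
  }
  out <- matrix(NA_real_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    out[i, ] <- psa_evaluate_draw(draws[i, ], params, intervention,
                                  reference, config)
  }
  dd <- data.frame(delta_cost = out[, 1], delta_qaly = out[, 2])
  ceac <- data.frame(
    wtp = psa$wtp_grid,
    prob_cost_effective = vapply(psa$wtp_grid, function(l)
      mean(l * dd$delta_qaly - dd$delta_cost > 0), numeric(1))
  )
  structure(
    list(
      draws = dd, ceac = ceac,
      ci_delta_cost = credible_interval(dd$delta_cost, 0.95),
      ci_delta_qaly = credible_interval(dd$delta_qaly, 0.95),
      icer_interval = icer_interval(dd, wtp = 100000),
      n_draws = n, seed = psa$seed, rejections = rejections,
      base = compare_arms(params, intervention, reference, config)$ce
    ),
    class = "psa_result"
  )
}

#' Percentile credible interval of empirical draws
#'
#' The `((1 - level)/2, 1 - (1 - level)/2)` percentile interval using the
#' mid-point empirical quantile definition (R quantile type 5), under which
#' the order statistic at position `n p + 1/2` is interpolated; for draws
#' `1..100` at level 0.9 this gives `(5.5, 95.5)`.
#'
#' @param draws numeric vector.
#' @param level coverage in `(0, 1)`.
#' @return numeric vector `c(low, high)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (!length(draws)) stop("credible_interval: empty draws")
  if (level <= 0 || level >= 1) stop("credible_interval: level in (0,1)")
  a <- (1 - level) / 2
  unname(stats::quantile(draws, probs = c(a, 1 - a), type = 5))
}

# Interval of the ICER across draws, ordered by net monetary benefit at the
# reporting threshold; bounds that are cost-saving (dE > 0, dC <= 0) are
# labelled rather than reported as sign-ambiguous negative ratios.
icer_interval <- function(draws, wtp = 100000, level = 0.95) {
  nmb <- wtp * draws$delta_qaly - draws$delta_cost
  ord <- order(nmb, decreasing = TRUE) # best value-for-money first
  n <- length(ord)
  pick <- function(p) {
    h <- max(1, min(n, round(n * p + 0.5)))
    i <- ord[h]
    dc <- draws$delta_cost[i]; de <- draws$delta_qaly[i]
    if (de > 0 && dc <= 0) "cost-saving"
    else if (de > 0) sprintf("%.0f", dc / de)
    else if (dc >= 0) "dominated"
    else sprintf("%.0f (less effective, cheaper)", dc / de)
  }
  c(low = pick((1 - level) / 2), high = pick(1 - (1 - level) / 2))
}

#' Export the cost-effectiveness plane
#'
#' Writes the PSA scatter as CSV (`delta_qaly, delta_cost`, one row per
#' draw) and optionally a plot with the willingness-to-pay threshold line.
#'
#' @param result a `psa_result`.
#' @param path CSV output path.
#' @param plot_path optional PNG/SVG path.
#' @param wtp threshold drawn on the plot (USD/QALY).
#' @return `path`, invisibly.
#' @export
ce_plane_export <- function(result, path, plot_path = NULL, wtp = 100000) {
  df <- result$draws[, c("delta_qaly", "delta_cost")]
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(plot_path)) {
    g <- plot_ce_plane(result, wtp = wtp)
    ggplot2::ggsave(plot_path, g, width = 6, height = 5, dpi = 150)
  }
  invisible(path)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws (seed", x$seed, ",",
      x$rejections, "rejections)\n")
  cat("  dC 95% CI: [", paste(round(x$ci_delta_cost), collapse = ", "),
      "]  dE 95% CI: [", paste(round(x$ci_delta_qaly, 3), collapse = ", "),
      "]\n")
  cat("  ICER interval (by NMB at $100k):",
      paste(x$icer_interval, collapse = " to "), "\n")
  i100 <- x$ceac$prob_cost_effective[x$ceac$wtp == 1e5]
  if (length(i100)) cat("  CEAC @ $100,000/QALY:", round(i100, 3), "\n")
  invisible(x)
}
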