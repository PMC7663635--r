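#' Scenario specification for schedule generation
#'
#' @param total_rescue_duration_h time for the rescue operation to complete
#'   under the status quo (hours; default 120).
#' @param improvement rescue-efficiency improvement fraction in `[0, 1)`;
#'   scales the total duration to `(1 - improvement) *
#'   total_rescue_duration_h`.
#' @param cycle_hours Markov cycle length (hours).
#' @param horizon_h model horizon (hours; a multiple of `cycle_hours`).
#' @param cohort_size initially trapped victims.
#' @param seed optional integer seed for random generation.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(total_rescue_duration_h = 120, improvement = 0,
                          cycle_hours = 6, horizon_h = 24,
                          cohort_size = 1000, seed = NULL) {
  if (improvement < 0 || improvement >= 1) {
    stop("scenario_spec: improvement must lie in [0, 1)")
  }
  if (horizon_h %% cycle_hours != 0) {
    stop("scenario_spec: horizon_h must be a multiple of cycle_hours")
  }
  structure(
    list(total_rescue_duration_h = total_rescue_duration_h,
         improvement = improvement, cycle_hours = cycle_hours,
         horizon_h = horizon_h, cohort_size = cohort_size, seed = seed),
    class = "scenario_spec"
  )
}

#' Rescue schedule for an arbitrary efficiency improvement
#'
#' Generates the improved arm's cumulative rescue curve from the status-quo
#' curve by time-axis compression: a fleet that completes the operation in
#' `(1 - improvement)` of the time reaches any cumulative rescue fraction
#' proportionally earlier, so
#' \deqn{R_{new}(t) = R_{base}\big(t / (1 - improvement)\big),}
#' evaluated by monotone linear interpolation between the base grid points,
#' capped at 1, and re-sampled on the cycle grid. `improvement = 0` returns
#' the base schedule exactly. The source rescue-rate model behind the base
#' curve is not re-derived; only its tabulated output is transformed.
#'
#' @param spec a [scenario_spec()].
#' @param base the status-quo [rescue_schedule()].
#' @return a [rescue_schedule()] on the `spec` cycle grid.
#' @export
scaled_rescue_schedule <- function(spec, base) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(base, "rescue_schedule"))
  tt <- seq(0, spec$horizon_h, by = spec$cycle_hours)
  stretched <- tt / (1 - spec$improvement)
  r <- stats::approx(base$time_points_h, base$cumulative_rescued,
                     xout = pmin(stretched, max(base$time_points_h)),
                     method = "linear", rule = 2)$y
  r <- pmin(cummax(r), 1)
  lab <- if (spec$improvement == 0) base$arm_label else
    sprintf("improvement_%g", round(100 * spec$improvement, 4))
  rescue_schedule(lab, spec$improvement, tt, r)
}

#' Random but valid parameter sets for property testing
#'
#' Draws every cost base uniformly within its published `[low, high]` range,
#' generates random monotone rescue and survival schedules (normalised
#' sorted-uniform increments; rescued survival dominating trapped survival
#' by construction) for a status-quo arm and one randomly improved arm, and
#' returns a fully validated [model_params()]. Reproducible by seed.
#'
#' @param seed integer seed.
#' @param n_cycles number of model cycles (default 4).
#' @return a validated [model_params()].
#' @export
random_params <- function(seed, n_cycles = 4) {
  set.seed(seed)
  fx <- paper_fixture()
  costs <- fx$costs
  for (nm in names(costs)) {
    x <- costs[[nm]]
    x[["base"]] <- stats::runif(1, x[["low"]], x[["high"]])
    costs[[nm]] <- x
  }
  costs <- do.call(cost_inputs, costs)

  cyc <- 6
  tt <- seq(0, n_cycles * cyc, by = cyc)
  # monotone cumulative rescue reaching 1 at the horizon
  inc <- stats::runif(n_cycles)
  R <- c(0, cumsum(inc) / sum(inc))
  # non-increasing survival, rescued dominating trapped
  sr <- cumprod(c(1, stats::runif(n_cycles, 0.70, 1)))
  st <- sr * cumprod(c(1, stats::runif(n_cycles, 0.50, 1)))
  surv <- survival_schedule(tt, sr, st)

  base_rs <- rescue_schedule("status_quo", 0, tt, R)
  impr <- stats::runif(1, 0.02, 0.20)
  spec <- scenario_spec(total_rescue_duration_h = 120, improvement = impr,
                        cycle_hours = cyc, horizon_h = n_cycles * cyc)
  faster <- scaled_rescue_schedule(spec, base_rs)
  faster$arm_label <- "intervention"

  model_params(
    costs = costs,
    utilities = utility_inputs(
      utility_survivor = stats::runif(1, 0.3, 1),
      discount_rate = stats::runif(1, 0, 0.08)
    ),
    schedules = list(
      status_quo = list(rescue = base_rs, survival = surv),
      intervention = list(rescue = faster, survival = surv)
    ),
    cycle_hours = cyc
  )
}
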