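#' Cost inputs with base / low / high triples
#'
#' Bundles the monetary inputs of the rescue cost-effectiveness model. Every
#' component is carried as a `(base, low, high)` triple so that one-way and
#' probabilistic sensitivity analyses can draw on the plausible range without
#' re-specifying it.
#'
#' Components (all 2017 USD):
#' * `gas_per_mile`, `maintenance_per_mile` - variable autonomous-vehicle
#'   (AV) operating costs per vehicle-mile.
#' * `overhead_per_person` - fixed programme overhead (wireless
#'   communication, information systems) per affected person.
#' * `av_cost_per_person` - the aggregate AV cost per person. This is an
#'   opaque published aggregate; it is *not* recomputed from the per-mile
#'   rates (see [av_cost_per_person()] for the per-trip variable component).
#' * `medical_cost_per_person` - medical cost for a rescued, injured person.
#' * `value_of_lost_life` - lump-sum productivity loss per death.
#' * `regulation_fee_per_person` - regulatory cost of an AV-control mandate,
#'   per affected person.
#'
#' @param ... named components, each a numeric vector
#'   `c(base = , low = , high = )` (order-insensitive if named; unnamed
#'   vectors are taken as base, low, high).
#' @return an object of class `cost_inputs`: a named list of triples.
#' @export
cost_inputs <- function(...) {
  comps <- list(...)
  required <- c(
    "gas_per_mile", "maintenance_per_mile", "overhead_per_person",
    "av_cost_per_person", "medical_cost_per_person", "value_of_lost_life",
    "regulation_fee_per_person"
  )
  missing <- setdiff(required, names(comps))
  if (length(missing)) {
    stop("cost_inputs: missing components: ", paste(missing, collapse = ", "))
  }
  comps <- comps[required]
  comps <- lapply(comps, function(x) {
    if (is.null(names(x))) names(x) <- c("base", "low", "high")[seq_along(x)]
    x <- x[c("base", "low", "high")]
    if (anyNA(x)) stop("cost_inputs: each component needs base, low and high")
    x
  })
  obj <- structure(comps, class = "cost_inputs")
  validate_cost_inputs(obj)
  obj
}

validate_cost_inputs <- function(costs) {
  for (nm in names(costs)) {
    x <- costs[[nm]]
    if (any(x < 0)) stop("cost_inputs: negative value in ", nm)
    if (!(x["low"] <= x["base"] && x["base"] <= x["high"])) {
      stop("cost_inputs: low <= base <= high violated for ", nm)
    }
  }
  invisible(costs)
}

#' Utility and discounting inputs
#'
#' @param utility_survivor health-utility weight of an earthquake survivor,
#'   in `[0, 1]` (dimensionless).
#' @param discount_rate annual discount rate (fraction per year).
#' @param median_age cohort median age, years.
#' @param life_expectancy general-population life expectancy, years.
#' @return object of class `utility_inputs`; `remaining_years` is derived as
#'   `life_expectancy - median_age`.
#' @export
utility_inputs <- function(utility_survivor = 0.68, discount_rate = 0.03,
                           median_age = 37.8, life_expectancy = 78.9) {
  if (utility_survivor < 0 || utility_survivor > 1) {
    stop("utility_inputs: utility_survivor must lie in [0, 1]")
  }
  if (discount_rate < 0) stop("utility_inputs: discount_rate must be >= 0")
  k <- life_expectancy - median_age
  if (k <= 0) stop("utility_inputs: life_expectancy must exceed median_age")
  structure(
    list(
      utility_survivor = utility_survivor, discount_rate = discount_rate,
      median_age = median_age, life_expectancy = life_expectancy,
      remaining_years = k
    ),
    class = "utility_inputs"
  )
}

#' Cumulative rescue schedule for one strategy arm
#'
#' @param arm_label text label of the arm.
#' @param improvement rescue-efficiency improvement fraction in `[0, 1)`
#'   (0 for the status quo).
#' @param time_points_h ordered hours, starting at 0, uniformly spaced.
#' @param cumulative_rescued cumulative fraction of the initially trapped
#'   cohort rescued by each time point; starts at 0, non-decreasing, <= 1.
#' @return object of class `rescue_schedule`.
#' @export
rescue_schedule <- function(arm_label, improvement, time_points_h,
                            cumulative_rescued) {
  obj <- structure(
    list(
      arm_label = arm_label, improvement = improvement,
      time_points_h = as.numeric(time_points_h),
      cumulative_rescued = as.numeric(cumulative_rescued)
    ),
    class = "rescue_schedule"
  )
  validate_rescue_schedule(obj)
  obj
}

validate_rescue_schedule <- function(s, cycle_hours = NULL) {
  t <- s$time_points_h; r <- s$cumulative_rescued
  if (length(t) != length(r)) stop("rescue_schedule: length mismatch")
  if (t[1] != 0 || r[1] != 0) stop("rescue_schedule: must start at (t=0, R=0)")
  if (any(diff(r) < 0)) stop("rescue_schedule: cumulative_rescued must be non-decreasing")
  if (any(r > 1 + 1e-12)) stop("rescue_schedule: cumulative_rescued must be <= 1")
  dt <- diff(t)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9) {
    stop("rescue_schedule: time points must be uniformly spaced and increasing")
  }
  if (!is.null(cycle_hours) && abs(dt[1] - cycle_hours) > 1e-9) {
    stop("rescue_schedule: time spacing must equal the configured cycle length")
  }
  if (s$improvement < 0 || s$improvement >= 1) {
    stop("rescue_schedule: improvement must lie in [0, 1)")
  }
  invisible(s)
}

#' Cumulative survival schedules for rescued and still-trapped victims
#'
#' Both series are cumulative survival fractions indexed by hours since the
#' earthquake; both start at 1 and are non-increasing, and rescued victims
#' must fare at least as well as trapped ones at every positive time point.
#'
#' @param time_points_h ordered hours, starting at 0.
#' @param rescued_survival cumulative survival of rescued victims, `(0, 1]`.
#' @param trapped_survival cumulative survival of trapped victims, `(0, 1]`.
#' @return object of class `survival_schedule`.
#' @export
survival_schedule <- function(time_points_h, rescued_survival,
                              trapped_survival) {
  obj <- structure(
    list(
      time_points_h = as.numeric(time_points_h),
      rescued_survival = as.numeric(rescued_survival),
      trapped_survival = as.numeric(trapped_survival)
    ),
    class = "survival_schedule"
  )
  validate_survival_schedule(obj)
  obj
}

validate_survival_schedule <- function(s) {
  t <- s$time_points_h
  for (nm in c("rescued_survival", "trapped_survival")) {
    v <- s[[nm]]
    if (length(v) != length(t)) stop("survival_schedule: length mismatch in ", nm)
    if (abs(v[1] - 1) > 1e-12) stop("survival_schedule: ", nm, " must start at 1")
    if (any(diff(v) > 1e-12)) stop("survival_schedule: ", nm, " must be non-increasing")
    if (any(v <= 0) || any(v > 1)) stop("survival_schedule: ", nm, " must lie in (0, 1]")
  }
  if (any(s$rescued_survival < s$trapped_survival - 1e-12)) {
    stop("survival_schedule: rescued_survival must be >= trapped_survival")
  }
  invisible(s)
}

#' Structural model configuration (the exposed switches)
#'
#' The published description of the rescue model leaves several mechanics
#' open; each is exposed here as a switch and adjudicated by the calibration
#' search ([calibrate_model()]). The package default is the frozen winning
#' configuration of that search.
#'
#' @param rate_input how the printed time-indexed rate columns are read:
#'   `"cumulative"` treats them as cumulative margins and converts them to
#'   per-cycle conditional probabilities by successive ratios;
#'   `"per_cycle"` reads the value at the end of each cycle directly as that
#'   cycle's transition probability.
#' @param ordering_rule within-cycle event ordering for the trapped state:
#'   `"rescue_first"` (rescue resolved before that cycle's mortality),
#'   `"death_first"`, or `"competing"` (constant competing hazards within the
#'   cycle).
#' @param rescued_survival_mode how the rescued-victims survival column acts:
#'   `"cohort_cumulative"` applies the per-cycle conditional mortality to
#'   everyone currently rescued; `"at_rescue"` applies the cumulative
#'   survival at the time of rescue once, to the newly rescued;
#'   `"from_rescue"` applies survival from the time of rescue to the model
#'   horizon (`S_R(horizon) / S_R(t_rescue)`) once, to the newly rescued.
#' @param productivity_loss_scope whether the value of lost life is charged
#'   for `"all_deaths"` or only `"trapped_deaths"` (victims who die awaiting
#'   rescue; those dying after rescue have already incurred medical care).
#' @param medical_cost_scope medical cost charged per person `"rescued"`
#'   (ever rescued) or per cohort member (`"all"`).
#' @param intervention_components which fixed cost components are charged to
#'   the intervention arm, a subset of
#'   `c("av_program", "overhead", "regulation_fee")`.
#' @param regulation_fee_both_arms charge the regulation fee in the status
#'   quo arm as well (default `FALSE`: intervention only).
#' @param qaly_integer_years truncate the remaining-life summation index to
#'   whole years (default `TRUE`).
#' @param half_cycle apply a half-cycle correction to the terminal survivor
#'   fraction (default `FALSE`; rewards here are terminal, not per-cycle
#'   accruals).
#' @return object of class `model_config`.
#' @export
model_config <- function(rate_input = c("per_cycle", "cumulative"),
                         ordering_rule = c("competing", "rescue_first",
                                           "death_first"),
                         rescued_survival_mode = c("from_rescue",
                                                   "cohort_cumulative",
                                                   "at_rescue"),
                         productivity_loss_scope = c("trapped_deaths",
                                                     "all_deaths"),
                         medical_cost_scope = c("rescued", "all"),
                         intervention_components = c("av_program",
                                                     "regulation_fee"),
                         regulation_fee_both_arms = FALSE,
                         qaly_integer_years = TRUE,
                         half_cycle = FALSE) {
  rate_input <- match.arg(rate_input)
  ordering_rule <- match.arg(ordering_rule)
  rescued_survival_mode <- match.arg(rescued_survival_mode)
  productivity_loss_scope <- match.arg(productivity_loss_scope)
  medical_cost_scope <- match.arg(medical_cost_scope)
  bad <- setdiff(intervention_components,
                 c("av_program", "overhead", "regulation_fee"))
  if (length(bad)) stop("model_config: unknown intervention component: ",
                        paste(bad, collapse = ", "))
  structure(
    list(
      rate_input = rate_input, ordering_rule = ordering_rule,
      rescued_survival_mode = rescued_survival_mode,
      productivity_loss_scope = productivity_loss_scope,
      medical_cost_scope = medical_cost_scope,
      intervention_components = intervention_components,
      regulation_fee_both_arms = isTRUE(regulation_fee_both_arms),
      qaly_integer_years = isTRUE(qaly_integer_years),
      half_cycle = isTRUE(half_cycle)
    ),
    class = "model_config"
  )
}

#' Full model parameter set
#'
#' @param costs a [cost_inputs()] object.
#' @param utilities a [utility_inputs()] object.
#' @param schedules named list, one entry per arm, each a list with elements
#'   `rescue` ([rescue_schedule()]) and `survival` ([survival_schedule()]).
#' @param cycle_hours Markov cycle length, hours.
#' @param cohort_size number of initially trapped victims.
#' @param distance_to_hospital_miles average one-way distance from the
#'   disaster area to the nearest hospital (symbol D).
#' @param seats_per_vehicle seats per autonomous vehicle (symbol N).
#' @param config a [model_config()].
#' @return object of class `model_params`.
#' @export
model_params <- function(costs, utilities, schedules, cycle_hours = 6,
                         cohort_size = 1000,
                         distance_to_hospital_miles = 2.5,
                         seats_per_vehicle = 4,
                         config = model_config()) {
  obj <- structure(
    list(
      costs = costs, utilities = utilities, schedules = schedules,
      cycle_hours = cycle_hours, cohort_size = cohort_size,
      distance_to_hospital_miles = distance_to_hospital_miles,
      seats_per_vehicle = seats_per_vehicle, config = config
    ),
    class = "model_params"
  )
  validate_params(obj)
  obj
}

#' Validate a full parameter set
#'
#' Checks every structural invariant: cost triples ordered, utility in range,
#' schedules monotone with matching time grids and cycle spacing, rescued
#' survival dominating trapped survival, and positive cohort constants.
#'
#' @param params a `model_params` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  validate_cost_inputs(params$costs)
  if (params$cohort_size <= 0) stop("model_params: cohort_size must be > 0")
  if (params$distance_to_hospital_miles <= 0) {
    stop("model_params: distance_to_hospital_miles must be > 0")
  }
  if (params$seats_per_vehicle < 1) {
    stop("model_params: seats_per_vehicle must be >= 1")
  }
  if (!length(params$schedules)) stop("model_params: no schedules")
  for (lab in names(params$schedules)) {
    arm <- params$schedules[[lab]]
    validate_rescue_schedule(arm$rescue, cycle_hours = params$cycle_hours)
    validate_survival_schedule(arm$survival)
    if (!isTRUE(all.equal(arm$rescue$time_points_h,
                          arm$survival$time_points_h))) {
      stop("model_params: rescue and survival time grids differ in arm ", lab)
    }
  }
  invisible(params)
}

#' Variable (per-trip) AV transport cost per person
#'
#' The published per-person trip cost formula
#' `cost/person = (cost per vehicle-mile) x D / N`, where `D` is the average
#' distance from the disaster area to the nearest hospital and `N` the number
#' of seats per vehicle. Only the variable per-mile components enter; fixed
#' components (overhead, regulation fee, the aggregate AV cost per person)
#' are separate fields of [cost_inputs()].
#'
#' @param gas_per_mile,maintenance_per_mile USD per vehicle-mile.
#' @param D distance to hospital, miles (> 0).
#' @param N seats per vehicle (> 0).
#' @return USD per transported person.
#' @examples
#' av_cost_per_person(0.16, 0.05, 2.5, 4) # 0.13125
#' @export
av_cost_per_person <- function(gas_per_mile, maintenance_per_mile, D, N) {
  if (N <= 0) stop("av_cost_per_person: N must be positive")
  if (D <= 0) stop("av_cost_per_person: D must be positive")
  if (gas_per_mile < 0 || maintenance_per_mile < 0) {
    stop("av_cost_per_person: per-mile rates must be non-negative")
  }
  (gas_per_mile + maintenance_per_mile) * D / N
}

#' Canonical parameter fixture (the published input tables)
#'
#' Returns the in-package encoding of the published cost table and
#' rescue/survival schedules: four arms (status quo and 5/10/15% efficiency
#' improvement), percentages stored as fractions. The 10% and 15% arms
#' complete rescue by 18 h and therefore carry three cycles; the printed `0`
#' in their 24-h row is a sentinel for "no one left to rescue", not a
#' probability, and is not encoded.
#'
#' @param config optional [model_config()] override.
#' @return a validated [model_params()] object.
#' @export
paper_fixture <- function(config = model_config()) {
  costs <- cost_inputs(
    gas_per_mile = c(base = 0.16, low = 0.12, high = 0.20),
    maintenance_per_mile = c(base = 0.05, low = 0.04, high = 0.06),
    overhead_per_person = c(base = 1066.18, low = 799.64, high = 1332.73),
    av_cost_per_person = c(base = 3471, low = 2603, high = 4339),
    medical_cost_per_person = c(base = 1001.14, low = 750.86, high = 1251.43),
    value_of_lost_life = c(base = 176482.98, low = 132362.24,
                           high = 220603.73),
    regulation_fee_per_person = c(base = 3204.58, low = 2403.44,
                                  high = 4005.73)
  )
  t4 <- seq(0, 24, by = 6)
  t3 <- seq(0, 18, by = 6)
  sr <- c(1, 0.96, 0.90, 0.84, 0.78)
  st <- c(1, 0.60, 0.44, 0.38, 0.32)
  surv4 <- survival_schedule(t4, sr, st)
  surv3 <- survival_schedule(t3, sr[1:4], st[1:4])
  schedules <- list(
    status_quo = list(
      rescue = rescue_schedule("status_quo", 0, t4,
                               c(0, 0.42, 0.56, 0.94, 1.00)),
      survival = surv4
    ),
    improvement_5 = list(
      rescue = rescue_schedule("improvement_5", 0.05, t4,
                               c(0, 0.44, 0.58, 0.99, 1.00)),
      survival = surv4
    ),
    improvement_10 = list(
      rescue = rescue_schedule("improvement_10", 0.10, t3,
                               c(0, 0.45, 0.59, 1.00)),
      survival = surv3
    ),
    improvement_15 = list(
      rescue = rescue_schedule("improvement_15", 0.15, t3,
                               c(0, 0.47, 0.62, 1.00)),
      survival = surv3
    )
  )
  model_params(
    costs = costs, utilities = utility_inputs(), schedules = schedules,
    cycle_hours = 6, cohort_size = 1000, distance_to_hospital_miles = 2.5,
    seats_per_vehicle = 4, config = config
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat("  arms:", paste(names(x$schedules), collapse = ", "), "\n")
  cat("  cycle:", x$cycle_hours, "h; cohort:", x$cohort_size, "\n")
  cat("  utility:", x$utilities$utility_survivor,
      "; discount:", x$utilities$discount_rate,
      "; remaining years:", x$utilities$remaining_years, "\n")
  invisible(x)
}
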