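#' Discounted lifetime QALYs of one survivor
#'
#' The survivor's expected quality-adjusted life years,
#' \deqn{\mathrm{QALY} = \sum_{n=1}^{\lfloor k \rfloor} \frac{U}{(1+r)^n},}
#' with utility weight `U`, annual discount rate `r` and `k` remaining life
#' years. Equals `U * k` when `r = 0` and the closed-form annuity
#' `U (1 - (1+r)^{-floor(k)}) / r` otherwise.
#'
#' @param U utility weight in `[0, 1]`.
#' @param r annual discount rate, >= 0.
#' @param k remaining life years, >= 0.
#' @param integer_years truncate `k` to whole years (default). With
#'   `FALSE`, the final fractional year contributes proportionally.
#' @return discounted QALYs (scalar).
#' @examples
#' lifetime_qaly(0.68, 0.03, 41) # 15.92043
#' @export
lifetime_qaly <- function(U, r, k, integer_years = TRUE) {
  if (U < 0 || U > 1) stop("lifetime_qaly: U must lie in [0, 1]")
  if (r < 0) stop("lifetime_qaly: r must be >= 0")
  if (k < 0) stop("lifetime_qaly: k must be >= 0")
  kk <- floor(k)
  out <- if (kk >= 1) sum(U / (1 + r)^(seq_len(kk))) else 0
  if (!integer_years && k > kk) {
    out <- out + (k - kk) * U / (1 + r)^(kk + 1)
  }
  out
}

#' Run one strategy arm: schedules to cohort trace
#'
#' @param params a [model_params()].
#' @param arm_label name of an arm in `params$schedules`.
#' @param config optional [model_config()] override (defaults to
#'   `params$config`).
#' @return a `cohort_trace` for the arm.
#' @export
run_arm <- function(params, arm_label, config = NULL) {
  config <- config %||% params$config
  arm <- params$schedules[[arm_label]]
  if (is.null(arm)) {
    stop("run_arm: unknown arm '", arm_label, "'; available: ",
         paste(names(params$schedules), collapse = ", "))
  }
  tr <- derive_cycle_transitions(arm$rescue, arm$survival,
                                 rate_input = config$rate_input)
  run_cohort(tr, ordering_rule = config$ordering_rule,
             rescued_survival_mode = config$rescued_survival_mode,
             arm_label = arm_label)
}

#' Expected per-person cost and QALYs of an arm
#'
#' Cost components:
#' * intervention arms are charged the fixed AV-programme components selected
#'   by `config$intervention_components` (aggregate AV cost per person,
#'   overhead, regulation fee) plus the variable per-trip transport cost
#'   ([av_cost_per_person()]) for every person ever rescued;
#' * medical cost per person ever rescued (or per cohort member, by
#'   `config$medical_cost_scope`);
#' * the value of lost life per death, scoped to all deaths or to deaths
#'   while still trapped by `config$productivity_loss_scope`.
#'
#' QALYs: terminal survivors times [lifetime_qaly()]. Costs and health in the
#' 24-hour window itself are not discounted (the window is far below one
#' year); `lifetime_qaly()` embeds the annual discounting of life years.
#'
#' @param trace a `cohort_trace` from [run_arm()].
#' @param params a [model_params()].
#' @param arm_is_intervention logical; charges the AV programme costs.
#' @param config optional [model_config()] override.
#' @return object of class `arm_result`: list with `arm_label`,
#'   `expected_cost_per_person`, `expected_qaly_per_person`,
#'   `cost_breakdown` (named numeric), `survivors`, `ever_rescued`,
#'   `dead_trapped`, `dead_rescued`.
#' @export
arm_outcomes <- function(trace, params, arm_is_intervention,
                         config = NULL) {
  config <- config %||% params$config
  cb <- params$costs
  ever <- attr(trace, "ever_rescued")
  dead_t <- sum(attr(trace, "dead_trapped"))
  dead_r <- sum(attr(trace, "dead_rescued"))
  surv <- terminal_survivors(trace)
  if (config$half_cycle) {
    prev <- trace$rescued[nrow(trace) - 1]
    surv <- (surv + prev) / 2
  }

  breakdown <- c(av_program = 0, overhead = 0, regulation_fee = 0,
                 av_transport = 0, medical = 0, productivity_loss = 0)
  if (arm_is_intervention) {
    comp <- config$intervention_components
    if ("av_program" %in% comp) {
      breakdown["av_program"] <- cb$av_cost_per_person[["base"]]
    }
    if ("overhead" %in% comp) {
      breakdown["overhead"] <- cb$overhead_per_person[["base"]]
    }
    if ("regulation_fee" %in% comp) {
      breakdown["regulation_fee"] <- cb$regulation_fee_per_person[["base"]]
    }
    breakdown["av_transport"] <- ever * av_cost_per_person(
      cb$gas_per_mile[["base"]], cb$maintenance_per_mile[["base"]],
      params$distance_to_hospital_miles, params$seats_per_vehicle
    )
  } else if (config$regulation_fee_both_arms) {
    breakdown["regulation_fee"] <- cb$regulation_fee_per_person[["base"]]
  }
  med_frac <- if (config$medical_cost_scope == "rescued") ever else 1
  breakdown["medical"] <- med_frac * cb$medical_cost_per_person[["base"]]
  dead_scope <- if (config$productivity_loss_scope == "all_deaths") {
    dead_t + dead_r
  } else {
    dead_t
  }
  breakdown["productivity_loss"] <- dead_scope * cb$value_of_lost_life[["base"]]

  u <- params$utilities
  lq <- lifetime_qaly(u$utility_survivor, u$discount_rate, u$remaining_years,
                      integer_years = config$qaly_integer_years)
  structure(
    list(
      arm_label = attr(trace, "arm_label"),
      expected_cost_per_person = sum(breakdown),
      expected_qaly_per_person = surv * lq,
      cost_breakdown = breakdown,
      survivors = surv, ever_rescued = ever,
      dead_trapped = dead_t, dead_rescued = dead_r
    ),
    class = "arm_result"
  )
}

#' Incremental cost-effectiveness with dominance handling
#'
#' @param reference `arm_result` of the comparator (status quo).
#' @param comparator `arm_result` of the strategy under evaluation.
#' @return object of class `ce_result`: `incremental_cost`,
#'   `incremental_qaly`, `icer` (finite only when `dominance == "interior"`,
#'   otherwise `NA`), and `dominance` in `interior`, `cost_saving_dominant`,
#'   `dominated`, `icer_undefined`.
#' @export
icer <- function(reference, comparator) {
  dc <- comparator$expected_cost_per_person - reference$expected_cost_per_person
  de <- comparator$expected_qaly_per_person - reference$expected_qaly_per_person
  dominance <-
    if (de == 0) {
      if (dc < 0) "cost_saving_dominant" else "icer_undefined"
    } else if (de > 0) {
      if (dc <= 0) "cost_saving_dominant" else "interior"
    } else {
      if (dc >= 0) "dominated" else "interior"
    }
  if (de == 0 && dc == 0) dominance <- "icer_undefined"
  structure(
    list(
      incremental_cost = dc, incremental_qaly = de,
      icer = if (dominance == "interior") dc / de else NA_real_,
      dominance = dominance
    ),
    class = "ce_result"
  )
}

#' Run a full two-arm comparison
#'
#' @param params a [model_params()].
#' @param intervention arm label of the intervention.
#' @param reference arm label of the comparator (default `"status_quo"`).
#' @param config optional [model_config()] override.
#' @return list with `reference`, `intervention` (both `arm_result`) and
#'   `ce` (a `ce_result`).
#' @export
compare_arms <- function(params, intervention, reference = "status_quo",
                         config = NULL) {
  config <- config %||% params$config
  ref_tr <- run_arm(params, reference, config)
  int_tr <- run_arm(params, intervention, config)
  ref <- arm_outcomes(ref_tr, params, arm_is_intervention = FALSE,
                      config = config)
  int <- arm_outcomes(int_tr, params, arm_is_intervention = TRUE,
                      config = config)
  list(reference = ref, intervention = int, ce = icer(ref, int))
}

#' Results table across all improvement arms
#'
#' One row per arm with expected cost, incremental cost, QALYs, incremental
#' QALYs and the ICER (or a dominance label), mirroring the conventional
#' cost-effectiveness results table. Full precision is kept in the numeric
#' columns; `icer_label` carries `"Cost saving"` for dominant arms.
#'
#' @param params a [model_params()].
#' @param config optional [model_config()] override.
#' @return data frame, reference arm first.
#' @export
ce_table <- function(params, config = NULL) {
  config <- config %||% params$config
  labs <- names(params$schedules)
  ref_lab <- labs[1]
  rows <- list()
  ref_tr <- run_arm(params, ref_lab, config)
  ref <- arm_outcomes(ref_tr, params, FALSE, config)
  rows[[ref_lab]] <- data.frame(
    arm = ref_lab, cost = ref$expected_cost_per_person,
    incremental_cost = NA_real_, qaly = ref$expected_qaly_per_person,
    incremental_qaly = NA_real_, icer = NA_real_, icer_label = "-"
  )
  for (lab in labs[-1]) {
    cmp <- compare_arms(params, lab, ref_lab, config)
    lbl <- switch(cmp$ce$dominance,
      interior = formatC(cmp$ce$icer, format = "f", digits = 0,
                         big.mark = ","),
      cost_saving_dominant = "Cost saving",
      dominated = "Dominated",
      icer_undefined = "icer_undefined"
    )
    rows[[lab]] <- data.frame(
      arm = lab, cost = cmp$intervention$expected_cost_per_person,
      incremental_cost = cmp$ce$incremental_cost,
      qaly = cmp$intervention$expected_qaly_per_person,
      incremental_qaly = cmp$ce$incremental_qaly,
      icer = cmp$ce$icer, icer_label = lbl
    )
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result>", x$arm_label, "\n")
  cat("  cost/person: $", formatC(x$expected_cost_per_person, format = "f",
                                  digits = 2, big.mark = ","), "\n", sep = "")
  cat("  QALY/person:", round(x$expected_qaly_per_person, 4), "\n")
  cat("  survivors:", round(x$survivors, 4),
      " ever rescued:", round(x$ever_rescued, 4), "\n")
  invisible(x)
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> dC = $", round(x$incremental_cost, 2),
      ", dE = ", round(x$incremental_qaly, 4), " QALY, ",
      if (x$dominance == "interior") {
        paste0("ICER = $", formatC(x$icer, format = "f", digits = 0,
                                   big.mark = ","), "/QALY")
      } else {
        x$dominance
      }, "\n", sep = "")
  invisible(x)
}
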