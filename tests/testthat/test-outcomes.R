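test_that("lifetime QALYs equal the closed-form annuity", {
  # 41-term discounted sum, cross-checked against the annuity formula
  expect_equal(lifetime_qaly(0.68, 0.03, 41), 15.920431983,
               tolerance = 1e-9)
  expect_equal(lifetime_qaly(1.0, 0.0, 10), 10.0)
  expect_equal(lifetime_qaly(0.68, 0.03, 0), 0.0)

  set.seed(5)
  for (i in 1:2000) {
    U <- runif(1); r <- runif(1, 1e-6, 0.15); k <- runif(1, 0, 80)
    kk <- floor(k)
    annuity <- U * (1 - (1 + r)^(-kk)) / r
    expect_equal(lifetime_qaly(U, r, k), annuity, tolerance = 1e-10)
  }
  expect_error(lifetime_qaly(-0.1, 0.03, 41), "U must")
  expect_error(lifetime_qaly(0.68, -0.01, 41), "r must")
})

test_that("lifetime QALYs are monotone in utility and horizon, antitone in r", {
  expect_gt(lifetime_qaly(0.9, 0.03, 41), lifetime_qaly(0.68, 0.03, 41))
  expect_gt(lifetime_qaly(0.68, 0.03, 50), lifetime_qaly(0.68, 0.03, 41))
  expect_lt(lifetime_qaly(0.68, 0.05, 41), lifetime_qaly(0.68, 0.03, 41))
  # fractional-year switch adds the partial final year
  expect_gt(lifetime_qaly(0.68, 0.03, 41.1, integer_years = FALSE),
            lifetime_qaly(0.68, 0.03, 41.1, integer_years = TRUE))
})

make_trace <- function(pr, pdt, n = 1) {
  tr <- data.frame(cycle = seq_len(n), p_rescue_given_trapped = pr,
                   p_death_given_trapped = pdt, p_death_given_rescued = 0)
  attr(tr, "time_points_h") <- seq(0, n * 6, by = 6)
  attr(tr, "rescued_survival") <- rep(1, n + 1)
  class(tr) <- c("cycle_transitions", "data.frame")
  run_cohort(tr, "rescue_first")
}

test_that("arm costs decompose as documented", {
  p <- paper_fixture()
  cfg <- model_config(rate_input = "cumulative",
                      ordering_rule = "rescue_first",
                      rescued_survival_mode = "cohort_cumulative",
                      productivity_loss_scope = "all_deaths",
                      medical_cost_scope = "rescued",
                      intervention_components = c("av_program", "overhead",
                                                  "regulation_fee"))
  all_rescued <- make_trace(1, 0)
  res <- arm_outcomes(all_rescued, p, arm_is_intervention = FALSE,
                      config = cfg)
  expect_equal(res$expected_cost_per_person,
               p$costs$medical_cost_per_person[["base"]])
  u <- p$utilities
  expect_equal(res$expected_qaly_per_person,
               lifetime_qaly(u$utility_survivor, u$discount_rate,
                             u$remaining_years))

  all_dead <- make_trace(0, 1)
  res2 <- arm_outcomes(all_dead, p, arm_is_intervention = FALSE, config = cfg)
  expect_equal(res2$expected_cost_per_person,
               p$costs$value_of_lost_life[["base"]])
  expect_equal(res2$expected_qaly_per_person, 0)

  # intervention minus status quo on identical traces = AV programme costs
  int <- arm_outcomes(all_rescued, p, arm_is_intervention = TRUE,
                      config = cfg)
  expect_equal(
    int$expected_cost_per_person - res$expected_cost_per_person,
    p$costs$av_cost_per_person[["base"]] +
      p$costs$overhead_per_person[["base"]] +
      p$costs$regulation_fee_per_person[["base"]] +
      av_cost_per_person(0.16, 0.05, 2.5, 4) # everyone transported once
  )
})

test_that("costs are linear in the unit inputs", {
  p <- paper_fixture()
  trace <- run_arm(p, "status_quo")
  base <- arm_outcomes(trace, p, FALSE)
  p2 <- p
  p2$costs$value_of_lost_life <- p2$costs$value_of_lost_life * 2
  doubled <- arm_outcomes(trace, p2, FALSE)
  expect_equal(doubled$cost_breakdown[["productivity_loss"]],
               2 * base$cost_breakdown[["productivity_loss"]])
  expect_equal(doubled$expected_qaly_per_person,
               base$expected_qaly_per_person)
})

test_that("ICER arithmetic and dominance sentinels", {
  mk <- function(cost, qaly) {
    structure(list(arm_label = "x", expected_cost_per_person = cost,
                   expected_qaly_per_person = qaly),
              class = "arm_result")
  }
  r <- icer(mk(0, 0), mk(100, 2))
  expect_equal(r$icer, 50)
  expect_identical(r$dominance, "interior")

  cs <- icer(mk(87869, 7.20), mk(87869 - 893, 7.20 + 0.56))
  expect_identical(cs$dominance, "cost_saving_dominant")
  expect_true(is.na(cs$icer))

  expect_identical(icer(mk(10, 1), mk(10, 1))$dominance, "icer_undefined")
  expect_identical(icer(mk(10, 1), mk(20, 0.5))$dominance, "dominated")
  sw <- icer(mk(10, 1), mk(5, 0.5)) # cheaper, less effective: interior
  expect_identical(sw$dominance, "interior")
  expect_equal(sw$icer, 10) # savings per QALY forgone
})

test_that("reported interior ICER is exactly dC/dE at full precision", {
  p <- paper_fixture()
  cmp <- compare_arms(p, "improvement_5")
  expect_identical(cmp$ce$dominance, "interior")
  expect_equal(cmp$ce$icer,
               cmp$ce$incremental_cost / cmp$ce$incremental_qaly,
               tolerance = 1e-15)
})

test_that("results table covers all arms with dominance labels", {
  tab <- ce_table(paper_fixture())
  expect_equal(tab$arm, c("status_quo", "improvement_5", "improvement_10",
                          "improvement_15"))
  expect_identical(tab$icer_label[4], "Cost saving")
  expect_true(all(diff(tab$qaly) > 0 | is.na(diff(tab$qaly))))
  expect_true(is.na(tab$incremental_cost[1]))
})

test_that("run_arm rejects unknown arms", {
  expect_error(run_arm(paper_fixture(), "improvement_50"), "unknown arm")
})
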