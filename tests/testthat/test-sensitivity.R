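test_that("null perturbation reproduces the base-case ICER", {
  p <- paper_fixture()
  tor <- tornado(p, pct = 0)
  base <- attr(tor, "base_icer")
  expect_equal(tor$icer_low, rep(base, 5), tolerance = 1e-12)
  expect_equal(tor$icer_high, rep(base, 5), tolerance = 1e-12)
})

test_that("tornado rejects unknown variables with a helpful message", {
  expect_error(tornado(paper_fixture(), variables = "phlogiston"),
               "valid names.*rescued_survival")
})

test_that("structural tornado directions: dearer programme, higher ICER", {
  p <- paper_fixture()
  tor <- tornado(p, variables = c("av_costs", "productivity_loss",
                                  "discount_rate"))
  base <- attr(tor, "base_icer")
  av <- tor[tor$variable == "av_costs", ]
  expect_gt(av$icer_high, base)
  expect_lt(av$icer_low, base)
  # a higher value of lost life rewards the life-saving arm
  vl <- tor[tor$variable == "productivity_loss", ]
  expect_lt(vl$icer_high, base)
  expect_gt(vl$icer_low, base)
  # heavier discounting shrinks the QALY denominator
  dr <- tor[tor$variable == "discount_rate", ]
  expect_gt(dr$icer_high, base)
  expect_lt(dr$icer_low, base)
})

degenerate_params <- function() {
  p <- paper_fixture()
  for (nm in names(p$costs)) {
    b <- p$costs[[nm]][["base"]]
    p$costs[[nm]] <- c(base = b, low = b, high = b)
  }
  p
}

test_that("degenerate distributions reproduce the base case exactly", {
  p <- degenerate_params()
  ps <- run_psa(p, psa_config(n_draws = 50, seed = 3, scale_range = 0))
  base <- compare_arms(p, "improvement_5")$ce
  expect_equal(ps$draws$delta_cost, rep(base$incremental_cost, 50),
               tolerance = 1e-12)
  expect_equal(ps$draws$delta_qaly, rep(base$incremental_qaly, 50),
               tolerance = 1e-12)
  # acceptability is a step function at the base ICER
  icer_base <- base$incremental_cost / base$incremental_qaly
  expect_equal(ps$ceac$prob_cost_effective,
               as.numeric(ps$ceac$wtp > icer_base))
  expect_identical(ps$rejections, 0L)
})

test_that("PSA draws are bit-reproducible for a fixed seed", {
  p <- paper_fixture()
  a <- run_psa(p, psa_config(n_draws = 150, seed = 11))
  b <- run_psa(p, psa_config(n_draws = 150, seed = 11))
  expect_identical(a$draws, b$draws)
  c <- run_psa(p, psa_config(n_draws = 150, seed = 12))
  expect_false(identical(a$draws, c$draws))
})

test_that("CEAC limits match their defining fractions", {
  p <- paper_fixture()
  ps <- run_psa(p, psa_config(n_draws = 400, seed = 21,
                              wtp_grid = c(0, 1e5, 1e9)))
  expect_equal(ps$ceac$prob_cost_effective[1],
               mean(ps$draws$delta_cost < 0))
  expect_equal(ps$ceac$prob_cost_effective[3],
               mean(ps$draws$delta_qaly > 0 |
                      (ps$draws$delta_qaly == 0 & ps$draws$delta_cost < 0)),
               tolerance = 0.01)
  expect_true(all(ps$ceac$prob_cost_effective >= 0 &
                    ps$ceac$prob_cost_effective <= 1))
})

test_that("triangular sampling has the textbook mean", {
  set.seed(8)
  lo <- 2; mo <- 5; hi <- 14
  x <- rtriangular(10000, lo, mo, hi)
  expect_true(all(x >= lo & x <= hi))
  mu <- (lo + mo + hi) / 3
  sdv <- sqrt((lo^2 + mo^2 + hi^2 - lo * mo - lo * hi - mo * hi) / 18)
  expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(10000))
  expect_equal(rtriangular(5, 3, 3, 3), rep(3, 5))
  expect_error(rtriangular(5, 3, 2, 4), "low <= mode <= high")
})

test_that("credible intervals follow the mid-point percentile rule", {
  expect_equal(credible_interval(1:100, 0.9), c(5.5, 95.5))
  expect_equal(credible_interval(rep(4.2, 50), 0.95), c(4.2, 4.2))
  # manual order-statistic interpolation at h = n p + 1/2
  x <- sort(rnorm(37))
  h <- 37 * 0.025 + 0.5
  lo <- x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  expect_equal(credible_interval(x, 0.95)[1], lo)
  expect_error(credible_interval(numeric(0)), "empty")
})

test_that("ICER interval labels dominant bounds as cost-saving", {
  draws <- data.frame(
    delta_cost = c(-500, -100, 200, 800, 1500),
    delta_qaly = c(0.4, 0.3, 0.25, 0.2, 0.1)
  )
  ci <- icer_interval(draws, wtp = 1e5, level = 0.6)
  expect_match(ci[["low"]], "cost-saving")
  expect_match(ci[["high"]], "^[0-9]+$")
})

test_that("the cost-effectiveness plane exports one row per draw", {
  p <- paper_fixture()
  ps <- run_psa(p, psa_config(n_draws = 10, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  ce_plane_export(ps, f)
  df <- read.csv(f)
  expect_named(df, c("delta_qaly", "delta_cost"))
  expect_equal(nrow(df), 10)
  expect_equal(df$delta_cost, ps$draws$delta_cost, tolerance = 1e-9)

  empty <- structure(list(draws = data.frame(delta_cost = numeric(0),
                                             delta_qaly = numeric(0))),
                     class = "psa_result")
  f2 <- withr::local_tempfile(fileext = ".csv")
  ce_plane_export(empty, f2)
  expect_equal(nrow(read.csv(f2)), 0)

  expect_s3_class(plot_ce_plane(ps), "ggplot")
  expect_s3_class(plot_ceac(ps), "ggplot")
  expect_s3_class(plot_tornado(tornado(p)), "ggplot")
})
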