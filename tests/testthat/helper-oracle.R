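# Independent brute-force cohort propagator: explicit per-cycle 3x3
# stochastic matrices multiplied into the occupancy row vector. Kept
# deliberately separate from the engine's flow arithmetic so the two can
# cross-check each other.
oracle_run_cohort <- function(transitions, ordering_rule,
                              rescued_survival_mode = "cohort_cumulative") {
  SR <- attr(transitions, "rescued_survival")
  n <- nrow(transitions)
  p_new <- switch(rescued_survival_mode,
    cohort_cumulative = rep(0, n),
    at_rescue = 1 - SR[2:(n + 1)],
    from_rescue = 1 - SR[n + 1] / SR[2:(n + 1)]
  )
  p_stand <- if (rescued_survival_mode == "cohort_cumulative") {
    transitions$p_death_given_rescued
  } else {
    rep(0, n)
  }
  occ <- c(1, 0, 0)
  hist <- matrix(NA_real_, n + 1, 3)
  hist[1, ] <- occ
  for (c in seq_len(n)) {
    q <- transitions$p_rescue_given_trapped[c]
    dt <- transitions$p_death_given_trapped[c]
    dn <- p_new[c]
    dr <- p_stand[c]
    if (ordering_rule == "rescue_first") {
      row_t <- c((1 - q) * (1 - dt), q * (1 - dn), q * dn + (1 - q) * dt)
    } else if (ordering_rule == "death_first") {
      row_t <- c((1 - dt) * (1 - q), (1 - dt) * q * (1 - dn),
                 dt + (1 - dt) * q * dn)
    } else { # competing constant hazards (q < 1, dt < 1 assumed here)
      a <- -log(1 - q); b <- -log(1 - dt)
      stay <- (1 - q) * (1 - dt)
      if (a + b == 0) {
        row_t <- c(1, 0, 0)
      } else {
        leave <- 1 - stay
        wq <- a / (a + b)
        row_t <- c(stay, leave * wq * (1 - dn),
                   leave * (wq * dn + (1 - wq)))
      }
    }
    M <- rbind(row_t, c(0, 1 - dr, dr), c(0, 0, 1))
    occ <- as.numeric(occ %*% M)
    hist[c + 1, ] <- occ
  }
  colnames(hist) <- c("trapped", "rescued", "dead")
  hist
}

# Random valid transition set for fuzzing (probabilities strictly inside
# [0, 1) so every ordering rule, including competing hazards, is exercised
# away from its saturated edge cases).
random_transitions <- function(n_cycles = 4) {
  tr <- data.frame(
    cycle = seq_len(n_cycles),
    p_rescue_given_trapped = runif(n_cycles, 0, 0.95),
    p_death_given_trapped = runif(n_cycles, 0, 0.9),
    p_death_given_rescued = runif(n_cycles, 0, 0.5)
  )
  attr(tr, "time_points_h") <- seq(0, n_cycles * 6, by = 6)
  attr(tr, "rescued_survival") <- cumprod(c(1, runif(n_cycles, 0.6, 1)))
  class(tr) <- c("cycle_transitions", "data.frame")
  tr
}

fixture_status_quo_transitions <- function(rate_input = "cumulative") {
  p <- paper_fixture()
  arm <- p$schedules$status_quo
  derive_cycle_transitions(arm$rescue, arm$survival, rate_input = rate_input)
}
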