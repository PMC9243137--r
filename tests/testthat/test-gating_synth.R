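test_that("two-state relaxation matches the closed-form mono-exponential", {
  m <- builtin_model("two_state", n_channels = 1)
  pr <- voltage_protocol(tibble::tibble(duration = c(0.05, 0.1),
                                        voltage = c(-80, 20)), rate = 5000)
  tr <- simulate_macroscopic(m, pr)
  a <- 50 * exp(0.5 * 20 / 25.7)       # C->O at +20
  b <- 30 * exp(-0.5 * 20 / 25.7)      # O->C at +20
  p_inf <- a / (a + b)
  seg <- dplyr::filter(tr, voltage_mV == 20)
  t_rel <- seg$time_s - seg$time_s[1]
  p0 <- seg$O[1]
  expect_lt(max(abs(seg$O - (p_inf + (p0 - p_inf) * exp(-(a + b) * t_rel)))),
            1e-8)
  # occupancies conserve probability
  states <- as.matrix(tr[, c("C", "O")])
  expect_lt(max(abs(rowSums(states) - 1)), 1e-10)
})

test_that("four-state scheme conserves probability and produces the tail hook", {
  wt <- builtin_model("wt")
  pr <- activation_protocol(tail_mV = -120, rate = 2000, hold_s = 0.05)
  tr <- simulate_macroscopic(wt, pr)
  expect_lt(max(abs(rowSums(as.matrix(tr[, wt$states])) - 1)), 1e-10)
  # hook: |tail| grows after repolarization before decaying
  tail <- dplyr::filter(tr, time_s >= 4.05)
  expect_gt(max(abs(tail$current_pA)), abs(tail$current_pA[1]) * 1.2)
  # removing the inactivation pathway removes the hook (monotone tail)
  ni <- builtin_model("noninact")
  tr2 <- simulate_macroscopic(ni, pr)
  tail2 <- dplyr::filter(tr2, time_s >= 4.05 + 0.002)
  expect_true(all(diff(abs(tail2$current_pA)) <= 1e-9))
})

test_that("modifiers: identity, unknown role, inactivation removal dominance", {
  wt <- builtin_model("wt")
  same <- apply_modifier(wt, modifier_set())
  expect_equal(same$edges, wt$edges)
  expect_equal(same$shift, wt$shift)
  expect_error(apply_modifier(wt, modifier_set(c(nonsense = 2))), "nonsense")
  # removing inactivation increases P_open pathwise through the hold and
  # depolarizing step; during the tail the inactivated reservoir refills O
  # (the hook), so only the integrated open probability dominates there
  pr <- activation_protocol(tail_mV = -120, rate = 1000, hold_s = 0.05)
  tr_wt <- simulate_macroscopic(wt, pr)
  tr_ni <- simulate_macroscopic(
    apply_modifier(wt, modifier_set(c(inactivation_on = 0))), pr)
  pre_tail <- tr_wt$voltage_mV != -120
  expect_true(all(tr_ni$O[pre_tail] >= tr_wt$O[pre_tail] - 1e-9))
  expect_gt(sum(tr_ni$O), sum(tr_wt$O))
})

test_that("activation shift is recovered from the simulated G-V", {
  ni <- builtin_model("noninact")
  f1 <- fit_boltzmann(simulate_gv(ni))
  f2 <- fit_boltzmann(simulate_gv(apply_modifier(ni,
                                                 modifier_set(shift_mV = -25))))
  expect_equal(f2$v_half - f1$v_half, -25, tolerance = 1)
})

test_that("single-channel simulation: two levels, reproducibility, stationarity", {
  m <- builtin_model("two_state", n_channels = 1, g = 0.5, e_rev = -85)
  pr <- voltage_protocol(tibble::tibble(duration = 1, voltage = 55),
                         rate = 2000)
  tr <- simulate_single_channel(m, pr, noise_sd = 0, filter_cutoff = Inf,
                                seed = 11)
  lv <- sort(unique(round(tr$current_pA, 9)))
  expect_equal(lv, c(0, 0.5 * 1e-3 * (55 + 85)))
  tr2 <- simulate_single_channel(m, pr, noise_sd = 0.05, seed = 11)
  tr3 <- simulate_single_channel(m, pr, noise_sd = 0.05, seed = 11)
  tr4 <- simulate_single_channel(m, pr, noise_sd = 0.05, seed = 12)
  expect_identical(tr2$current_pA, tr3$current_pA)
  expect_false(identical(tr2$current_pA, tr4$current_pA))
  expect_error(simulate_single_channel(m, pr, noise_sd = 0), "seed")

  # long-run open probability within 3 SE of the stationary distribution
  prl <- voltage_protocol(tibble::tibble(duration = 500, voltage = 0),
                          rate = 200)
  trl <- simulate_single_channel(m, prl, noise_sd = 0, filter_cutoff = Inf,
                                 seed = 4)
  p_stat <- chanalyze:::stationary_distribution(m, 0)[["O"]]
  # effective sample size from the relaxation rate at 0 mV
  k_sum <- 50 + 30
  n_eff <- 500 * k_sum / 2
  se <- sqrt(p_stat * (1 - p_stat) / n_eff)
  expect_lt(abs(mean(trl$n_open) - p_stat), 3 * se + 0.01)
})

test_that("macroscopic trace equals the mean of 2,000 stochastic runs within 3 SE", {
  m <- builtin_model("two_state", n_channels = 1)
  pr <- voltage_protocol(tibble::tibble(duration = c(0.02, 0.04),
                                        voltage = c(-80, 40)), rate = 2000)
  mac <- simulate_macroscopic(m, pr)
  tr <- simulate_single_channel(m, pr, n_channels = 2000, noise_sd = 0,
                                filter_cutoff = Inf, seed = 8)
  p_emp <- tr$n_open / 2000
  se <- sqrt(pmax(mac$O * (1 - mac$O), 1e-12) / 2000)
  z <- abs(p_emp - mac$O) / pmax(se, 1e-6)
  # pointwise 3 SE, allowing a small number of excursions over 120 samples
  expect_lt(mean(z > 3), 0.02)
  expect_lt(abs(mean(p_emp) - mean(mac$O)), 3 * mean(se))
})

test_that("trace TSV + JSON sidecar round trip", {
  m <- builtin_model("two_state", n_channels = 1)
  pr <- voltage_protocol(tibble::tibble(duration = 0.05, voltage = 0),
                         rate = 1000)
  tr <- simulate_single_channel(m, pr, noise_sd = 0.02, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$current_pA, tr$current_pA, tolerance = 1e-9)
  expect_equal(attr(back, "kind"), "single_channel")
  expect_equal(attr(back, "seed"), 2)
})
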