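test_that("monotone decaying tails give fraction exactly 1; hooks recover closed form", {
  tt <- seq(0, 0.9, by = 2e-4)
  mono <- tibble::tibble(time_s = tt, current_pA = -80 * exp(-tt / 0.2))
  ta <- analyze_tail(mono, t0 = 0)
  expect_false(ta$hook)
  expect_identical(ta$non_inactivated_fraction, 1)

  for (f_rec in c(0.2, 0.5, 0.8)) {
    ht <- hook_tail(f_rec = f_rec)
    ta2 <- analyze_tail(ht, t0 = 0)
    expect_true(ta2$hook)
    expect_equal(ta2$non_inactivated_fraction, 1 - f_rec, tolerance = 0.02)
  }
  # property: random mono/bi-exponential decays are never hooks
  set.seed(14)
  for (rep in 1:20) {
    a1 <- runif(1, 10, 200); a2 <- runif(1, 0, 50)
    t1 <- runif(1, 0.05, 0.3); t2 <- runif(1, 0.01, 0.05)
    y <- a1 * exp(-tt / t1) + a2 * exp(-tt / t2)
    taa <- analyze_tail(tibble::tibble(time_s = tt, current_pA = y), t0 = 0)
    expect_false(taa$hook)
    expect_identical(taa$non_inactivated_fraction, 1)
  }
})

test_that("non-inactivated fraction is invariant under uniform gain", {
  ht <- hook_tail(f_rec = 0.6, noise_sd = 0)
  base <- analyze_tail(ht, t0 = 0)$non_inactivated_fraction
  for (gain in c(0.1, 3, -1, 40)) {
    sc <- dplyr::mutate(tibble::as_tibble(ht), current_pA = current_pA * gain)
    expect_equal(analyze_tail(sc, t0 = 0)$non_inactivated_fraction, base,
                 tolerance = 1e-9)
  }
})

test_that("G-V construction: proportional tails reproduce the source curve", {
  V <- seq(-80, 60, by = 20)
  g_true <- 1 / (1 + exp((-20 - V) / 9))
  tails <- tibble::tibble(voltage_mV = V, tail_pA = -350 * g_true)
  gv <- gv_curve(tails)
  expect_equal(gv$g, g_true / max(g_true), tolerance = 1e-12)
  # constant tails -> flat G-V of 1
  expect_true(all(gv_curve(tibble::tibble(voltage_mV = V,
                                          tail_pA = 5))$g == 1))
  # permutation invariance
  set.seed(3)
  p <- sample(length(V))
  gv2 <- gv_curve(tails[p, ])
  expect_equal(gv2, gv)
  expect_error(gv_curve(tibble::tibble(voltage_mV = V, tail_pA = 0)), "zero")
})

test_that("Boltzmann fit: exact noiseless recovery and half-max identity", {
  V <- seq(-80, 40, by = 10)
  g <- 1 / (1 + exp((-35.3 - V) / 8))
  fit <- fit_boltzmann(tibble::tibble(voltage_mV = V, g = g))
  expect_equal(fit$v_half, -35.3, tolerance = 1e-6)
  expect_equal(fit$k, 8, tolerance = 1e-6)
  expect_equal(fit$g_max, 1, tolerance = 1e-6)
  expect_gt(fit$k, 0)
  # G(V_half) = Gmax/2 by construction of the functional form
  expect_equal(predict(fit, fit$v_half), fit$g_max / 2, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "v_half"], fit$v_half)
  expect_equal(nrow(glance(fit)), 1)
})

test_that("fold change identity, ratio, and scale invariance", {
  expect_equal(fold_change(120, 120), 1)
  expect_equal(fold_change(55, 440), 8)
  expect_equal(fold_change(-55, -440), 8)        # inward tails, same polarity
  set.seed(6)
  for (rep in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); s <- runif(1, 0.1, 10)
    expect_equal(fold_change(a * s, b * s), fold_change(a, b),
                 tolerance = 1e-12)
  }
  expect_error(fold_change(0, 5), "zero")
})

test_that("spearman: trivial cases, exhaustive-permutation equality at n = 6, invariances", {
  sp <- spearman_rank(1:7, c(0.1, 0.5, 0.6, 2, 3, 10, 50))
  expect_equal(sp$r_s, 1)
  set.seed(19)
  for (rep in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    sp <- spearman_rank(x, y)
    # independent brute-force oracle over all 720 rank permutations
    rx <- rank(x); ry <- rank(y)
    r_obs <- cor(rx, ry)
    idx <- expand.grid(rep(list(1:6), 6))
    idx <- idx[apply(idx, 1, function(p) length(unique(p)) == 6), ]
    r_all <- apply(idx, 1, function(p) cor(rx[as.integer(p)], ry))
    expect_equal(sp$r_s, r_obs, tolerance = 1e-12)
    expect_equal(sp$p, mean(abs(r_all) >= abs(r_obs) - 1e-12),
                 tolerance = 1e-12)
    # and against the standard library's exact test (tie-free data)
    ct <- cor.test(x, y, method = "spearman")
    expect_equal(sp$r_s, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(sp$p, ct$p.value, tolerance = 1e-9)
  }
  # monotone transform of x leaves r_s unchanged; reversing order flips sign
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(spearman_rank(exp(x), y)$r_s, spearman_rank(x, y)$r_s)
  expect_equal(spearman_rank(-x, y)$r_s, -spearman_rank(x, y)$r_s)
  expect_true(abs(spearman_rank(x, y)$r_s) <= 1)
  expect_warning(spearman_rank(rep(1, 5), 1:5), "constant")
})

test_that("amplitude histogram: exact noiseless peak and blank degeneracy", {
  x <- rep(c(0, 0.05), each = 5000)
  h <- amplitude_histogram(x, bin_width = 0.01)
  expect_equal(h$open_peak, 0.05, tolerance = 1e-6)
  expect_equal(h$bin_width, 0.01)
  # blank sweep: single component near 0, no open peak
  set.seed(23)
  blank <- rnorm(20000, 0, 0.015)
  hb <- amplitude_histogram(blank, bin_width = 0.01)
  expect_true(is.na(hb$open_peak))
  expect_match(hb$flag, "degenerate")
  expect_equal(hb$components$mean[1], 0, tolerance = 0.005)
})

test_that("drug response table: decreasing cohort gives r_s = -1; mechanism gives r_s < -0.7", {
  tb <- tibble::tibble(construct = paste0("c", 1:6),
                       fraction = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0),
                       fold = c(9, 7, 4, 2.5, 1.4, 1.0))
  dr <- drug_response_table(tb)
  expect_equal(dr$correlation$r_s, -1)
  expect_error(drug_response_table(tb[1:2, ]), ">= 3")
  # mechanism cohort: fold ~ 1/fraction + noise
  set.seed(31)
  fr <- runif(12, 0.15, 1)
  tb2 <- tibble::tibble(construct = paste0("m", 1:12), fraction = fr,
                        fold = 1 / fr * exp(rnorm(12, 0, 0.15)))
  expect_lt(drug_response_table(tb2)$correlation$r_s, -0.7)
})

test_that("end-to-end synthetic cohort recovers fractions and the correlation class", {
  co <- simulate_cohort(n_constructs = 10, seed = 1)
  expect_equal(nrow(co), 10)
  expect_true(all(abs(co$fraction - co$fraction_true) < 0.05))
  expect_false(co$hook[co$inact_factor == 0])
  expect_identical(co$fraction[co$inact_factor == 0], 1)
  dr <- drug_response_table(co)
  expect_lt(dr$correlation$r_s, -0.7)
  # seed changes only the stochastic measurement noise, not the mechanism
  co2 <- simulate_cohort(n_constructs = 10, seed = 2)
  expect_equal(co2$fraction_true, co$fraction_true, tolerance = 1e-12)
  expect_false(identical(co2$fold, co$fold))
})
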