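#' Simulate a synthetic mutant cohort for the drug-response analysis
#'
#' Builds a family of constructs from a base gating model by scaling the
#' inactivation on-rate (factor 0 = non-inactivating construct), then for
#' each construct simulates (i) a control tail at -120 mV to measure the
#' non-inactivated fraction by back-extrapolation, and (ii) control and
#' activator tails at -40 mV to measure the fold change.  Because the
#' activator acts chiefly by removing inactivation, constructs that
#' inactivate more (smaller fraction) respond more (larger fold), so the
#' cohort's Spearman correlation between fraction and fold change is
#' strongly negative.
#'
#' @param n_constructs Number of constructs (>= 3).
#' @param seed Seed for the measurement-noise generator.
#' @param base Base [gating_model()].
#' @param modifier [modifier_set()] emulating the activator.
#' @param inact_factors Per-construct factors on the inactivation on-rate
#'   (default: evenly spaced 0 to 2.5).
#' @param noise Lognormal SD of multiplicative measurement noise on tail
#'   amplitudes (0 = noiseless).
#' @param rate Sampling rate for the deterministic solver (Hz).
#' @param step_s Depolarizing step duration (s).
#' @return Tibble: construct, inact_factor, fraction (measured),
#'   fraction_true (model open/(open+inactivated) at the end of the step),
#'   tail_control, tail_drug, fold, hook.
#' @export
simulate_cohort <- function(n_constructs = 10, seed = 1,
                            base = builtin_model("wt"),
                            modifier = activator_modifier(),
                            inact_factors = NULL, noise = 0.03,
                            rate = 2000, step_s = 4) {
  if (n_constructs < 3) abort("need >= 3 constructs")
  if (is.null(inact_factors))
    inact_factors <- seq(0, 2.5, length.out = n_constructs)
  set.seed(seed)
  hook_protocol <- activation_protocol(tail_mV = -120, step_s = step_s,
                                       rate = rate, hold_s = 0.05)
  tail_protocol <- activation_protocol(tail_mV = -40, step_s = step_s,
                                       rate = rate, hold_s = 0.05)
  t0 <- 0.05 + step_s
  rows <- vector("list", n_constructs)
  for (i in seq_len(n_constructs)) {
    f <- inact_factors[i]
    m <- if ("inactivation_on" %in% base$edges$role)
      apply_modifier(base, modifier_set(c(inactivation_on = f)))
    else base
    m$id <- sprintf("construct_%02d", i)
    ctrl_hook <- simulate_macroscopic(m, hook_protocol)
    ta <- analyze_tail(ctrl_hook, t0 = t0)
    end_step <- dplyr::slice_tail(filter(ctrl_hook, .data$time_s < t0), n = 1)
    frac_true <- if ("I" %in% names(end_step))
      end_step$O / (end_step$O + end_step$I) else 1
    drug_mod <- modifier
    drug_mod$factors <- drug_mod$factors[names(drug_mod$factors) %in%
                                           m$edges$role]
    ctrl <- simulate_macroscopic(m, tail_protocol)
    drug <- simulate_macroscopic(apply_modifier(m, drug_mod), tail_protocol)
    tc <- tail_peak(ctrl, t0) * exp(rnorm(1, 0, noise))
    td <- tail_peak(drug, t0) * exp(rnorm(1, 0, noise))
    rows[[i]] <- tibble(construct = m$id, inact_factor = f,
                        fraction = ta$non_inactivated_fraction,
                        fraction_true = frac_true,
                        tail_control = tc, tail_drug = td,
                        fold = fold_change(tc, td), hook = ta$hook)
  }
  out <- bind_rows(rows)
  attr(out, "seed") <- seed
  out
}
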