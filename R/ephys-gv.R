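#' Normalized conductance-voltage points from tail-current peaks
#'
#' Tail amplitudes measured immediately upon repolarization are
#' proportional to the open probability at the end of the step, so
#' normalizing each cell's tails to its own maximum yields G/G_max.
#'
#' @param tails Data frame with columns `voltage_mV` and `tail_pA` (one row
#'   per step voltage; magnitudes are used).
#' @return Tibble: voltage_mV, g (normalized to the per-cell maximum).
#' @export
gv_curve <- function(tails) {
  tb <- as_tibble(tails)
  stopifnot(all(c("voltage_mV", "tail_pA") %in% names(tb)))
  if (nrow(tb) < 4) abort("need >= 4 voltages for a G-V curve")
  amp <- abs(tb$tail_pA)
  if (max(amp) == 0) abort("zero maximum tail amplitude")
  tibble(voltage_mV = tb$voltage_mV, g = amp / max(amp)) |>
    arrange(.data$voltage_mV)
}

#' Boltzmann sigmoid fit of a G-V curve
#'
#' Least-squares fit of G(V) = G_max / (1 + exp((V_half - V) / k)) by
#' Gauss-Newton (`nls`) from a deterministic logistic-linearization start,
#' with a Nelder-Mead fallback.  By construction the fitted curve passes
#' through G_max / 2 at V_half.
#'
#' @param gv Tibble from [gv_curve()] (columns voltage_mV, g).
#' @return A `boltzmann_fit`: coefficients `v_half` (mV), `k` (mV, > 0),
#'   `g_max`; standard errors where available; residual norm.
#' @export
fit_boltzmann <- function(gv) {
  tb <- as_tibble(gv)
  stopifnot(all(c("voltage_mV", "g") %in% names(tb)))
  if (nrow(tb) < 4) abort("need >= 4 points to fit a Boltzmann")
  V <- tb$voltage_mV; G <- tb$g
  gmax0 <- max(G)
  # logistic linearization on interior points for the start values
  frac <- pmin(pmax(G / (gmax0 * 1.001), 1e-6), 1 - 1e-6)
  lg <- log(frac / (1 - frac))
  cf <- stats::lm.fit(cbind(1, V), lg)$coefficients
  k0 <- if (is.finite(cf[2]) && cf[2] > 0) 1 / cf[2] else 10
  v0 <- if (is.finite(cf[1])) -cf[1] * k0 else stats::median(V)
  fit <- tryCatch(
    stats::nls(g ~ g_max / (1 + exp((v_half - voltage_mV) / k)),
               data = tb,
               start = list(g_max = gmax0, v_half = v0, k = k0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- summary(fit)$coefficients
    est <- co[, "Estimate"]; se <- co[, "Std. Error"]
    rss <- sum(stats::residuals(fit)^2)
  } else {
    obj <- function(p) sum((G - p[1] / (1 + exp((p[2] - V) / p[3])))^2)
    op <- optim(c(gmax0, v0, k0), obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    est <- setNames(op$par, c("g_max", "v_half", "k"))
    se <- setNames(rep(NA_real_, 3), names(est))
    rss <- op$value
  }
  if (est["k"] <= 0) abort("Boltzmann fit pinned at non-positive slope")
  flag <- if (est["k"] < 0.1 || est["k"] > 100) "slope at bound" else ""
  out <- list(v_half = unname(est["v_half"]), k = unname(est["k"]),
              g_max = unname(est["g_max"]),
              se = c(v_half = unname(se["v_half"]), k = unname(se["k"]),
                     g_max = unname(se["g_max"])),
              rss = rss, n = nrow(tb), flag = flag, data = tb)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit: V1/2 = %.2f mV, k = %.2f mV, Gmax = %.3f>\n",
              x$v_half, x$k, x$g_max))
  invisible(x)
}

#' Predict from a Boltzmann fit
#' @param object A `boltzmann_fit`.
#' @param voltage_mV Voltages (mV).
#' @param ... Unused.
#' @return Predicted normalized conductance.
#' @export
predict.boltzmann_fit <- function(object, voltage_mV, ...) {
  object$g_max / (1 + exp((object$v_half - voltage_mV) / object$k))
}

#' Tidy a Boltzmann fit
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One row per parameter: term, estimate, std.error.
#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble(term = c("v_half", "k", "g_max"),
         estimate = c(x$v_half, x$k, x$g_max),
         std.error = unname(x$se[c("v_half", "k", "g_max")]))
}

#' Glance at a Boltzmann fit
#' @param x A `boltzmann_fit`.
#' @param ... Unused.
#' @return One-row tibble: rss, n, flag.
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, flag = x$flag)
}

#' Simulate a conductance-voltage experiment
#'
#' Runs the activation protocol at each step voltage, measures the peak
#' tail amplitude immediately after repolarization, and assembles the
#' normalized G-V.
#'
#' @param model A [gating_model()].
#' @param voltages Step voltages (mV).
#' @param tail_mV Tail voltage (mV).
#' @param step_s Step duration (s).
#' @param rate Sampling rate (Hz); modest rates are fine for the
#'   deterministic solver.
#' @return Tibble: voltage_mV, tail_pA, g.
#' @export
simulate_gv <- function(model, voltages = seq(-80, 60, by = 20),
                        tail_mV = -40, step_s = 2, rate = 1000) {
  tails <- vapply(voltages, function(v) {
    pr <- activation_protocol(step_mV = v, tail_mV = tail_mV,
                              step_s = step_s, tail_s = 0.5, hold_s = 0.05,
                              rate = rate)
    tr <- simulate_macroscopic(model, pr)
    tail_peak(tr, t0 = 0.05 + step_s)
  }, numeric(1))
  tibble(voltage_mV = voltages, tail_pA = tails,
         g = abs(tails) / max(abs(tails)))
}

#' Tail amplitude after repolarization
#'
#' `"initial"` (default) is the current immediately upon repolarization --
#' the conductance-voltage convention -- while `"max"` is the largest
#' amplitude anywhere in the window (the hook peak for hooked tails).
#'
#' @param trace A `chan_trace`.
#' @param t0 Repolarization time (s).
#' @param window Search window (s; default to trace end).
#' @param mode `"initial"` or `"max"`.
#' @return Tail amplitude in pA (signed as recorded).
#' @export
tail_peak <- function(trace, t0, window = NULL, mode = c("initial", "max")) {
  mode <- match.arg(mode)
  tb <- as_tibble(trace)
  t_end <- if (is.null(window)) max(tb$time_s) else t0 + window
  seg <- filter(tb, .data$time_s >= t0, .data$time_s <= t_end)
  if (nrow(seg) == 0) abort("no samples in tail window")
  if (mode == "initial") seg$current_pA[1]
  else seg$current_pA[which.max(abs(seg$current_pA))]
}
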