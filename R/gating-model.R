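#' Voltage-dependent Markov gating model
#'
#' States connected by edges with rates k(V) = k0 * exp(z * (V - shift) /
#' 25.7 mV) (25.7 mV is RT/F at 25 C).  Each edge carries a `role` label
#' (`"activation_f"`, `"activation_b"`, `"opening"`, `"deactivation"`,
#' `"inactivation_on"`, `"inactivation_off"`, ...) which activator
#' modifiers address by name.
#'
#' @param states Character vector of state names; exactly one must be
#'   `"O"` (open).
#' @param edges Data frame with columns `from`, `to`, `k0` (1/s, > 0),
#'   `z` (dimensionless valence) and `role`.
#' @param g Unitary conductance in pS.
#' @param e_rev Reversal potential in mV.
#' @param n_channels Channel count for macroscopic currents.
#' @param shift Activation shift in mV applied inside the exponential of
#'   shifted roles (see [apply_modifier()]).
#' @param id Model label.
#' @return A `gating_model` object.
#' @export
gating_model <- function(states, edges, g = 0.5, e_rev = -85,
                         n_channels = 3000, shift = 0, id = "model") {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "k0", "z", "role") %in% names(edges)))
  if (any(edges$k0 <= 0)) abort("all k0 must be > 0")
  if (sum(states == "O") != 1) abort("exactly one open state 'O' required")
  if (!all(c(edges$from, edges$to) %in% states))
    abort("edge endpoints must be model states")
  structure(list(states = states, edges = edges, g = g, e_rev = e_rev,
                 n_channels = n_channels, shift = shift, id = id),
            class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf("<gating_model '%s': %d states (%s), %d edges, g=%.2g pS, E=%g mV, N=%d>\n",
              x$id, length(x$states), paste(x$states, collapse = ","),
              nrow(x$edges), x$g, x$e_rev, x$n_channels))
  invisible(x)
}

THERMAL_MV <- 25.7  # RT/F at 25 C, mV

# edge rates at voltage V (mV); the activation shift moves the voltage
# axis of voltage-dependent activation/deactivation edges.
edge_rates <- function(model, V) {
  e <- model$edges
  shifted <- e$role %in% c("activation_f", "activation_b", "opening",
                           "deactivation")
  Veff <- ifelse(shifted, V - model$shift, V)
  e$k0 * exp(e$z * Veff / THERMAL_MV)
}

# generator matrix Q (rows = from): dP/dt = P Q with row sums 0
generator_matrix <- function(model, V) {
  n <- length(model$states)
  Q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  k <- edge_rates(model, V)
  for (i in seq_len(nrow(model$edges))) {
    Q[model$edges$from[i], model$edges$to[i]] <-
      Q[model$edges$from[i], model$edges$to[i]] + k[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

stationary_distribution <- function(model, V) {
  Q <- generator_matrix(model, V)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  setNames(pmax(p, 0) / sum(pmax(p, 0)), model$states)
}

#' Voltage protocol
#'
#' @param segments Data frame with columns `duration` (s) and `voltage`
#'   (mV), applied in order.
#' @param rate Sampling rate in Hz.
#' @return A `voltage_protocol` object.
#' @export
voltage_protocol <- function(segments, rate = 5000) {
  segments <- as_tibble(segments)
  stopifnot(all(c("duration", "voltage") %in% names(segments)))
  if (any(segments$duration <= 0) || rate <= 0)
    abort("durations and sampling rate must be > 0")
  structure(list(segments = segments, rate = rate),
            class = "voltage_protocol")
}

#' Activation/tail protocol (hold, depolarizing step, repolarizing tail)
#'
#' Default mirrors the drug-response protocol: hold at -90 mV, pulse to
#' +60 mV for 4 s, tail for 0.9 s (at -40 mV for conductance-voltage
#' measurements, or -120 mV to expose the inactivation hook).
#'
#' @param step_mV Step voltage (mV).
#' @param tail_mV Tail voltage (mV).
#' @param hold_mV Holding voltage (mV).
#' @param step_s,tail_s,hold_s Durations (s).
#' @param rate Sampling rate (Hz).
#' @return A [voltage_protocol()].
#' @export
activation_protocol <- function(step_mV = 60, tail_mV = -40, hold_mV = -90,
                                step_s = 4, tail_s = 0.9, hold_s = 0.1,
                                rate = 5000) {
  voltage_protocol(tibble(duration = c(hold_s, step_s, tail_s),
                          voltage = c(hold_mV, step_mV, tail_mV)),
                   rate = rate)
}

#' Voltage trace of a protocol
#' @param protocol A [voltage_protocol()].
#' @return Tibble: time_s, voltage_mV, segment.
#' @export
protocol_trace <- function(protocol) {
  segs <- protocol$segments
  dt <- 1 / protocol$rate
  out <- list()
  t0 <- 0
  for (i in seq_len(nrow(segs))) {
    tt <- seq(0, segs$duration[i] - dt / 2, by = dt)
    out[[i]] <- tibble(time_s = t0 + tt, voltage_mV = segs$voltage[i],
                       segment = i)
    t0 <- t0 + segs$duration[i]
  }
  bind_rows(out)
}

#' Activator/modifier set for a gating model
#'
#' Multiplicative factors on rates addressed by role name (0 removes the
#' rate's effect) plus an activation shift in mV.  The canonical activator
#' phenotype is `factors = c(inactivation_on = 0), slows deactivation and
#' shifts activation negative`.
#'
#' @param factors Named numeric vector of multiplicative factors (>= 0) on
#'   edge roles.
#' @param shift_mV Activation shift (mV; negative = hyperpolarizing).
#' @return A `modifier_set`.
#' @export
modifier_set <- function(factors = numeric(), shift_mV = 0) {
  if (length(factors) && (is.null(names(factors)) || any(factors < 0)))
    abort("factors must be a named, non-negative vector")
  structure(list(factors = factors, shift_mV = shift_mV),
            class = "modifier_set")
}

#' Activator modifier emulating the drug phenotype
#'
#' Removes fast inactivation, slows deactivation and shifts activation to
#' hyperpolarized voltages -- the three hallmarks of the activator's action
#' on wild-type channels.
#'
#' @param inact_factor Factor on `inactivation_on` (0 = eliminated).
#' @param deact_factor Factor on `deactivation` (< 1 = slower tails).
#' @param shift_mV Activation shift (mV).
#' @return A [modifier_set()].
#' @export
activator_modifier <- function(inact_factor = 0, deact_factor = 0.25,
                               shift_mV = -25) {
  modifier_set(c(inactivation_on = inact_factor,
                 deactivation = deact_factor), shift_mV = shift_mV)
}

#' Apply a modifier to a gating model
#'
#' Returns a new model with scaled rates and shifted activation midpoint;
#' the input model is untouched.  Edges whose rate factor is 0 are removed
#' from the scheme.  Unknown role names are an error.
#'
#' @param model A [gating_model()].
#' @param modifier A [modifier_set()].
#' @return A new `gating_model`.
#' @export
apply_modifier <- function(model, modifier) {
  stopifnot(inherits(model, "gating_model"), inherits(modifier, "modifier_set"))
  e <- model$edges
  for (nm in names(modifier$factors)) {
    hit <- e$role == nm
    if (!any(hit)) abort(paste0("model has no edges with role '", nm, "'"))
    e$k0[hit] <- e$k0[hit] * modifier$factors[[nm]]
  }
  e <- filter(e, .data$k0 > 0)
  out <- model
  out$edges <- e
  out$shift <- model$shift + modifier$shift_mV
  out$id <- paste0(model$id, "+mod")
  out
}

#' Built-in gating parameter sets
#'
#' Shipped fixture models for a four-state C1-C2-O-I scheme (the smallest
#' scheme producing hooked tail currents): `"wt"` sits about 70%
#' inactivated at the end of a long +60 mV step and shows a recovery hook
#' at -120 mV; `"s338a"` inactivates more deeply and deactivates more
#' slowly; `"noninact"` lacks the inactivated state entirely; `"stable_open"`
#' is a slow two-state C-O model used for single-channel fixtures.  These
#' are calibration choices of this package, not measured values.
#'
#' @param name One of `"wt"`, `"s338a"`, `"noninact"`, `"stable_open"`,
#'   `"two_state"`.
#' @param ... Overrides passed to [gating_model()] (`g`, `e_rev`,
#'   `n_channels`).
#' @return A [gating_model()].
#' @export
builtin_model <- function(name = c("wt", "s338a", "noninact", "stable_open",
                                   "two_state"), ...) {
  name <- match.arg(name)
  base_edges <- tibble(
    from = c("C1", "C2", "C2", "O", "O", "I"),
    to   = c("C2", "C1", "O", "C2", "I", "O"),
    k0   = c(2.0, 0.5, 5.0, 1.0, 0.55, 2.0),
    z    = c(1.2, -1.2, 0.4, -0.4, 0.10, -0.85),
    role = c("activation_f", "activation_b", "opening", "deactivation",
             "inactivation_on", "inactivation_off"))
  switch(name,
    wt = gating_model(c("C1", "C2", "O", "I"), base_edges, id = "wt", ...),
    s338a = {
      e <- base_edges
      e$k0[e$role == "inactivation_on"] <- e$k0[e$role == "inactivation_on"] * 2.5
      e$k0[e$role == "deactivation"] <- e$k0[e$role == "deactivation"] * 0.5
      gating_model(c("C1", "C2", "O", "I"), e, id = "s338a", ...)
    },
    noninact = {
      e <- filter(base_edges, !.data$role %in% c("inactivation_on",
                                                 "inactivation_off"))
      gating_model(c("C1", "C2", "O"), e, id = "noninact", ...)
    },
    stable_open = gating_model(
      c("C", "O"),
      tibble(from = c("C", "O"), to = c("O", "C"), k0 = c(20, 15),
             z = c(0.2, -0.2), role = c("opening", "deactivation")),
      id = "stable_open", ...),
    two_state = gating_model(
      c("C", "O"),
      tibble(from = c("C", "O"), to = c("O", "C"), k0 = c(50, 30),
             z = c(0.5, -0.5), role = c("opening", "deactivation")),
      id = "two_state", ...))
}
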