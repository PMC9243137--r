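#' Deterministic macroscopic current from the master equation
#'
#' Within each protocol segment the voltage is constant, so occupancies are
#' propagated exactly by one matrix exponential per sampling step:
#' P(t + dt) = P(t) expm(Q dt).  Current is I(t) = N g P_open(t)
#' (V - E_rev); units pA with g in pS and V in mV.
#'
#' @param model A [gating_model()].
#' @param protocol A [voltage_protocol()].
#' @param p0 Initial occupancy (default: stationary at the first segment's
#'   voltage).
#' @return A `chan_trace` tibble: time_s, current_pA, voltage_mV, plus the
#'   state occupancies as columns; probability is conserved to 1e-10.
#' @export
simulate_macroscopic <- function(model, protocol, p0 = NULL) {
  stopifnot(inherits(model, "gating_model"),
            inherits(protocol, "voltage_protocol"))
  segs <- protocol$segments
  dt <- 1 / protocol$rate
  p <- if (is.null(p0)) stationary_distribution(model, segs$voltage[1])
       else setNames(as.numeric(p0), model$states)
  out <- vector("list", nrow(segs))
  t0 <- 0
  for (s in seq_len(nrow(segs))) {
    V <- segs$voltage[s]
    Q <- generator_matrix(model, V)
    Tdt <- as.matrix(Matrix::expm(Q * dt))
    nstep <- max(1L, round(segs$duration[s] / dt))
    P <- matrix(NA_real_, nstep, length(model$states),
                dimnames = list(NULL, model$states))
    for (k in seq_len(nstep)) {
      P[k, ] <- p             # occupancy at segment-local time (k-1)*dt
      p <- as.numeric(p %*% Tdt)
    }
    drift <- max(abs(rowSums(P) - 1))
    if (drift > 1e-10) abort(sprintf(
      "probability conservation violated (|sum P - 1| = %.2e); non-conservative rate matrix?",
      drift))
    tt <- t0 + (seq_len(nstep) - 1) * dt
    seg_tb <- as_tibble(P)
    seg_tb$time_s <- tt
    seg_tb$voltage_mV <- V
    out[[s]] <- seg_tb
    t0 <- t0 + nstep * dt
  }
  tb <- bind_rows(out)
  # pS * mV = fA; 1e-3 converts to pA
  tb$current_pA <- model$n_channels * model$g * 1e-3 * tb$O *
    (tb$voltage_mV - model$e_rev)
  new_trace(tb[, c("time_s", "current_pA", "voltage_mV", model$states)],
            model = model$id, kind = "macroscopic", rate = protocol$rate)
}

new_trace <- function(tb, model, kind, rate, seed = NULL) {
  structure(as_tibble(tb), class = c("chan_trace", class(tibble())),
            model = model, kind = kind, rate = rate, seed = seed)
}

#' @export
print.chan_trace <- function(x, ...) {
  cat(sprintf("# %s current trace (model '%s'): %d samples at %g Hz\n",
              attr(x, "kind"), attr(x, "model"), nrow(x), attr(x, "rate")))
  NextMethod()
}

#' Stochastic single-channel simulation (exact, event-driven)
#'
#' Gillespie simulation of `n_channels` independent channels through the
#' protocol, sampled onto the protocol's time grid; unitary current
#' g (V - E_rev), optional additive Gaussian noise, and an optional
#' low-pass filter (cascade of four one-pole sections approximating a
#' 4-pole Bessel response).  Bit-reproducible for a given seed.
#'
#' @param model A [gating_model()].
#' @param protocol A [voltage_protocol()].
#' @param n_channels Number of channels in the patch.
#' @param noise_sd Gaussian noise SD in pA, added before filtering.
#' @param filter_cutoff -3 dB cutoff in Hz (`Inf` = unfiltered).
#' @param seed Mandatory RNG seed.
#' @param p0 Initial occupancy (default stationary at the holding voltage).
#' @return A `chan_trace` tibble: time_s, current_pA, voltage_mV, n_open.
#' @export
simulate_single_channel <- function(model, protocol, n_channels = 1,
                                    noise_sd = 0.05, filter_cutoff = 200,
                                    seed, p0 = NULL) {
  if (missing(seed)) abort("seed is mandatory for stochastic simulation")
  stopifnot(n_channels >= 1)
  withr_seed <- .Random.seed_exists()
  old <- if (withr_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (withr_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  segs <- protocol$segments
  dt <- 1 / protocol$rate
  pstart <- if (is.null(p0)) stationary_distribution(model, segs$voltage[1])
            else setNames(as.numeric(p0), model$states)
  n_states <- length(model$states)
  open_idx <- which(model$states == "O")
  total <- sum(round(segs$duration / dt))
  n_open <- integer(total)
  volt <- numeric(total)
  pos <- 0L
  # per-channel trajectories
  states0 <- sample.int(n_states, n_channels, replace = TRUE, prob = pstart)
  from <- match(model$edges$from, model$states)
  to <- match(model$edges$to, model$states)
  seg_rates <- lapply(segs$voltage, function(V) edge_rates(model, V))
  edges_by_state <- lapply(seq_len(n_states), function(s) which(from == s))
  for (ch in seq_len(n_channels)) {
    st <- states0[ch]
    pos <- 0L
    for (s in seq_len(nrow(segs))) {
      V <- segs$voltage[s]
      k <- seg_rates[[s]]
      nstep <- round(segs$duration[s] / dt)
      t_seg <- nstep * dt
      t <- 0
      grid_t <- (seq_len(nstep) - 1) * dt
      fill_from <- 1L
      repeat {
        out_edges <- edges_by_state[[st]]
        ktot <- sum(k[out_edges])
        t_next <- if (ktot > 0) t + stats::rexp(1, ktot) else Inf
        upto <- if (t_next >= t_seg) nstep else sum(grid_t < t_next)
        if (upto >= fill_from) {
          sel <- pos + (fill_from:upto)
          if (st == open_idx) n_open[sel] <- n_open[sel] + 1L
          if (ch == 1) volt[sel] <- V
          fill_from <- upto + 1L
        }
        if (t_next >= t_seg) break
        t <- t_next
        st <- to[out_edges[sample.int(length(out_edges), 1,
                                      prob = k[out_edges])]]
      }
      pos <- pos + nstep
    }
  }
  tt <- (seq_len(total) - 1) * dt
  i_unit <- model$g * 1e-3 * (volt - model$e_rev)   # pA per open channel
  current <- n_open * i_unit
  if (noise_sd > 0) current <- current + rnorm(total, 0, noise_sd)
  if (is.finite(filter_cutoff))
    current <- bessel_lowpass(current, filter_cutoff, protocol$rate)
  new_trace(tibble(time_s = tt, current_pA = current, voltage_mV = volt,
                   n_open = n_open),
            model = model$id, kind = "single_channel", rate = protocol$rate,
            seed = seed)
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

#' Low-pass filter approximating a 4-pole Bessel response
#'
#' Implemented as four cascaded identical one-pole IIR sections; the
#' per-section cutoff is scaled so the cascade's -3 dB point sits at
#' `cutoff`.
#'
#' @param x Numeric signal.
#' @param cutoff -3 dB cutoff (Hz).
#' @param rate Sampling rate (Hz).
#' @return Filtered signal.
#' @export
bessel_lowpass <- function(x, cutoff, rate) {
  if (!is.finite(cutoff) || cutoff >= rate / 2) return(x)
  m <- 4
  fc1 <- cutoff / sqrt(2^(1 / m) - 1)
  a <- exp(-2 * pi * fc1 / rate)
  for (k in seq_len(m)) x <- stats::filter(x * (1 - a), a, method = "recursive")
  as.numeric(x)
}

#' Write / read a trace as TSV with a JSON metadata sidecar
#'
#' @param trace A `chan_trace`.
#' @param path Output TSV path (`<path>.json` holds the metadata).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as_tibble(trace)[, c("time_s", "current_pA")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(model = attr(trace, "model"), kind = attr(trace, "kind"),
               rate = attr(trace, "rate"), seed = attr(trace, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tb <- as_tibble(utils::read.delim(path, sep = "\t"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(model = "unknown", kind = "unknown", rate = NA)
  rate <- meta$rate %||% 1 / stats::median(diff(tb$time_s))
  new_trace(tb, model = meta$model %||% "unknown",
            kind = meta$kind %||% "unknown", rate = rate,
            seed = meta$seed)
}
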