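#' Tail-current fold change
#'
#' Drug tail amplitude divided by the initial control tail amplitude.
#' Magnitude ratio, carrying a negative sign only when the two tails have
#' opposite polarity.
#'
#' @param tail_control,tail_drug Tail amplitudes (pA).
#' @return Dimensionless ratio.
#' @export
fold_change <- function(tail_control, tail_drug) {
  if (any(tail_control == 0)) abort("zero control tail amplitude")
  sign(tail_drug * tail_control) * abs(tail_drug) / abs(tail_control)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Ranks use average ranks for ties.  For n <= 9 the two-sided p-value is
#' computed by exhaustive enumeration of all n! rank permutations; for
#' larger n the t-distribution approximation is used.
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param exact_max Largest n for exhaustive enumeration.
#' @return List: `r_s`, `p`, `n`, `method`; `r_s` is `NA` (with a warning)
#'   when either vector is constant.
#' @export
spearman_rank <- function(x, y, exact_max = 9) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman correlation undefined")
    return(list(r_s = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  r_obs <- cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # correlation is linear in the permuted ranks: precompute moments
    mrx <- mean(rx); sdx <- sd(rx)
    ry_s <- ry; mry <- mean(ry); sdy <- sd(ry)
    # sum(rx[perm] * ry) for every permutation; correlation is affine in it
    rs_all <- apply(perms, 1, function(p) sum(rx[p] * ry_s))
    r_all <- (rs_all / n - mrx * mry) / (sdx * sdy) * n / (n - 1)
    p <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- r_obs * sqrt((n - 2) / (1 - r_obs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(r_s = r_obs, p = p, n = n, method = method)
}

# all permutations of 1..n as an (n! x n) matrix, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- row:(row + nrow(sub) - 1)
    out[idx, 1] <- first
    out[idx, -1] <- matrix(rest[sub], nrow(sub), n - 1)
    row <- row + nrow(sub)
  }
  out
}

#' All-points amplitude histogram with a Gaussian mixture fit
#'
#' Every sample of a (filtered) single-channel record is binned at
#' `bin_width` (default 0.01 pA) and a 1- or 2-component Gaussian mixture
#' is fitted to the raw samples by EM with a deterministic initialization
#' (baseline component at the sample mode, open component at the 90th
#' percentile).  The open-level peak is the mean of the non-baseline
#' component; if the components merge the result is flagged and collapsed
#' to a single component (as for a blank sweep).
#'
#' @param trace A `chan_trace` or numeric vector of current samples (pA).
#' @param bin_width Histogram bin width (pA).
#' @param n_components 1 or 2.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An `amplitude_histogram`: `bins` (tibble: mid, count),
#'   `components` (tibble: mean, sd, weight), `open_peak` (pA or `NA`),
#'   `flag`.
#' @export
amplitude_histogram <- function(trace, bin_width = 0.01, n_components = 2,
                                max_iter = 200, tol = 1e-8) {
  stopifnot(n_components %in% c(1, 2), bin_width > 0)
  xs <- if (is.numeric(trace)) trace else as_tibble(trace)$current_pA
  xs <- xs[is.finite(xs)]
  edges <- seq(floor(min(xs) / bin_width) * bin_width,
               max(xs) + bin_width, by = bin_width)
  h <- graphics::hist(xs, breaks = edges, plot = FALSE)
  bins <- tibble(mid = h$mids, count = h$counts)
  mode_x <- h$mids[which.max(h$counts)]
  flag <- ""
  if (n_components == 1 || sd(xs) == 0) {
    comps <- tibble(mean = mean(xs), sd = max(sd(xs), bin_width / 10),
                    weight = 1)
    open_peak <- NA_real_
    if (n_components == 2) flag <- "degenerate: single component"
  } else {
    mu <- c(mode_x, quantile(xs, 0.9, names = FALSE))
    sg <- rep(max(sd(xs) / 2, bin_width / 4), 2)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(xs, mu[1], sg[1])
      d2 <- w[2] * dnorm(xs, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g1 <- d1 / tot
      ll <- sum(log(tot))
      w <- c(mean(g1), mean(1 - g1))
      mu <- c(sum(g1 * xs) / sum(g1), sum((1 - g1) * xs) / sum(1 - g1))
      sg <- sqrt(c(sum(g1 * (xs - mu[1])^2) / sum(g1),
                   sum((1 - g1) * (xs - mu[2])^2) / sum(1 - g1)))
      sg <- pmax(sg, bin_width / 10)
      if (is.finite(ll) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (abs(mu[1] - mu[2]) < max(bin_width / 2, 2 * min(sg)) ||
        any(w < 1e-4)) {
      flag <- "degenerate: components merged"
      comps <- tibble(mean = mean(xs), sd = sd(xs), weight = 1)
      open_peak <- NA_real_
    } else {
      baseline <- which.min(abs(mu))   # zero-pA baseline convention
      open <- 3 - baseline
      comps <- tibble(mean = mu, sd = sg, weight = w)[c(baseline, open), ]
      comps$role <- c("baseline", "open")
      open_peak <- mu[open]
    }
  }
  out <- list(bins = bins, components = comps, open_peak = open_peak,
              bin_width = bin_width, flag = flag, n = length(xs))
  class(out) <- "amplitude_histogram"
  out
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf("<amplitude_histogram: %d samples, %d component(s)%s>\n",
              x$n, nrow(x$components),
              if (is.na(x$open_peak)) "" else
                sprintf(", open peak %.3f pA", x$open_peak)))
  invisible(x)
}

#' Assemble a per-construct drug-response table with its rank correlation
#'
#' Combines per-construct tail fold-changes (drug over control) with the
#' control non-inactivated fraction and reports the Spearman correlation
#' between the two.  The published display uses a log ordinate for the
#' fold change; ranks are unaffected, so the correlation is computed on
#' the raw values.
#'
#' @param constructs Data frame with columns `construct`, `fraction`
#'   (control non-inactivated fraction), `fold` (tail fold-change), and
#'   optionally `v_half_control`, `v_half_drug`.
#' @return A `drug_response` list: `table` (tibble) and `correlation`
#'   (from [spearman_rank()] on fraction vs fold).
#' @export
drug_response_table <- function(constructs) {
  tb <- as_tibble(constructs)
  stopifnot(all(c("construct", "fraction", "fold") %in% names(tb)))
  if (nrow(tb) < 3) abort("need >= 3 constructs")
  if (any(tb$fold <= 0)) abort("fold changes must be positive")
  cor <- spearman_rank(tb$fraction, tb$fold)
  structure(list(table = tb, correlation = cor), class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("<drug_response: %d constructs, r_s = %.3f (p = %.2g, %s)>\n",
              nrow(x$table), x$correlation$r_s, x$correlation$p,
              x$correlation$method))
  invisible(x)
}
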