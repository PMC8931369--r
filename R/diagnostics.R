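# MCMC convergence diagnostics: Gelman's potential scale reduction and
# autocorrelation-based effective sample size.

#' Gelman's R-hat (potential scale reduction factor)
#'
#' Classic between/within-chain variance ratio: with m chains of length n,
#' `R-hat = sqrt((((n-1)/n) W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B/n` the variance of the chain means. Values
#' near 1 indicate the chains sample the same distribution.
#'
#' @param chains a `posterior_chains` object or a list of >= 2 numeric
#'   traces of equal length.
#' @param parameter trace name (e.g. `"alpha"`, `"sigma2"`, `"k"`) when
#'   `chains` is a `posterior_chains` object.
#' @return the R-hat scalar.
#' @export
gelman_rhat <- function(chains, parameter = NULL) {
  traces <- if (inherits(chains, "posterior_chains")) {
    if (is.null(parameter)) stop("`parameter` required")
    post_burnin_traces(chains, parameter)
  } else {
    chains
  }
  if (length(traces) < 2L) stop("R-hat needs at least 2 chains")
  len <- lengths(traces)
  if (length(unique(len)) != 1L) stop("chains must have equal post-burn-in lengths")
  n <- len[1]
  if (n < 2L) stop("chains too short")
  means <- vapply(traces, mean, numeric(1))
  w <- mean(vapply(traces, stats::var, numeric(1)))
  b_over_n <- stats::var(means)
  if (w <= 0) return(if (b_over_n <= 0) 1 else Inf)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = N / (1 + 2 * sum(rho_t))` with autocorrelations accumulated up
#' to the first non-positive consecutive pair (Geyer's initial positive
#' sequence). Negative-autocorrelation traces would give ESS > N; these
#' are capped at N and flagged, as are constant traces.
#'
#' @param trace numeric vector (post burn-in), length >= 10.
#' @return ESS (scalar) with attribute `degenerate` when the trace was
#'   constant or anti-correlated.
#' @export
effective_sample_size <- function(trace) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 10L) stop("trace too short for ESS (need >= 10 samples)")
  if (stats::var(trace) == 0) {
    return(structure(as.numeric(n), degenerate = TRUE))
  }
  max_lag <- min(n - 1L, 10 * floor(10 * log10(n)))
  rho <- stats::acf(trace, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  t <- 1L
  while (t <= length(rho)) {
    pair <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- n / (1 + 2 * s)
  # anti-correlated traces (negative lag-1 autocorrelation) would exceed N
  # without truncation: cap at N and flag
  if (ess >= n && rho[1] < 0) {
    return(structure(as.numeric(n), degenerate = TRUE))
  }
  min(ess, n)
}
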