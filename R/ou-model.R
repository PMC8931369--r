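# Multi-regime Ornstein-Uhlenbeck regression: parameters, priors, and the
# reference (dense-matrix) likelihood. The sampler in src/ carries its own
# fast likelihood; the two are cross-checked in the test suite.

#' Multi-regime OU regression parameters
#'
#' @param alpha attraction toward the regime optimum (1/My), > 0.
#' @param sigma_sq diffusion variance of the response (log10^2/My), > 0.
#' @param theta per-regime optima on the intercept scale (log10), length K.
#' @param beta per-regime log-log slopes, length K (recycled if scalar).
#' @return an `ou_params` list with regime count `k`.
#' @export
ou_params <- function(alpha, sigma_sq, theta, beta) {
  beta <- rep_len(beta, length(theta))
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (sigma_sq <= 0) stop("`sigma_sq` must be > 0")
  structure(list(alpha = alpha, sigma_sq = sigma_sq,
                 theta = as.numeric(theta), beta = as.numeric(beta),
                 k = length(theta)),
            class = "ou_params")
}

#' Log-likelihood of the multi-regime OU allometric regression
#'
#' The response at tip i is normal with mean
#' `sum_k W[i,k] * (theta_k + beta_k * x_i)` — regime optima blended by the
#' OU weight matrix — and covariance `ou_covariance(tree, alpha, sigma_sq)`.
#' The predictor is treated as error-free and fixed per tip.
#'
#' @param x,y numeric vectors in tree tip order, or named by tip label.
#' @param tree an ultrametric `phylo`.
#' @param painting a [regime_painting()] covering every branch.
#' @param params an [ou_params()] with `k` equal to the painting's regime
#'   count.
#' @return the log-likelihood (scalar).
#' @export
ou_regression_loglik <- function(x, y, tree, painting, params) {
  stopifnot(inherits(params, "ou_params"), inherits(painting, "regime_painting"))
  if (params$k != painting$k) stop("params have ", params$k, " regimes, painting has ", painting$k)
  x <- align_to_tips(x, tree); y <- align_to_tips(y, tree)
  w <- ou_weight_matrix(tree, painting, params$alpha)
  mu <- as.numeric(w %*% params$theta + (w %*% params$beta) * x)
  v <- ou_covariance(tree, params$alpha, params$sigma_sq)
  dmvn_chol(y - mu, v)
}

align_to_tips <- function(v, tree) {
  n <- ape::Ntip(tree)
  if (!is.null(names(v))) {
    miss <- setdiff(tree$tip.label, names(v))
    if (length(miss)) stop("missing values for tips: ", paste(miss, collapse = ", "))
    v <- v[tree$tip.label]
  }
  if (length(v) != n) stop("trait vector length ", length(v), " != ", n, " tips")
  unname(v)
}

# multivariate normal log-density of residual r with covariance v
dmvn_chol <- function(r, v) {
  cl <- tryCatch(chol(v), error = function(e) {
    cl2 <- tryCatch(chol(v + diag(1e-10 * mean(diag(v)), nrow(v))),
                    error = function(e2) NULL)
    if (is.null(cl2)) {
      stop("covariance not positive definite (condition ~ ", format(kappa(v)), ")")
    }
    cl2
  })
  z <- backsolve(cl, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi) + 2 * sum(log(diag(cl))) + sum(z^2))
}

#' Prior specification for reversible-jump shift detection
#'
#' Defaults follow the standard weakly-informative choices for adaptive
#' shift detection: half-Cauchy(scale 0.1) on both `alpha` and `sigma_sq`;
#' a Poisson prior on the number of shifts with mean 2% of the branch
#' count, truncated at 20% of the branch count; shift locations uniform
#' over branches (at most one shift per branch); regime optima
#' `theta ~ N(mean(y), 1.5 sd(y))` and slopes `beta ~ N(PGLS slope, 0.3)`.
#'
#' @param tree a `phylo`; sets the branch count for the shift-count prior.
#' @param x,y predictor and response used to centre the theta and beta
#'   priors (named by tip or in tip order). If `beta_mean` is not given it
#'   is set to the slope of a REML PGLS of y on x.
#' @param alpha_scale,sigma_scale half-Cauchy scales.
#' @param shift_rate Poisson mean as a fraction of the branch count.
#' @param shift_max truncation as a fraction of the branch count.
#' @param theta_mean,theta_sd,beta_mean,beta_sd normal hyperparameters;
#'   data-derived defaults when `NULL`.
#' @return a `prior_spec` list (includes the realized Poisson mean
#'   `pois_mean` and truncation `max_shifts` for this tree).
#' @export
shift_priors <- function(tree, x, y, alpha_scale = 0.1, sigma_scale = 0.1,
                         shift_rate = 0.02, shift_max = 0.2,
                         theta_mean = NULL, theta_sd = NULL,
                         beta_mean = NULL, beta_sd = 0.3) {
  n_branch <- nrow(tree$edge)
  x <- align_to_tips(x, tree); y <- align_to_tips(y, tree)
  if (is.null(theta_mean)) theta_mean <- mean(y)
  if (is.null(theta_sd)) theta_sd <- 1.5 * stats::sd(y)
  if (is.null(beta_mean)) {
    d <- tibble::tibble(species = tree$tip.label, x = x, y = y)
    beta_mean <- unname(fit_pgls(d, y ~ x, tree)$coefficients["x"])
  }
  if (shift_max < shift_rate) stop("truncation fraction below the Poisson-mean fraction")
  max_shifts <- floor(shift_max * n_branch)
  pois_mean <- shift_rate * n_branch
  structure(list(alpha_scale = alpha_scale, sigma_scale = sigma_scale,
                 pois_mean = pois_mean, max_shifts = max_shifts,
                 n_branch = n_branch,
                 theta_mean = theta_mean, theta_sd = theta_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Shift priors: alpha, sigma2 ~ half-Cauchy(", x$alpha_scale, ", ",
      x$sigma_scale, "); shifts ~ Poisson(", signif(x$pois_mean, 4),
      ") truncated at ", x$max_shifts, " of ", x$n_branch, " branches;\n",
      "  theta ~ N(", signif(x$theta_mean, 4), ", ", signif(x$theta_sd, 4),
      "); beta ~ N(", signif(x$beta_mean, 4), ", ", x$beta_sd, ")\n", sep = "")
  invisible(x)
}

half_cauchy_logpdf <- function(x, scale) {
  ifelse(x <= 0, -Inf, log(2 / (pi * scale)) - log1p((x / scale)^2))
}

# normalized truncated-Poisson log-mass
trunc_pois_logpmf <- function(k, mean, max_k) {
  norm <- sum(stats::dpois(0:max_k, mean))
  ifelse(k > max_k | k < 0, -Inf, stats::dpois(k, mean, log = TRUE) - log(norm))
}

#' Log prior density of a multi-regime OU state
#'
#' Sum of the half-Cauchy densities for `alpha` and `sigma_sq`, normal
#' densities for every regime's `theta` and `beta`, the truncated-Poisson
#' mass of the shift count, and the uniform location mass over ways of
#' placing that many shifts on distinct branches (zero shifts contribute
#' no location term). States above the truncation bound get `-Inf`.
#'
#' @param params an [ou_params()].
#' @param painting a [regime_painting()].
#' @param priors a [shift_priors()] spec.
#' @return the log prior density.
#' @export
log_prior <- function(params, painting, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  k_shifts <- length(painting$shifts)
  if (k_shifts > priors$max_shifts) return(-Inf)
  half_cauchy_logpdf(params$alpha, priors$alpha_scale) +
    half_cauchy_logpdf(params$sigma_sq, priors$sigma_scale) +
    sum(stats::dnorm(params$theta, priors$theta_mean, priors$theta_sd, log = TRUE)) +
    sum(stats::dnorm(params$beta, priors$beta_mean, priors$beta_sd, log = TRUE)) +
    trunc_pois_logpmf(k_shifts, priors$pois_mean, priors$max_shifts) -
    lchoose(priors$n_branch, k_shifts)
}
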